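# Training: two-phase settling + combined error-driven / Hebbian updates.

set_inputs <- function(net, set) {
  list(mossy_fibers = t(set$mossy), climbing_fibers = t(set$climbing))
}

output_layer_name <- function(net) {
  nm <- names(Filter(function(l) l$role == "output", net$layers))
  if (length(nm) != 1L) stop("network must have exactly one output group")
  nm
}

# TRUE when the output layer projects to nothing, so plus-phase activations
# of all other layers equal their minus-phase values and the plus phase
# reduces to clamping the output.
output_is_terminal <- function(net) {
  out <- output_layer_name(net)
  !any(vapply(net$projections, function(p) p$src == out, TRUE))
}

#' Association error over an epoch
#'
#' Runs minus-phase (free-output) settling on every sample and returns
#' `100 * sum((target - output)^2) / (n_patterns * n_outputs)` — the averaged
#' sum-squared output error expressed as a percentage loss of the learned
#' association. Evaluation does not modify weights.
#'
#' @param network A `microzone_network`.
#' @param set A `training_set`.
#' @return Error percentage in `[0, 100]` (for targets and outputs in
#'   `[0, 1]`).
#' @export
epoch_error <- function(network, set) {
  out <- output_layer_name(network)
  if (network$layers[[out]]$n != ncol(set$targets)) {
    stop("shape error: output layer size does not match target size")
  }
  res <- settle_batch(network, set_inputs(network, set))
  Y <- res$act[[out]]
  100 * mean((t(set$targets) - Y)^2)
}

# One epoch: settle both phases over all patterns, apply the combined
# learning rule. Returns list(network, error_pct, max_wchange).
train_epoch <- function(net, set, order = NULL) {
  dy <- net$config$dynamics
  if (identical(dy$aggregation, "per_pattern")) {
    return(train_epoch_online(net, set, order))
  }
  inputs <- set_inputs(net, set)
  out <- output_layer_name(net)
  targets <- unname(t(set$targets))
  minus <- settle_batch(net, inputs)
  err <- 100 * mean((targets - minus$act[[out]])^2)
  if (output_is_terminal(net)) {
    plus_act <- minus$act
    tg <- targets
    tg[net$layers[[out]]$lesioned, ] <- 0
    plus_act[[out]] <- tg
  } else {
    plus <- settle_batch(net, inputs, clamp = stats::setNames(list(targets), out))
    plus_act <- plus$act
  }
  net2 <- apply_weight_deltas(net, minus$act, plus_act, ncol(targets))
  list(network = net2$net, error_pct = err, max_wchange = net2$max_change)
}

# Shared delta computation for a batch of patterns (columns).
apply_weight_deltas <- function(net, act_minus, act_plus, P) {
  lp <- net$config$learning
  max_change <- 0
  for (i in seq_along(net$projections)) {
    p <- net$projections[[i]]
    if (!p$plastic) next
    lr <- lp$epsilon * min(p$strength, lp$eps_cap)
    if (lr == 0 && lp$lambda == 0) next
    Xm <- act_minus[[p$src]]; Ym <- act_minus[[p$dst]]
    Xp <- act_plus[[p$src]]; Yp <- act_plus[[p$dst]]
    phases_agree <- identical(Xp, Xm) && identical(Yp, Ym)
    if (phases_agree && lp$lambda * lp$cpca_correction == 0) next
    xy_plus <- tcrossprod(Xp, Yp)
    # when neither end differs between phases the error-driven term vanishes
    gr <- if (phases_agree) 0 else {
      (xy_plus - tcrossprod(Xm, Ym)) / P
    }
    if (p$sign < 0) gr <- -gr
    # soft weight bounding: increases approach 1, decreases approach 0
    # (keeps weights in [0,1] smoothly and damps batch oscillation)
    gr <- ifelse(gr > 0, gr * (1 - p$W), gr * p$W)
    ybar <- rowMeans(Yp)
    hb <- xy_plus / P - sweep(p$W, 2, ybar, `*`)
    dW <- lr * ((1 - lp$lambda) * gr +
                  lp$lambda * lp$cpca_correction * hb)
    Wnew <- clip01(p$W + dW)
    if (!is.null(p$mask)) Wnew <- Wnew * p$mask
    max_change <- max(max_change, max(abs(Wnew - p$W)))
    net$projections[[i]]$W <- Wnew
  }
  # trainable biases on all non-input layers (error-driven rule)
  for (nm in names(net$layers)) {
    ly <- net$layers[[nm]]
    if (ly$role == "input") next
    if (identical(act_plus[[nm]], act_minus[[nm]])) next
    db <- lp$epsilon * (1 - lp$lambda) *
      rowMeans(act_plus[[nm]] - act_minus[[nm]])
    bnew <- unname(pmin(pmax(ly$bias + db, 0), lp$bias_max))
    max_change <- max(max_change, max(abs(bnew - ly$bias)))
    net$layers[[nm]]$bias <- bnew
  }
  list(net = net, max_change = max_change)
}

train_epoch_online <- function(net, set, order = NULL) {
  inputs <- set_inputs(net, set)
  out <- output_layer_name(net)
  targets <- unname(t(set$targets))
  order <- order %||% seq_len(set$n_samples)
  sq_err <- 0
  max_change <- 0
  for (j in order) {
    in1 <- lapply(inputs, function(m) m[, j, drop = FALSE])
    t1 <- targets[, j, drop = FALSE]
    minus <- settle_batch(net, in1)
    sq_err <- sq_err + sum((t1 - minus$act[[out]])^2)
    if (output_is_terminal(net)) {
      plus_act <- minus$act
      t1c <- t1
      t1c[net$layers[[out]]$lesioned, ] <- 0
      plus_act[[out]] <- t1c
    } else {
      plus <- settle_batch(net, in1, clamp = stats::setNames(list(t1), out))
      plus_act <- plus$act
    }
    upd <- apply_weight_deltas(net, minus$act, plus_act, 1L)
    net <- upd$net
    max_change <- max(max_change, upd$max_change)
  }
  err <- 100 * sq_err / (set$n_samples * nrow(targets))
  list(network = net, error_pct = err, max_wchange = max_change)
}

# When every projection outside the output layer is effectively frozen (the
# contrastive term vanishes on them in a circuit whose output projects to
# nothing, and the Hebbian mix is zero), the cortical stage settles to the
# same state every epoch. Training then caches one full settle per run and
# replays only the output layer's cycles against the recorded per-cycle
# activations of its presynaptic layer.
trainer_cacheable <- function(net) {
  if (!identical(net$config$dynamics$aggregation, "per_epoch")) return(FALSE)
  if (isTRUE(net$config$training$shuffle)) return(FALSE)
  if (!output_is_terminal(net)) return(FALSE)
  out <- output_layer_name(net)
  lp <- net$config$learning
  free_srcs <- character(0)
  for (p in net$projections) {
    if (p$dst == out) {
      if (net$layers[[p$src]]$role != "input") {
        free_srcs <- union(free_srcs, p$src)
      }
      next
    }
    lr <- lp$epsilon * min(p$strength, lp$eps_cap)
    if (p$plastic && lr * lp$lambda * lp$cpca_correction != 0) return(FALSE)
  }
  length(free_srcs) <= 1L
}

# Replay the output layer's settling cycles against the cached per-cycle
# activation history of its free presynaptic layer. Mirrors the engine's
# dynamics exactly (synchronous updates: cycle c sees cycle c-1 activations).
replay_output <- function(net, inputs, hist, P) {
  out <- output_layer_name(net)
  ly <- net$layers[[out]]
  dy <- net$config$dynamics
  ch <- net$config$channels
  gb_e <- ch$gbar[["excit"]]; gb_l <- ch$gbar[["leak"]]
  gb_i <- ch$gbar[["inhib"]]
  E_e <- ch$E[["excit"]]; E_l <- ch$E[["leak"]]; E_i <- ch$E[["inhib"]]
  th <- dy$threshold
  E_min <- min(ch$E); E_max <- max(ch$E)
  ge0 <- matrix(ly$bias, ly$n, P)
  gi0 <- matrix(0, ly$n, P)
  dyn <- NULL
  for (p in net$projections) {
    if (p$dst != out) next
    src <- net$layers[[p$src]]
    scale <- p$strength / (src$n * src$act_avg)
    if (src$role == "input") {
      contrib <- scale * crossprod(p$W, inputs[[p$src]])
      if (p$sign > 0) ge0 <- ge0 + contrib else gi0 <- gi0 + contrib
    } else {
      dyn <- list(p = p, scale = scale, n_src = src$n)
    }
  }
  alive <- !ly$lesioned
  vm <- matrix(E_l, ly$n, P)
  y <- matrix(0, ly$n, P)
  for (cyc in seq_len(dy$cycles)) {
    ge <- ge0; gi_syn <- gi0
    if (!is.null(dyn)) {
      x <- if (cyc == 1L) matrix(0, dyn$n_src, P) else hist[[cyc - 1L]]
      contrib <- dyn$scale * crossprod(dyn$p$W, x)
      if (dyn$p$sign > 0) ge <- ge + contrib else gi_syn <- gi_syn + contrib
    }
    gith <- (ge * gb_e * (E_e - th) + gb_l * (E_l - th) +
               gi_syn * gb_i * (E_i - th)) / ((th - E_i) * gb_i)
    gik <- kwta_gi_columns(gith, ly$k, alive)
    gi <- gi_syn + rep(gik, each = ly$n)
    G <- ge * gb_e + gb_l + gi * gb_i
    num <- ge * gb_e * E_e + gb_l * E_l + gi * gb_i * E_i
    alpha <- pmin(dy$tau * G, 1)
    vm <- vm + alpha * (num / G - vm)
    vm <- pmin(pmax(vm, E_min), E_max)
    y <- rate_activation(vm, dy)
    y[!alive, ] <- 0
  }
  y
}

#' Train a network to criterion
#'
#' Repeats epochs of (minus-phase settle, plus-phase settle, weight update)
#' over all patterns until the association error, measured on free
#' (minus-phase) outputs, falls below the criterion — zero percent to six
#' significant figures by default — or `max_epochs` is reached. The error
#' reported for an epoch is measured before that epoch's weight update, and
#' training stops without a further update once the criterion is met.
#'
#' @param network A `microzone_network`.
#' @param set A `training_set`.
#' @param max_epochs Cap on epochs (default from the config).
#' @param seed Seed used only when the config enables pattern shuffling.
#' @return A list with `network` (trained), `records` (data.frame of
#'   `epoch`, `error_pct`, `max_wchange`), `converged`, `epochs`.
#' @export
train_to_criterion <- function(network, set, max_epochs = NULL, seed = 1L) {
  tr <- network$config$training
  max_epochs <- as.integer(max_epochs %||% tr$max_epochs)
  stopifnot(max_epochs >= 1)
  crit <- tr$criterion
  epochs <- integer(0); errs <- numeric(0); chg <- numeric(0)
  converged <- FALSE
  if (trainer_cacheable(network)) {
    out <- output_layer_name(network)
    if (network$layers[[out]]$n != ncol(set$targets)) {
      stop("shape error: output layer size does not match target size")
    }
    inputs <- set_inputs(network, set)
    targets <- unname(t(set$targets))
    P <- ncol(targets)
    free_src <- NULL
    for (p in network$projections) {
      if (p$dst == out && network$layers[[p$src]]$role != "input") {
        free_src <- p$src
      }
    }
    base <- settle_batch(network, inputs, track = free_src)
    hist <- base$history
    for (e in seq_len(max_epochs)) {
      out_act <- replay_output(network, inputs, hist, P)
      err <- 100 * mean((targets - out_act)^2)
      if (err < crit) {
        epochs <- c(epochs, e); errs <- c(errs, err); chg <- c(chg, 0)
        converged <- TRUE
        break
      }
      act_minus <- base$act
      act_minus[[out]] <- out_act
      act_plus <- base$act
      tg <- targets
      tg[network$layers[[out]]$lesioned, ] <- 0
      act_plus[[out]] <- tg
      upd <- apply_weight_deltas(network, act_minus, act_plus, P)
      network <- upd$net
      epochs <- c(epochs, e); errs <- c(errs, err)
      chg <- c(chg, upd$max_change)
    }
    return(list(network = network,
                records = data.frame(epoch = epochs, error_pct = errs,
                                     max_wchange = chg),
                converged = converged, epochs = length(epochs)))
  }
  for (e in seq_len(max_epochs)) {
    order <- if (isTRUE(tr$shuffle)) {
      with_seed(derive_seed(seed, 7L, e), sample(set$n_samples))
    } else NULL
    step <- train_epoch(network, set, order = order)
    if (step$error_pct < crit) {
      # criterion met on current weights; do not apply this epoch's update
      epochs <- c(epochs, e); errs <- c(errs, step$error_pct)
      chg <- c(chg, 0)
      converged <- TRUE
      break
    }
    network <- step$network
    epochs <- c(epochs, e); errs <- c(errs, step$error_pct)
    chg <- c(chg, step$max_wchange)
  }
  list(network = network,
       records = data.frame(epoch = epochs, error_pct = errs,
                            max_wchange = chg),
       converged = converged, epochs = length(epochs))
}

#' Detect a training local minimum
#'
#' TRUE when the latest epoch's maximum absolute weight change is strictly
#' below `tolerance` while the error is still above criterion — i.e. the
#' network has stopped adjusting without having learned the association.
#'
#' @param records Training records (`data.frame` with `error_pct`,
#'   `max_wchange`), at least 2 rows.
#' @param tolerance Strict threshold on the weight change.
#' @param criterion Error criterion (percent).
#' @return Logical.
#' @export
detect_local_minimum <- function(records, tolerance = 1e-9,
                                 criterion = 5e-7) {
  stopifnot(nrow(records) >= 2)
  last <- records[nrow(records), ]
  (last$max_wchange < tolerance) && (last$error_pct > criterion)
}
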