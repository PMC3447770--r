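# Batched settling. Patterns are columns; every per-layer quantity is an
# (n_units x n_patterns) matrix. The cycle loop runs in compiled code
# (src/settle.cpp); settle_batch_r below is a plain-R reference
# implementation of the same dynamics, kept for cross-checking.

settle_batch <- function(net, inputs, clamp = NULL, cycles = NULL,
                         track = NULL) {
  dy <- net$config$dynamics
  ch <- net$config$channels
  cycles <- cycles %||% dy$cycles
  P <- ncol(inputs[[1]])
  lnames <- names(net$layers)
  acts <- vector("list", length(lnames))
  is_free <- logical(length(lnames))
  for (li in seq_along(lnames)) {
    ly <- net$layers[[li]]
    nm <- ly$name
    if (ly$role == "input") {
      a <- inputs[[nm]]
      if (is.null(a)) stop(sprintf("settle: no input provided for '%s'", nm))
      a <- matrix(a, ly$n, P)
      a[ly$lesioned, ] <- 0
      acts[[li]] <- a
    } else if (nm %in% names(clamp %||% list())) {
      a <- matrix(clamp[[nm]], ly$n, P)
      a[ly$lesioned, ] <- 0
      acts[[li]] <- a
    } else {
      acts[[li]] <- matrix(0, ly$n, P)
      is_free[li] <- TRUE
    }
  }
  src_i <- match(vapply(net$projections, `[[`, "", "src"), lnames) - 1L
  dst_i <- match(vapply(net$projections, `[[`, "", "dst"), lnames) - 1L
  scales <- vapply(net$projections, function(p) {
    s <- net$layers[[p$src]]
    p$strength / (s$n * s$act_avg)
  }, 0)
  res <- .settle_engine(
    acts, is_free,
    lapply(net$layers, `[[`, "bias"),
    lapply(net$layers, function(l) !l$lesioned),
    vapply(net$layers, function(l) as.integer(l$k), 0L),
    as.list(src_i), as.list(dst_i), as.list(scales),
    lapply(net$projections, `[[`, "sign"),
    lapply(net$projections, `[[`, "W"),
    as.integer(cycles), dy$tau, dy$gain, dy$threshold,
    ch$gbar[["excit"]], ch$gbar[["leak"]], ch$gbar[["inhib"]],
    ch$E[["excit"]], ch$E[["leak"]], ch$E[["inhib"]],
    if (is.null(track)) -1L else match(track, lnames) - 1L
  )
  names(res$act) <- lnames
  names(res$vm) <- lnames
  res
}

# --- plain-R reference implementation (used in tests as an independent
# --- cross-check of the compiled engine) -----------------------------------

layer_net_input <- function(net, dst, act, P) {
  ly <- net$layers[[dst]]
  ge <- matrix(ly$bias, ly$n, P)
  gi <- matrix(0, ly$n, P)
  for (p in net$projections) {
    if (p$dst != dst) next
    src_ly <- net$layers[[p$src]]
    scale <- p$strength / (src_ly$n * src_ly$act_avg)
    contrib <- scale * crossprod(p$W, act[[p$src]])
    if (p$sign > 0) ge <- ge + contrib else gi <- gi + contrib
  }
  list(ge = ge, gi = gi)
}

kwta_gi_columns <- function(gith, k, alive) {
  n_alive <- sum(alive)
  k <- min(k, n_alive)
  P <- ncol(gith)
  if (k >= n_alive) return(numeric(P))
  if (!all(alive)) gith[!alive, ] <- -Inf
  if (k <= 0L) {
    mx <- apply(gith, 2, function(x) max(x[is.finite(x)], 0))
    return(mx + 1)
  }
  vapply(seq_len(P), function(j) {
    s <- sort(-gith[, j], partial = c(k, k + 1L))
    max(-(s[k] + s[k + 1L]) / 2, 0)
  }, 0)
}

settle_batch_r <- function(net, inputs, clamp = NULL, cycles = NULL) {
  ch <- net$config$channels
  dy <- net$config$dynamics
  cycles <- cycles %||% dy$cycles
  P <- ncol(inputs[[1]])
  gb_e <- ch$gbar[["excit"]]; gb_l <- ch$gbar[["leak"]]
  gb_i <- ch$gbar[["inhib"]]
  E_e <- ch$E[["excit"]]; E_l <- ch$E[["leak"]]; E_i <- ch$E[["inhib"]]
  th <- dy$threshold
  E_min <- min(ch$E); E_max <- max(ch$E)
  act <- list(); vm <- list(); free <- character(0)
  for (ly in net$layers) {
    nm <- ly$name
    if (ly$role == "input") {
      a <- matrix(inputs[[nm]], ly$n, P)
      a[ly$lesioned, ] <- 0
      act[[nm]] <- a
    } else if (nm %in% names(clamp %||% list())) {
      a <- matrix(clamp[[nm]], ly$n, P)
      a[ly$lesioned, ] <- 0
      act[[nm]] <- a
    } else {
      act[[nm]] <- matrix(0, ly$n, P)
      vm[[nm]] <- matrix(E_l, ly$n, P)
      free <- c(free, nm)
    }
  }
  for (cyc in seq_len(cycles)) {
    new_act <- act
    for (nm in free) {
      ly <- net$layers[[nm]]
      ni <- layer_net_input(net, nm, act, P)
      ge <- ni$ge; gi_syn <- ni$gi
      alive <- !ly$lesioned
      gith <- (ge * gb_e * (E_e - th) + gb_l * (E_l - th) +
                 gi_syn * gb_i * (E_i - th)) / ((th - E_i) * gb_i)
      gik <- kwta_gi_columns(gith, ly$k, alive)
      gi <- gi_syn + rep(gik, each = ly$n)
      G <- ge * gb_e + gb_l + gi * gb_i
      num <- ge * gb_e * E_e + gb_l * E_l + gi * gb_i * E_i
      alpha <- pmin(dy$tau * G, 1)
      v <- vm[[nm]] + alpha * (num / G - vm[[nm]])
      if (!all(is.finite(v))) {
        stop(sprintf("settling-failure: non-finite state in layer '%s' at cycle %d",
                     nm, cyc))
      }
      v <- pmin(pmax(v, E_min), E_max)
      y <- rate_activation(v, dy)
      y[!alive, ] <- 0
      vm[[nm]] <- v
      new_act[[nm]] <- y
    }
    act <- new_act
  }
  list(act = act, vm = vm)
}

#' Settle the network on one pattern
#'
#' Runs the configured number of cycles of net-input -> kWTA inhibition ->
#' membrane update -> rate activation for all non-clamped layers
#' (synchronous updates). In the minus (expectation) phase the output layer
#' runs free; in the plus (outcome) phase it is clamped to the target.
#' Clamped layers hold their values exactly. Final activations are recorded
#' per layer as `y_minus` or `y_plus`.
#'
#' @param network A [build_microzone()] network.
#' @param clamped Named list mapping group names to activation vectors.
#'   Input layers must be clamped; in the plus phase the output layer is
#'   clamped to the target.
#' @param phase `"minus"` or `"plus"`.
#' @param params Optional [dynamics_params()] override.
#' @return The network with per-layer `act` (final activations) and phase
#'   records updated.
#' @export
settle <- function(network, clamped, phase = c("minus", "plus"),
                   params = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(network, "microzone_network"))
  if (!is.null(params)) network$config$dynamics <- params
  input_names <- names(Filter(function(l) l$role == "input", network$layers))
  output_names <- names(Filter(function(l) l$role == "output", network$layers))
  missing_in <- setdiff(input_names, names(clamped))
  if (length(missing_in)) {
    stop("settle: input groups not clamped: ", paste(missing_in, collapse = ", "))
  }
  if (phase == "plus" && !all(output_names %in% names(clamped))) {
    stop("settle: plus phase requires the output group(s) to be clamped")
  }
  unknown <- setdiff(names(clamped), names(network$layers))
  if (length(unknown)) stop("settle: unknown clamped group(s): ",
                            paste(unknown, collapse = ", "))
  inputs <- lapply(clamped[intersect(names(clamped), input_names)],
                   function(v) matrix(v, ncol = 1))
  clamp <- lapply(clamped[setdiff(names(clamped), input_names)],
                  function(v) matrix(v, ncol = 1))
  res <- settle_batch(network, inputs, clamp = clamp)
  slot <- if (phase == "minus") "y_minus" else "y_plus"
  for (nm in names(network$layers)) {
    network$layers[[nm]]$act <- drop(res$act[[nm]])
    network$layers[[nm]][[slot]] <- drop(res$act[[nm]])
  }
  network
}
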