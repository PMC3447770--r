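#' Parametric stimulus-trace reference curve
#'
#' The classic conditioned-response curve relating association strength to
#' the inter-stimulus interval: `A * (t/t0) * exp(1 - t/t0)`, peaking at
#' `t0` (0.25 s by default) and decaying slowly for longer intervals.
#'
#' @param isi Inter-stimulus interval(s) in seconds.
#' @param t0 Peak location (s).
#' @param A Peak amplitude.
#' @return Reference association strength(s).
#' @export
stimulus_trace <- function(isi, t0 = 0.25, A = 1) {
  x <- isi / t0
  A * x * exp(1 - x)
}

#' Inter-stimulus-interval validation sweep
#'
#' Trains the network on the conditioning set and, at checkpoints of the
#' training (start, middle, end by default, as fractions of the epochs
#' needed to reach criterion), evaluates the association over a grid of
#' inter-stimulus intervals by shifting the climbing-fiber stream relative to
#' the mossy stream. Association strength at a checkpoint is the epoch error
#' min-max rescaled across the sweep (1 at the best interval, 0 at the
#' worst); the divergence of each checkpoint is the mean absolute difference
#' from the reference trace, in percent. Training proceeds deterministically,
#' so checkpoint states are reconstructed by re-running the recorded number
#' of epochs.
#'
#' @param config A `microzone_config`.
#' @param isi_grid Inter-stimulus intervals in seconds (must span 0 to 3).
#' @param checkpoints Fractions of the training duration.
#' @param seed Master seed.
#' @param reference Reference trace: a function of isi or a numeric vector
#'   over `isi_grid`; defaults to [stimulus_trace()].
#' @return An object of class `hull_result` with the strength matrix
#'   (checkpoint x isi), the reference values and per-checkpoint divergence.
#' @export
run_hull_test <- function(config, isi_grid = seq(0, 3, by = 0.25),
                          checkpoints = c(0, 0.5, 1), seed = 1L,
                          reference = stimulus_trace) {
  stopifnot(all(isi_grid >= 0), all(isi_grid <= 3))
  ref <- if (is.function(reference)) reference(isi_grid) else {
    stopifnot(length(reference) == length(isi_grid))
    as.numeric(reference)
  }
  fit <- fit_microzone(config, seed = seed)
  total <- fit$epochs
  ep_at <- sort(unique(pmax(0L, as.integer(round(checkpoints * total)))))
  # reconstruct network state at each checkpoint by deterministic re-runs
  weight_seed <- fit$seeds$weights
  set <- fit$set
  strengths <- matrix(NA_real_, length(ep_at), length(isi_grid),
                      dimnames = list(paste0("epoch_", ep_at), NULL))
  errors <- strengths
  degenerate <- logical(length(ep_at))
  for (ci in seq_along(ep_at)) {
    net <- if (ep_at[ci] == 0L) {
      build_microzone(config, seed = weight_seed)
    } else if (ep_at[ci] >= total) {
      fit$network
    } else {
      build_microzone(config, seed = weight_seed) |>
        train_to_criterion(set, max_epochs = ep_at[ci], seed = fit$seeds$master) |>
        (\(x) x$network)()
    }
    errs <- vapply(isi_grid, function(isi) {
      epoch_error(net, shift_stimuli(set, isi))
    }, 0)
    errors[ci, ] <- errs
    rng <- max(errs) - min(errs)
    if (rng < 1e-9) {
      degenerate[ci] <- TRUE
      strengths[ci, ] <- 0
    } else {
      strengths[ci, ] <- (max(errs) - errs) / rng
    }
  }
  divergence <- 100 * rowMeans(abs(sweep(strengths, 2, ref)))
  structure(
    list(isi_grid = isi_grid, checkpoints = checkpoints,
         checkpoint_epochs = ep_at, total_epochs = total,
         strength = strengths, error_pct = errors, reference = ref,
         divergence = divergence, degenerate = degenerate,
         converged = fit$converged, seed = as.integer(seed)),
    class = "hull_result"
  )
}

#' @export
print.hull_result <- function(x, ...) {
  cat(sprintf("ISI sweep: %d intervals in [%g, %g] s, %d checkpoints (trained %d epochs)\n",
              length(x$isi_grid), min(x$isi_grid), max(x$isi_grid),
              length(x$checkpoint_epochs), x$total_epochs))
  cat("  divergence from reference trace (%):",
      paste(sprintf("%.1f", x$divergence), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.hull_result <- function(x, ...) {
  graphics::matplot(x$isi_grid, t(x$strength), type = "l", lty = 1,
                    xlab = "inter-stimulus interval (s)",
                    ylab = "association strength", ...)
  graphics::lines(x$isi_grid, x$reference, lty = 2)
  graphics::legend("topright",
                   legend = c(rownames(x$strength), "reference"),
                   lty = c(rep(1, nrow(x$strength)), 2),
                   col = c(seq_len(nrow(x$strength)), 1), cex = 0.8)
  invisible(x)
}
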