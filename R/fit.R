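#' Fit a cerebellar microzone to the conditioning task
#'
#' Builds the network from a configuration, generates (or accepts) a
#' training set, and trains to criterion with two-phase settling and the
#' combined error-driven / Hebbian rule. This is the package's central
#' model-fitting entry point; the returned object supports `print()`,
#' `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()` and
#' `plot()`.
#'
#' @param config A [microzone_config()]; default [default_config()].
#' @param set Optional `training_set`; generated from `config` when `NULL`.
#' @param seed Integer master seed. Weight initialization and the mossy
#'   stream get independent seeds derived from it.
#' @param max_epochs Optional cap on training epochs.
#' @return An object of class `microzone_fit`.
#' @examples
#' \donttest{
#' fit <- fit_microzone(seed = 1)
#' fit
#' }
#' @export
fit_microzone <- function(config = default_config(), set = NULL, seed = 1L,
                          max_epochs = NULL) {
  weight_seed <- derive_seed(seed, 1L)
  set_seed <- derive_seed(seed, 2L)
  if (is.null(set)) set <- generate_training_set(config, seed = set_seed)
  net <- build_microzone(config, seed = weight_seed)
  tr <- train_to_criterion(net, set, max_epochs = max_epochs, seed = seed)
  structure(
    list(network = tr$network, records = tr$records,
         converged = tr$converged, epochs = tr$epochs, set = set,
         config = config,
         seeds = list(master = as.integer(seed), weights = weight_seed,
                      stream = set_seed)),
    class = "microzone_fit"
  )
}

#' @export
print.microzone_fit <- function(x, ...) {
  err <- x$records$error_pct[nrow(x$records)]
  cat(sprintf("Microzone fit: %d epochs, final association error %.6g%%%s\n",
              x$epochs, err,
              if (x$converged) " (criterion reached)" else " (NOT converged)"))
  invisible(x)
}

#' @export
summary.microzone_fit <- function(object, ...) {
  print(object)
  cat("Layers:\n")
  for (ly in object$network$layers) {
    cat(sprintf("  %-16s n=%5d k=%4d lesioned=%d\n", ly$name, ly$n, ly$k,
                sum(ly$lesioned)))
  }
  cat(sprintf("Training: %d samples, seed %d\n", object$set$n_samples,
              object$seeds$master))
  invisible(object)
}

#' @export
coef.microzone_fit <- function(object, ...) {
  ws <- lapply(object$network$projections, `[[`, "W")
  names(ws) <- vapply(object$network$projections,
                      function(p) paste0(p$src, "->", p$dst), "")
  ws
}

#' Predict deep-nuclei responses for a training set
#'
#' Runs minus-phase (free) settling and returns the output-layer rate
#' activations, one row per sample.
#'
#' @param object A `microzone_fit`.
#' @param newdata A `training_set`; defaults to the set used for fitting.
#' @param ... Unused.
#' @return A numeric matrix (samples x output units).
#' @export
predict.microzone_fit <- function(object, newdata = NULL, ...) {
  set <- newdata %||% object$set
  out <- output_layer_name(object$network)
  res <- settle_batch(object$network, set_inputs(object$network, set))
  t(res$act[[out]])
}

#' @export
fitted.microzone_fit <- function(object, ...) predict(object)

#' @export
residuals.microzone_fit <- function(object, ...) {
  object$set$targets - fitted(object)
}

#' Simulate deep-nuclei responses under fresh stimulus streams
#'
#' Draws `nsim` new conditioning sets (fresh mossy-fiber random walks; the
#' climbing sequence is deterministic) and returns the trained network's
#' free-phase output for each.
#'
#' @param object A `microzone_fit`.
#' @param nsim Number of simulated stimulus streams.
#' @param seed Integer seed for the new streams.
#' @param ... Unused.
#' @return A list of `nsim` response matrices (samples x output units), each
#'   with its `training_set` attached as attribute `"set"`.
#' @export
simulate.microzone_fit <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(i) {
    set <- generate_training_set(object$config,
                                 seed = derive_seed(seed, 91L, i))
    out <- predict(object, newdata = set)
    attr(out, "set") <- set
    out
  })
}

#' @export
plot.microzone_fit <- function(x, ...) {
  graphics::plot(x$records$epoch, x$records$error_pct, type = "l",
                 xlab = "epoch", ylab = "association error (%)",
                 main = "Training error", ...)
  invisible(x)
}
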