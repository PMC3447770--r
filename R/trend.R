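#' Linear vs logarithmic trend of a degradation curve
#'
#' Least-squares fits of trial-mean error against fraction removed, to
#' `y = a + b*f` and to `y = a + b*log(1 + c*f)` with the inner scale `c`
#' fixed at `n_steps / max_fraction` before fitting (keeping the second model
#' linear in its parameters). The curve is classified `"sublinear"` when the
#' logarithmic R-squared exceeds the linear R-squared by at least `margin`,
#' otherwise `"linear"`. A constant curve yields a degenerate-fit flag and no
#' classification.
#'
#' @param curve A `degradation_curve` (at least 4 steps).
#' @param margin R-squared margin for the sublinear call.
#' @return An object of class `trend_fit` with `linear` and `logarithmic`
#'   coefficient/R-squared lists and `classification`.
#' @export
fit_trend <- function(curve, margin = 0.02) {
  stopifnot(inherits(curve, "degradation_curve"))
  f <- curve$fractions
  y <- curve$mean_error
  if (length(f) < 4) stop("fit_trend requires at least 4 steps")
  if (!all(is.finite(y)) || stats::var(y) < 1e-20) {
    return(structure(list(group = curve$group, degenerate = TRUE,
                          linear = NULL, logarithmic = NULL,
                          classification = NA_character_),
                     class = "trend_fit"))
  }
  c_scale <- length(f) / max(f)
  lin <- stats::lm(y ~ f)
  z <- log(1 + c_scale * f)
  lg <- stats::lm(y ~ z)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- function(m) 1 - sum(stats::residuals(m)^2) / ss_tot
  cls <- if (r2(lg) - r2(lin) >= margin) "sublinear" else "linear"
  structure(
    list(group = curve$group, degenerate = FALSE,
         linear = list(intercept = unname(stats::coef(lin)[1]),
                       slope = unname(stats::coef(lin)[2]),
                       r_squared = r2(lin)),
         logarithmic = list(intercept = unname(stats::coef(lg)[1]),
                            coefficient = unname(stats::coef(lg)[2]),
                            inner_scale = c_scale,
                            r_squared = r2(lg)),
         classification = cls),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("Trend fit [%s]: degenerate (constant curve)\n", x$group))
  } else {
    cat(sprintf("Trend fit [%s]: %s (linear R2 = %.3f, log R2 = %.3f)\n",
                x$group, x$classification, x$linear$r_squared,
                x$logarithmic$r_squared))
  }
  invisible(x)
}
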