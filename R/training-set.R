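#' Generate the mossy-fiber input stream
#'
#' Each fiber is a bounded random walk on `[0, 1]`, reflecting at the edges,
#' with per-step increments drawn uniformly from
#' `[-slow_change_bound, slow_change_bound]`. The values change slowly from
#' sample to sample while the long-run marginal distribution is approximately
#' uniform on `[0, 1]` (reflection preserves the uniform stationary law).
#'
#' @param n_samples Number of samples (rows), `>= 1`.
#' @param n_fibers Number of mossy fibers (columns).
#' @param slow_change_bound Maximum per-step change, in `(0, 1]`.
#' @param seed Integer seed.
#' @return An `n_samples x n_fibers` matrix of values in `[0, 1]`.
#' @export
generate_mossy_stream <- function(n_samples, n_fibers = 24L,
                                  slow_change_bound = 0.15, seed = 1L) {
  if (!is.finite(slow_change_bound) || slow_change_bound <= 0 ||
      slow_change_bound > 1) {
    stop("parameter error: slow_change_bound must be in (0, 1]")
  }
  stopifnot(n_samples >= 1, n_fibers >= 1)
  with_seed(seed, {
    x0 <- stats::runif(n_fibers)
    steps <- matrix(stats::runif((n_samples - 1) * n_fibers,
                                 -slow_change_bound, slow_change_bound),
                    nrow = max(n_samples - 1, 0), ncol = n_fibers)
    out <- matrix(0, n_samples, n_fibers)
    out[1, ] <- x0
    if (n_samples > 1) {
      for (t in 2:n_samples) {
        v <- out[t - 1, ] + steps[t - 1, ]
        # reflect at the boundaries
        v <- abs(v)
        v <- 1 - abs(1 - v)
        out[t, ] <- v
      }
    }
    colnames(out) <- sprintf("MF_%d", seq_len(n_fibers))
    out
  })
}

# 3-bit reflected (gray) sequence: consecutive codes differ in one bit,
# including the wrap-around.
gray_codes <- function(bits = 3L) {
  n <- 2L^bits
  idx <- 0:(n - 1)
  g <- bitwXor(idx, idx %/% 2L)
  t(vapply(g, function(v) as.integer(intToBits(v)[bits:1]), integer(bits)))
}

#' Generate the climbing-fiber input stream
#'
#' Emits the 3-bit reflected (gray-code) sequence cyclically, so consecutive
#' rows differ in exactly one position (including the wrap-around) and all 8
#' patterns appear once per period of 8. `code = "binary"` instead emits
#' plain binary counting (the literal table layout), which changes more than
#' one bit on some transitions.
#'
#' @param n_samples Number of samples.
#' @param n_fibers Number of climbing fibers (3).
#' @param code `"gray"` (canonical) or `"binary"`.
#' @return An `n_samples x n_fibers` binary matrix.
#' @export
generate_climbing_stream <- function(n_samples, n_fibers = 3L,
                                     code = c("gray", "binary")) {
  code <- match.arg(code)
  stopifnot(n_samples >= 1, n_fibers == 3L)
  period <- if (code == "gray") {
    gray_codes(3L)
  } else {
    t(vapply(0:7, function(v) as.integer(intToBits(v)[3:1]), integer(3)))
  }
  out <- period[((seq_len(n_samples) - 1L) %% 8L) + 1L, , drop = FALSE]
  colnames(out) <- sprintf("CF_%d", seq_len(n_fibers))
  out
}

#' Derive deep-cerebellar-neuron targets from the climbing-fiber pattern
#'
#' The target is one-hot on two output units: `(1, 0)` when the first
#' climbing-fiber bit is 0 and `(0, 1)` when it is 1.
#'
#' @param climbing A binary matrix with 3 columns (or a single row vector).
#' @return A two-column binary target matrix.
#' @export
derive_targets <- function(climbing) {
  if (is.null(dim(climbing))) climbing <- matrix(climbing, nrow = 1)
  if (ncol(climbing) != 3L) stop("encoding error: climbing rows must be 3 wide")
  if (!all(climbing %in% c(0, 1))) {
    stop("encoding error: climbing values must be binary")
  }
  out <- cbind(DN_1 = 1 - climbing[, 1], DN_2 = climbing[, 1])
  out
}

#' Generate the puff/buzz conditioning training set
#'
#' 140 samples (by default) of 24 mossy-fiber values (slow bounded random
#' walks on `[0, 1]`), 3 climbing-fiber bits (cyclic gray-code sequence) and
#' 2 one-hot deep-nuclei targets determined by the first climbing bit. Only
#' the mossy stream is stochastic; the climbing sequence is fixed.
#'
#' @param config A `microzone_config` (provides input/output sizes and
#'   training parameters); defaults to [default_config()].
#' @param seed Integer seed for the mossy stream.
#' @param n_samples Optional override of the sample count.
#' @return An object of class `training_set` with elements `mossy`,
#'   `climbing`, `targets`, `n_samples`, `seed`, `isi`, `sample_dt`.
#' @examples
#' ts <- generate_training_set(default_config(), seed = 1)
#' dim(ts$mossy)
#' @export
generate_training_set <- function(config = default_config(), seed = 1L,
                                  n_samples = NULL) {
  tr <- config$training
  n <- as.integer(n_samples %||% tr$n_samples)
  nms <- vapply(config$groups, `[[`, "", "name")
  n_mf <- config$groups[[match("mossy_fibers", nms)]]$count
  n_cf <- config$groups[[match("climbing_fibers", nms)]]$count
  mossy <- generate_mossy_stream(n, n_mf, tr$slow_change_bound, seed)
  climbing <- generate_climbing_stream(n, n_cf, tr$code)
  targets <- derive_targets(climbing)
  structure(
    list(mossy = mossy, climbing = climbing, targets = targets,
         n_samples = n, seed = as.integer(seed), isi = 0,
         sample_dt = tr$sample_dt),
    class = "training_set"
  )
}

#' Shift the climbing-fiber stream relative to the mossy stream
#'
#' Delays the climbing stream (and with it the targets, which always follow
#' the climbing pattern) by `round(isi_seconds / sample_dt)` samples, using a
#' cyclic shift so the set length is preserved. Used for the
#' inter-stimulus-interval sweep.
#'
#' @param set A `training_set`.
#' @param isi_seconds Inter-stimulus interval in seconds; non-negative, up
#'   to one full period of the set (a full-period shift is the identity).
#'   The conditioning sweep itself uses intervals in `[0, 3]` s.
#' @return The shifted `training_set`.
#' @export
shift_stimuli <- function(set, isi_seconds) {
  stopifnot(inherits(set, "training_set"))
  if (!is.finite(isi_seconds) || isi_seconds < 0 ||
      isi_seconds > set$n_samples * set$sample_dt) {
    stop("parameter error: isi_seconds must be in [0, one full period]")
  }
  s <- as.integer(round(isi_seconds / set$sample_dt)) %% set$n_samples
  if (s == 0L) {
    set$isi <- isi_seconds
    return(set)
  }
  n <- set$n_samples
  idx <- ((seq_len(n) - 1L - s) %% n) + 1L
  set$climbing <- set$climbing[idx, , drop = FALSE]
  set$targets <- derive_targets(set$climbing)
  set$isi <- isi_seconds
  set
}

#' Read / write a training set as CSV
#'
#' Columns `MF_1..MF_k`, `CF_1..CF_3`, `DN_1`, `DN_2`; one sample per row.
#'
#' @param set A `training_set`.
#' @param path File path.
#' @param sample_dt Sampling interval to attach when reading.
#' @return `write_training_set()` returns `path` invisibly;
#'   `read_training_set()` returns a `training_set`.
#' @export
write_training_set <- function(set, path) {
  stopifnot(inherits(set, "training_set"))
  df <- cbind(as.data.frame(set$mossy), as.data.frame(set$climbing),
              as.data.frame(set$targets))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path, sample_dt = 0.25) {
  df <- utils::read.csv(path)
  mf <- as.matrix(df[grepl("^MF_", names(df))])
  cf <- as.matrix(df[grepl("^CF_", names(df))])
  dn <- as.matrix(df[grepl("^DN_", names(df))])
  structure(
    list(mossy = mf, climbing = cf, targets = dn, n_samples = nrow(df),
         seed = NA_integer_, isi = 0, sample_dt = sample_dt),
    class = "training_set"
  )
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("Training set: %d samples, %d mossy + %d climbing inputs, %d targets (isi = %gs)\n",
              x$n_samples, ncol(x$mossy), ncol(x$climbing), ncol(x$targets),
              x$isi))
  invisible(x)
}
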