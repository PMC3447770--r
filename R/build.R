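#' Build a microzone network from a configuration
#'
#' Instantiates layers and weight matrices. Connectivity is all-to-all within
#' each connection spec, except subgroup-aligned connections (climbing fibers
#' to Purkinje cells), where Purkinje subgroup g receives input only from
#' climbing fiber g. Initial weights are uniform in `[0.25, 0.75]`, seeded
#' per projection so a rebuild with the same seed is bit-identical.
#' Inhibitory projections keep their stored weights in `[0, 1]` and
#' contribute with negative sign at net-input time.
#'
#' @param config A [microzone_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `microzone_network`: layers (with lesion masks
#'   and trainable biases) and projections (with weight matrices).
#' @examples
#' net <- build_microzone(default_config(), seed = 1)
#' @export
build_microzone <- function(config, seed = 1L) {
  stopifnot(inherits(config, "microzone_config"))
  validate_config(config)
  layers <- list()
  for (g in config$groups) {
    layers[[g$name]] <- list(
      name = g$name, n = g$count, role = g$role, k = group_k(g),
      subgroups = g$subgroups,
      # expected activity level, used to normalize projection net input
      act_avg = g$act_avg %||%
        if (g$role == "hidden" || g$role == "output") {
          min(1, group_k(g) / g$count)
        } else 0.5,
      bias = numeric(g$count),
      lesioned = logical(g$count)
    )
  }
  projections <- vector("list", length(config$connections))
  for (i in seq_along(config$connections)) {
    cn <- config$connections[[i]]
    n_src <- layers[[cn$src]]$n
    n_dst <- layers[[cn$dst]]$n
    W <- with_seed(derive_seed(seed, 101L, i),
                   matrix(stats::runif(n_src * n_dst, 0.25, 0.75),
                          n_src, n_dst))
    mask <- NULL
    if (cn$aligned) {
      sg_src <- config$groups[[match(cn$src, vapply(config$groups, `[[`, "",
                                                    "name"))]]$subgroups
      sg_dst <- layers[[cn$dst]]$subgroups
      nb <- max(sg_dst, n_src)  # one source unit per target subgroup
      mask <- matrix(0, n_src, n_dst)
      block <- n_dst / nb
      for (b in seq_len(min(n_src, nb))) {
        cols <- seq.int((b - 1) * block + 1, b * block)
        mask[b, cols] <- 1
      }
      W <- W * mask
    }
    projections[[i]] <- list(
      src = cn$src, dst = cn$dst,
      sign = if (cn$sign == "inhibitory") -1 else 1,
      strength = cn$strength, plastic = cn$plastic,
      W = W, mask = mask
    )
  }
  structure(
    list(config = config, layers = layers, projections = projections,
         seed = as.integer(seed)),
    class = "microzone_network"
  )
}

# Projection indices grouped by target layer, computed on demand.
proj_by_dst <- function(net) {
  split(seq_along(net$projections),
        vapply(net$projections, `[[`, "", "dst"))
}

#' @export
print.microzone_network <- function(x, ...) {
  n_w <- sum(vapply(x$projections, function(p) length(p$W), 0))
  les <- vapply(x$layers, function(l) sum(l$lesioned), 0)
  cat(sprintf("Microzone network: %d layers, %d projections, %d weights\n",
              length(x$layers), length(x$projections), n_w))
  if (any(les > 0)) {
    cat("  lesioned:",
        paste(sprintf("%s=%d", names(les)[les > 0], les[les > 0]),
              collapse = ", "), "\n")
  }
  invisible(x)
}
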