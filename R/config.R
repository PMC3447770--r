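#' Declarative microzone configuration
#'
#' Describes cell groups (name, count, role, optional kWTA `k`, optional
#' subgroup count), connections (source, target, sign, relative strength,
#' subgroup alignment), neuron dynamics, and learning parameters. Use
#' [default_config()] for the canonical cerebellar microzone.
#'
#' @param groups A list of group specs; each a list with `name`, `count`,
#'   `role` (`"input"`, `"hidden"` or `"output"`), and optionally `k`
#'   (kWTA winners; derived from layer size when `NULL`) and `subgroups`.
#' @param connections A list of connection specs; each a list with `src`,
#'   `dst`, `sign` (`"excitatory"` or `"inhibitory"`), `strength` (positive),
#'   and optionally `aligned` (subgroup-aligned connectivity) and `plastic`.
#' @param dynamics A [dynamics_params()] object.
#' @param channels A [leabra_channels()] object.
#' @param learning List with `epsilon` (base learning rate), `lambda`
#'   (Hebbian/error-driven mix; the net delta is
#'   `lambda * Hebbian + (1 - lambda) * error-driven`), `eps_cap` (cap on the
#'   strength-derived learning-rate multiplier), `bias_max`, and
#'   `cpca_correction`.
#' @param training List with `n_samples`, `slow_change_bound`, `sample_dt`
#'   (seconds per training sample), `code` (`"gray"` or `"binary"` climbing
#'   sequence), `max_epochs`, `criterion` (stop when error percent falls
#'   below it), `shuffle`.
#' @param include_nuclear_collaterals Logical; kept for provenance (the
#'   canonical config adds mossy- and climbing-fiber collaterals onto the
#'   deep nuclei when TRUE).
#' @return An object of class `microzone_config`.
#' @seealso [default_config()], [scale_group()], [build_microzone()]
#' @export
microzone_config <- function(groups, connections,
                             dynamics = dynamics_params(),
                             channels = leabra_channels(),
                             learning = list(),
                             training = list(),
                             include_nuclear_collaterals = TRUE) {
  learning <- utils::modifyList(
    list(epsilon = 0.8, lambda = 0, eps_cap = 4,
         bias_max = 5, cpca_correction = 1),
    learning
  )
  training <- utils::modifyList(
    list(n_samples = 140L, slow_change_bound = 0.15, sample_dt = 0.25,
         code = "gray", max_epochs = 2000L, criterion = 5e-7,
         shuffle = FALSE),
    training
  )
  groups <- lapply(groups, function(g) {
    g$count <- as.integer(g$count)
    g$subgroups <- as.integer(g$subgroups %||% 1L)
    g$role <- match.arg(g$role, c("input", "hidden", "output"))
    g
  })
  connections <- lapply(connections, function(cn) {
    cn$sign <- match.arg(cn$sign, c("excitatory", "inhibitory"))
    cn$strength <- cn$strength %||% 1
    cn$aligned <- isTRUE(cn$aligned)
    cn$plastic <- cn$plastic %||% TRUE
    cn
  })
  cfg <- structure(
    list(groups = groups, connections = connections, dynamics = dynamics,
         channels = channels, learning = learning, training = training,
         include_nuclear_collaterals = include_nuclear_collaterals),
    class = "microzone_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  nms <- vapply(cfg$groups, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("config error: duplicated group names")
  counts <- vapply(cfg$groups, `[[`, 1L, "count")
  if (any(counts < 1L)) stop("config error: group counts must be >= 1")
  roles <- vapply(cfg$groups, `[[`, "", "role")
  names(roles) <- nms
  for (cn in cfg$connections) {
    if (!(cn$src %in% nms) || !(cn$dst %in% nms)) {
      stop(sprintf("config error: dangling group reference in %s->%s",
                   cn$src, cn$dst))
    }
    if (cn$src == cn$dst) stop("config error: self-projections not allowed")
    if (roles[[cn$dst]] == "input") {
      stop(sprintf("config error: input group '%s' cannot receive projections",
                   cn$dst))
    }
    if (cn$strength <= 0) stop("config error: connection strength must be > 0")
  }
  invisible(cfg)
}

# Default kWTA winner count: 10% of the layer, granule cells 5% (sparse
# expansion code); at least 1.
derive_k <- function(name, count) {
  frac <- if (identical(name, "granule")) 0.05 else 0.10
  max(1L, as.integer(round(frac * count)))
}

group_k <- function(g) {
  if (!is.null(g$k)) as.integer(g$k) else derive_k(g$name, g$count)
}

#' Canonical cerebellar microzone configuration
#'
#' Cell counts: mossy fibers 24, climbing fibers 3, granule cells 3300, Golgi
#' cells 300, basket cells 130, Purkinje cells 15 (three subgroups of 5),
#' deep cerebellar neurons 2. Wiring: MF->GrC (excitatory, 4x strength),
#' GrC->GoC, GoC->GrC (inhibitory), GrC->BC, GrC->PC, BC->PC (inhibitory),
#' CF->PC (excitatory, 26000x strength, subgroup-aligned), PC->DCN
#' (inhibitory), plus excitatory nuclear collaterals MF->DCN and CF->DCN
#' (flag-controlled, default on). Three kWTA overrides relative to the
#' generic 10%/5% rule: Purkinje cells are exempt from competition (k = 15)
#' so each subgroup can relay its private climbing-fiber signal; basket
#' cells run at k = 65 (tonically active interneurons — at 10% activity
#' their pooled inhibition cannot gate Purkinje cells); and the two deep
#' nuclei are read out independently (k = 2). Rationale in the methods
#' vignette.
#'
#' @param include_nuclear_collaterals Include MF->DCN and CF->DCN excitatory
#'   collaterals (default TRUE). Without them the deep nuclei rely on their
#'   trainable bias for excitatory drive.
#' @param ... Overrides passed to [microzone_config()] (`dynamics`,
#'   `learning`, `training`, ...).
#' @return A `microzone_config`.
#' @examples
#' cfg <- default_config()
#' vapply(cfg$groups, `[[`, 1L, "count")
#' @export
default_config <- function(include_nuclear_collaterals = TRUE, ...) {
  groups <- list(
    list(name = "mossy_fibers", count = 24L, role = "input"),
    list(name = "climbing_fibers", count = 3L, role = "input"),
    list(name = "granule", count = 3300L, role = "hidden"),
    list(name = "golgi", count = 300L, role = "hidden"),
    list(name = "basket", count = 130L, role = "hidden", k = 65L),
    list(name = "purkinje", count = 15L, role = "hidden", k = 15L,
         subgroups = 3L),
    list(name = "deep_nuclei", count = 2L, role = "output", k = 2L)
  )
  connections <- list(
    list(src = "mossy_fibers", dst = "granule", sign = "excitatory",
         strength = 4),
    list(src = "granule", dst = "golgi", sign = "excitatory", strength = 1),
    list(src = "golgi", dst = "granule", sign = "inhibitory", strength = 1),
    list(src = "granule", dst = "basket", sign = "excitatory", strength = 1),
    list(src = "granule", dst = "purkinje", sign = "excitatory",
         strength = 1),
    list(src = "basket", dst = "purkinje", sign = "inhibitory",
         strength = 1),
    list(src = "climbing_fibers", dst = "purkinje", sign = "excitatory",
         strength = 26000, aligned = TRUE),
    list(src = "purkinje", dst = "deep_nuclei", sign = "inhibitory",
         strength = 1)
  )
  if (include_nuclear_collaterals) {
    connections <- c(connections, list(
      list(src = "mossy_fibers", dst = "deep_nuclei", sign = "excitatory",
           strength = 1),
      list(src = "climbing_fibers", dst = "deep_nuclei", sign = "excitatory",
           strength = 1)
    ))
  }
  microzone_config(groups, connections,
                   include_nuclear_collaterals = include_nuclear_collaterals,
                   ...)
}

#' Scale a cell group's size
#'
#' Returns a new configuration with the group's cell count multiplied by
#' `factor` (rounded to the nearest integer); wiring is preserved and the
#' kWTA winner count is re-derived from the new size.
#'
#' @param config A `microzone_config`.
#' @param group Group name.
#' @param factor Positive scale factor; the resulting count must be >= 1.
#' @return The scaled `microzone_config`.
#' @examples
#' cfg <- scale_group(default_config(), "granule", 0.1)
#' @export
scale_group <- function(config, group, factor) {
  stopifnot(inherits(config, "microzone_config"))
  idx <- match(group, vapply(config$groups, `[[`, "", "name"))
  if (is.na(idx)) stop(sprintf("invalid-scale error: unknown group '%s'", group))
  if (!is.finite(factor) || factor <= 0) {
    stop("invalid-scale error: factor must be > 0")
  }
  g <- config$groups[[idx]]
  new_count <- as.integer(round(g$count * factor))
  if (new_count < 1L) {
    stop("invalid-scale error: resulting group count would be < 1")
  }
  g$count <- new_count
  if (!is.null(g$k)) g$k <- max(1L, as.integer(round(g$k * factor)))
  config$groups[[idx]] <- g
  validate_config(config)
  config
}

#' Read / write a microzone configuration file
#'
#' Configurations are stored as YAML (JSON, being a YAML subset, also reads).
#' The packaged default, `system.file("extdata", "default_config.yaml",
#' package = "microzone")`, reproduces the canonical cell counts.
#'
#' @param path File path.
#' @param config A `microzone_config`.
#' @return `read_config()` returns a `microzone_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dyn <- do.call(dynamics_params, raw$dynamics %||% list())
  ch <- do.call(leabra_channels, raw$channels %||% list())
  microzone_config(
    groups = raw$groups, connections = raw$connections,
    dynamics = dyn, channels = ch,
    learning = raw$learning %||% list(),
    training = raw$training %||% list(),
    include_nuclear_collaterals = raw$include_nuclear_collaterals %||% TRUE
  )
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "microzone_config"))
  ch <- config$channels
  out <- list(
    groups = config$groups,
    connections = config$connections,
    dynamics = unclass(config$dynamics),
    channels = list(E_excit = ch$E[["excit"]], E_leak = ch$E[["leak"]],
                    E_inhib = ch$E[["inhib"]],
                    gbar_excit = ch$gbar[["excit"]],
                    gbar_leak = ch$gbar[["leak"]],
                    gbar_inhib = ch$gbar[["inhib"]]),
    learning = config$learning,
    training = config$training,
    include_nuclear_collaterals = config$include_nuclear_collaterals
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

# Stable hash of a configuration for run manifests.
config_hash <- function(config) {
  js <- jsonlite::serializeJSON(unclass(config))
  # small rolling hash; avoids external digest dependencies
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.microzone_config <- function(x, ...) {
  cat("Microzone configuration\n")
  for (g in x$groups) {
    cat(sprintf("  %-16s n=%5d  role=%-6s k=%d%s\n", g$name, g$count, g$role,
                group_k(g),
                if (g$subgroups > 1L) sprintf(" subgroups=%d", g$subgroups)
                else ""))
  }
  for (cn in x$connections) {
    cat(sprintf("  %s -> %s (%s, s=%g%s)\n", cn$src, cn$dst, cn$sign,
                cn$strength, if (cn$aligned) ", aligned" else ""))
  }
  invisible(x)
}
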