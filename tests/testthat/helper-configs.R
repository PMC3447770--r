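# Shared fixtures: a miniature microzone with the canonical wiring pattern,
# built entirely in code. Training-dependent tests reuse one cached fit.

tiny_config <- function(n_samples = 40L, ...) {
  microzone_config(
    groups = list(
      list(name = "mossy_fibers", count = 8L, role = "input"),
      list(name = "climbing_fibers", count = 3L, role = "input"),
      list(name = "granule", count = 40L, role = "hidden"),
      list(name = "golgi", count = 8L, role = "hidden"),
      list(name = "basket", count = 6L, role = "hidden", k = 3L),
      list(name = "purkinje", count = 6L, role = "hidden", k = 6L,
           subgroups = 3L),
      list(name = "deep_nuclei", count = 2L, role = "output", k = 2L)
    ),
    connections = list(
      list(src = "mossy_fibers", dst = "granule", sign = "excitatory",
           strength = 4),
      list(src = "granule", dst = "golgi", sign = "excitatory"),
      list(src = "golgi", dst = "granule", sign = "inhibitory"),
      list(src = "granule", dst = "basket", sign = "excitatory"),
      list(src = "granule", dst = "purkinje", sign = "excitatory"),
      list(src = "basket", dst = "purkinje", sign = "inhibitory"),
      list(src = "climbing_fibers", dst = "purkinje", sign = "excitatory",
           strength = 26000, aligned = TRUE),
      list(src = "purkinje", dst = "deep_nuclei", sign = "inhibitory"),
      list(src = "mossy_fibers", dst = "deep_nuclei", sign = "excitatory"),
      list(src = "climbing_fibers", dst = "deep_nuclei", sign = "excitatory")
    ),
    training = list(n_samples = n_samples),
    ...
  )
}

# a small two-layer recurrent network for settling tests
toy_recurrent_config <- function(k1 = 2L, k2 = 2L) {
  microzone_config(
    groups = list(
      list(name = "inp", count = 2L, role = "input"),
      list(name = "a", count = 2L, role = "hidden", k = k1),
      list(name = "b", count = 2L, role = "output", k = k2)
    ),
    connections = list(
      list(src = "inp", dst = "a", sign = "excitatory"),
      list(src = "a", dst = "b", sign = "excitatory"),
      list(src = "b", dst = "a", sign = "excitatory")
    )
  )
}

# one converged tiny fit, computed once per test run
cached_tiny_fit <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- fit_microzone(tiny_config(), seed = 1, max_epochs = 200)
    }
    val
  }
})
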