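test_that("canonical configuration reproduces the reference cell counts", {
  cfg <- default_config()
  counts <- vapply(cfg$groups, `[[`, 1L, "count")
  names(counts) <- vapply(cfg$groups, `[[`, "", "name")
  expect_identical(counts,
                   c(mossy_fibers = 24L, climbing_fibers = 3L,
                     granule = 3300L, golgi = 300L, basket = 130L,
                     purkinje = 15L, deep_nuclei = 2L))
})

test_that("connection strengths keep the reference ratios", {
  cfg <- default_config()
  s <- vapply(cfg$connections, `[[`, 0, "strength")
  names(s) <- vapply(cfg$connections, function(cn) paste0(cn$src, "->", cn$dst), "")
  expect_identical(unname(s[["climbing_fibers->purkinje"]] /
                            s[["granule->purkinje"]]), 26000)
  expect_identical(unname(s[["mossy_fibers->granule"]] /
                            s[["granule->purkinje"]]), 4)
})

test_that("inhibitory connections are exactly GoC->GrC, BC->PC, PC->DCN", {
  cfg <- default_config()
  inhib <- Filter(function(cn) cn$sign == "inhibitory", cfg$connections)
  pairs <- sort(vapply(inhib, function(cn) paste0(cn$src, "->", cn$dst), ""))
  expect_identical(pairs, sort(c("golgi->granule", "basket->purkinje",
                                 "purkinje->deep_nuclei")))
})

test_that("effective net-input scaling preserves the strength ratios", {
  net <- build_microzone(default_config(), seed = 1)
  eff <- vapply(net$projections, function(p) {
    s <- net$layers[[p$src]]
    (p$strength / (s$n * s$act_avg)) * (s$n * s$act_avg)
  }, 0)
  names(eff) <- vapply(net$projections, function(p) paste0(p$src, "->", p$dst), "")
  expect_equal(unname(eff[["climbing_fibers->purkinje"]] /
                        eff[["granule->purkinje"]]), 26000)
  expect_equal(unname(eff[["mossy_fibers->granule"]] /
                        eff[["granule->purkinje"]]), 4)
})

test_that("climbing->Purkinje connectivity is block-diagonal by subgroup", {
  net <- build_microzone(default_config(), seed = 2)
  cfpc <- NULL
  for (p in net$projections) {
    if (p$src == "climbing_fibers" && p$dst == "purkinje") cfpc <- p
  }
  expect_identical(dim(cfpc$W), c(3L, 15L))
  for (g in 1:3) {
    cols <- ((g - 1) * 5 + 1):(g * 5)
    expect_true(all(cfpc$W[g, cols] > 0))
    expect_true(all(cfpc$W[-g, cols] == 0))
  }
})

test_that("projections are all-to-all with weights in the initial range", {
  net <- build_microzone(default_config(), seed = 3)
  for (p in net$projections) {
    if (p$src == "golgi" && p$dst == "granule") {
      expect_identical(length(p$W), 300L * 3300L)
    }
    if (is.null(p$mask)) {
      expect_true(all(p$W >= 0.25 & p$W <= 0.75))
    }
  }
})

test_that("builds are deterministic in the seed", {
  cfg <- tiny_config()
  expect_identical(build_microzone(cfg, seed = 7),
                   build_microzone(cfg, seed = 7))
  a <- build_microzone(cfg, seed = 7)
  b <- build_microzone(cfg, seed = 8)
  expect_false(identical(a$projections[[1]]$W, b$projections[[1]]$W))
})

test_that("config validation rejects malformed wiring", {
  groups <- list(
    list(name = "x", count = 2L, role = "input"),
    list(name = "y", count = 2L, role = "output")
  )
  expect_error(
    microzone_config(groups, list(list(src = "x", dst = "z",
                                       sign = "excitatory"))),
    "dangling")
  expect_error(
    microzone_config(groups, list(list(src = "y", dst = "y",
                                       sign = "excitatory"))),
    "self-projections")
  expect_error(
    microzone_config(groups, list(list(src = "y", dst = "x",
                                       sign = "excitatory"))),
    "input group")
})

test_that("scale_group rescales counts and winner numbers", {
  cfg <- default_config()
  small <- scale_group(cfg, "granule", 0.1)
  nms <- vapply(small$groups, `[[`, "", "name")
  expect_identical(small$groups[[match("granule", nms)]]$count, 330L)
  # identity scaling leaves the config unchanged
  expect_identical(scale_group(cfg, "granule", 1), cfg)
  expect_error(scale_group(cfg, "granule", 1e-4), "invalid-scale")
  expect_error(scale_group(cfg, "granule", -1), "invalid-scale")
  expect_error(scale_group(cfg, "nonesuch", 0.5), "invalid-scale")
  # k is re-derived from the new size at build time
  net <- build_microzone(small, seed = 1)
  expect_identical(net$layers$granule$k, 16L)
})

test_that("the packaged default config file reproduces the counts", {
  path <- system.file("extdata", "default_config.yaml", package = "microzone")
  expect_true(nzchar(path))
  cfg <- read_config(path)
  expect_identical(vapply(cfg$groups, `[[`, 1L, "count"),
                   c(24L, 3L, 3300L, 300L, 130L, 15L, 2L))
  ref <- default_config()
  expect_equal(cfg$connections, ref$connections)
  expect_equal(cfg$learning, ref$learning)
  expect_equal(unclass(cfg$dynamics), unclass(ref$dynamics))
})
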