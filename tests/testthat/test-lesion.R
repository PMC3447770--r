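test_that("removing zero cells leaves the association error unchanged", {
  fit <- cached_tiny_fit()
  e0 <- epoch_error(fit$network, fit$set)
  net <- remove_cells(fit$network, "granule", 0, seed = 1)
  expect_identical(epoch_error(net, fit$set), e0)
})

test_that("lesioning a unit is equivalent to zeroing its weight rows", {
  # toy oracle: mark unit dead vs. zero its incoming and outgoing weights
  cfg <- tiny_config(n_samples = 12L)
  net <- build_microzone(cfg, seed = 9)
  set <- generate_training_set(cfg, seed = 9)
  lesioned <- net
  lesioned$layers$granule$lesioned[7] <- TRUE
  zeroed <- net
  for (i in seq_along(zeroed$projections)) {
    p <- zeroed$projections[[i]]
    if (p$src == "granule") zeroed$projections[[i]]$W[7, ] <- 0
    if (p$dst == "granule") zeroed$projections[[i]]$W[, 7] <- 0
  }
  # granule kWTA ignores the dead unit; align the comparison by keeping the
  # zero-weight unit out of the winner count in the zeroed variant too
  expect_equal(epoch_error(lesioned, set), epoch_error(zeroed, set),
               tolerance = 1e-9)
})

test_that("removing a full group silences its downstream drive", {
  fit <- cached_tiny_fit()
  net <- remove_cells(fit$network, "purkinje", 6, seed = 2)
  res <- microzone:::settle_batch(net, microzone:::set_inputs(net, fit$set))
  expect_true(all(res$act$purkinje == 0))
  ni <- microzone:::layer_net_input(net, "deep_nuclei", res$act,
                                    fit$set$n_samples)
  expect_true(all(ni$gi == 0))  # PC->DCN is the only inhibitory input
})

test_that("removal draws without replacement and respects bounds", {
  fit <- cached_tiny_fit()
  net <- remove_cells(fit$network, "granule", 10, seed = 3)
  expect_identical(sum(net$layers$granule$lesioned), 10L)
  net2 <- remove_cells(net, "granule", 30, seed = 4)
  expect_identical(sum(net2$layers$granule$lesioned), 40L)
  expect_error(remove_cells(net2, "granule", 1, seed = 5), "lesion error")
  expect_error(remove_cells(fit$network, "nonesuch", 1), "lesion error")
})

test_that("schedules follow the per-type removal rules", {
  cfg <- default_config()
  gr <- build_schedule("granule", cfg)
  expect_identical(gr$counts, as.integer(33 * (1:30)))
  expect_identical(gr$counts[30], 990L)
  go <- build_schedule("golgi", cfg)
  expect_identical(go$counts, as.integer(3 * (1:30)))
  pc <- build_schedule("purkinje", cfg)
  expect_identical(pc$counts, 1:5)
  mf <- build_schedule("mossy_fibers", cfg)
  expect_identical(mf$counts, 1:8)
  cf <- build_schedule("climbing_fibers", cfg)
  expect_identical(cf$counts, 1L)
  # percentage reading: 30% of 130 basket cells
  bk <- build_schedule("basket", cfg)
  expect_identical(bk$counts[length(bk$counts)], 39L)
  # printed-count reading ends at 29
  bk2 <- build_schedule("basket", cfg, mode = "table")
  expect_identical(bk2$counts[length(bk2$counts)], 29L)
  expect_true(all(diff(bk2$counts) > 0))
  expect_error(build_schedule("nonesuch", cfg), "schedule error")
})

test_that("scaled granule layer keeps the 1%-step schedule", {
  cfg <- scale_group(default_config(), "granule", 0.1)
  sch <- build_schedule("granule", cfg, mode = "table")
  expect_identical(sch$counts[length(sch$counts)], 99L)
})

test_that("degradation curves are deterministic and anchored at zero", {
  fit <- cached_tiny_fit()
  cfg <- tiny_config()
  fits <- list(fit, fit)
  cv1 <- run_degradation(cfg, "purkinje", n_trials = 2, base_seed = 21,
                         fits = fits)
  cv2 <- run_degradation(cfg, "purkinje", n_trials = 2, base_seed = 21,
                         fits = fits)
  expect_identical(cv1$errors, cv2$errors)
  expect_identical(cv1$fractions[1], 0)
  expect_lt(max(cv1$errors[, 1]), 5e-7)   # trained to criterion at step 0
  expect_identical(cv1$mean_error, colMeans(cv1$errors))
  # a different removal seed gives a different curve tail
  cv3 <- run_degradation(cfg, "purkinje", n_trials = 2, base_seed = 99,
                         fits = fits)
  expect_false(identical(cv1$errors[, -1], cv3$errors[, -1]))
  # damage never helps: the trial-mean error at maximal removal is at
  # least the error of the intact trained network
  expect_gte(cv1$mean_error[length(cv1$mean_error)], cv1$mean_error[1])
})

test_that("non-convergent trials are excluded from the mean", {
  cfg <- tiny_config(learning = list(epsilon = 0))
  cfg$training$max_epochs <- 2L
  cv <- run_degradation(cfg, "purkinje", n_trials = 2, base_seed = 1,
                        final_only = TRUE)
  expect_identical(cv$n_excluded, 2L)
  expect_true(all(is.na(cv$errors)))
})

test_that("random degeneration pools the intrinsic cell groups", {
  cfg <- default_config()
  nms <- vapply(cfg$groups, `[[`, "", "name")
  counts <- vapply(cfg$groups, `[[`, 1L, "count")
  names(counts) <- nms
  pool <- counts[c("granule", "golgi", "basket", "purkinje")]
  expect_identical(sum(pool), 3745L)
  expect_equal(unname(pool[["granule"]] / sum(pool)), 0.881, tolerance = 1e-3)
})

test_that("pooled removal hits groups in proportion to their size", {
  net <- build_microzone(default_config(), seed = 13)
  draws <- c(granule = 0L, golgi = 0L, basket = 0L, purkinje = 0L)
  for (rep in 1:20) {   # 20 independent draws of 500 cells from a fresh pool
    res <- microzone:::remove_cells_pooled(
      net, c("granule", "golgi", "basket", "purkinje"), 500, seed = 77 + rep)
    draws <- draws + res$removed
  }
  expect_identical(sum(draws), 10000L)
  expected <- 10000 * c(3300, 300, 130, 15) / 3745
  chi <- sum((draws - expected)^2 / expected)
  # 3 degrees of freedom at alpha = 0.01
  expect_lt(chi, stats::qchisq(0.99, df = 3))
  # excluded groups are never touched
  expect_identical(sum(res$network$layers$mossy_fibers$lesioned), 0L)
  expect_identical(sum(res$network$layers$climbing_fibers$lesioned), 0L)
  expect_identical(sum(res$network$layers$deep_nuclei$lesioned), 0L)
})

test_that("pool accounting: per-group removals sum to the pooled count", {
  fit <- cached_tiny_fit()
  cfg <- tiny_config()
  cv <- run_random_degeneration(cfg, n_trials = 1, base_seed = 5,
                                fits = list(fit))
  rem <- cv$removed_by_group[[1]]
  expect_identical(as.integer(rowSums(rem)), diff(cv$counts))
  expect_true(all(c("granule", "golgi", "basket", "purkinje")
                  %in% colnames(rem)))
})

test_that("degradation curves write valid CSV output", {
  fit <- cached_tiny_fit()
  cv <- run_degradation(tiny_config(), "basket", n_trials = 1,
                        base_seed = 2, fits = list(fit))
  path <- withr::local_tempfile(fileext = ".csv")
  means <- withr::local_tempfile(fileext = ".csv")
  write_degradation_curve(cv, path, means)
  df <- read.csv(path)
  expect_identical(names(df),
                   c("group", "fraction_removed", "trial", "error_pct"))
  mdf <- read.csv(means)
  expect_equal(mdf$mean_error_pct, unname(cv$mean_error))
})
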