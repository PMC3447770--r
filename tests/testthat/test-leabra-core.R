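test_that("membrane potential stays put with no driving current", {
  ch <- leabra_channels()
  dp <- dynamics_params()
  u <- list(v_m = 0.42, g = c(excit = 0, inhib = 0, leak = 0))
  expect_identical(step_membrane(u, ch, dp)$v_m, 0.42)
})

test_that("membrane potential at a channel's reversal is a fixed point", {
  ch <- leabra_channels(gbar_leak = 0)
  dp <- dynamics_params()
  u <- list(v_m = ch$E[["excit"]], g = c(excit = 2.5))
  expect_equal(step_membrane(u, ch, dp)$v_m, ch$E[["excit"]],
               tolerance = 1e-12)
  # conductance-weighted mixture fixed point with several channels
  ch2 <- leabra_channels()
  g <- c(excit = 0.7, inhib = 0.4, leak = 1)
  gg <- g * ch2$gbar[names(g)]
  v_star <- sum(gg * ch2$E[names(g)]) / sum(gg)
  u2 <- list(v_m = v_star, g = g)
  expect_equal(step_membrane(u2, ch2, dp)$v_m, v_star, tolerance = 1e-12)
})

test_that("single-channel trajectory matches the closed-form relaxation", {
  # one constant excitatory channel, no leak: the update is linear, so
  # V_t = E + (V_0 - E) * (1 - tau*g*gbar)^t
  ch <- leabra_channels(gbar_leak = 0, gbar_excit = 0.8)
  dp <- dynamics_params(tau = 0.15)
  g_e <- 1.7
  v0 <- 0.3
  u <- list(v_m = v0, g = c(excit = g_e))
  rate <- dp$tau * g_e * ch$gbar[["excit"]]
  stopifnot(rate < 1)
  for (t in 1:40) {
    u <- step_membrane(u, ch, dp)
    expected <- ch$E[["excit"]] + (v0 - ch$E[["excit"]]) * (1 - rate)^t
    expect_equal(u$v_m, expected, tolerance = 1e-9)
  }
})

test_that("membrane potential is bounded by the reversal potentials", {
  ch <- leabra_channels()
  dp <- dynamics_params(tau = 0.9)   # deliberately large steps
  set.seed(11)
  for (rep in 1:20) {
    u <- list(v_m = runif(1, 0.15, 1),
              g = c(excit = runif(1, 0, 50), inhib = runif(1, 0, 50),
                    leak = runif(1, 0, 5)))
    for (s in 1:30) {
      u$g <- abs(u$g + rnorm(3, sd = 5))
      u <- step_membrane(u, ch, dp)
      expect_gte(u$v_m, min(ch$E))
      expect_lte(u$v_m, max(ch$E))
    }
  }
})

test_that("step_membrane rejects non-finite state", {
  ch <- leabra_channels()
  dp <- dynamics_params()
  expect_error(step_membrane(list(v_m = NaN, g = c(excit = 1)), ch, dp),
               "non-finite")
  expect_error(step_membrane(list(v_m = 0.5, g = c(excit = Inf)), ch, dp),
               "non-finite")
})

test_that("rate activation is zero below threshold, monotone, saturating", {
  dp <- dynamics_params(gain = 100, threshold = 0.5)
  expect_identical(rate_activation(0.1, dp), 0)
  expect_identical(rate_activation(0.5, dp), 0)
  v <- seq(0, 1, by = 0.01)
  y <- rate_activation(v, dp)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0 & y <= 1))
  # large gain saturates slightly above threshold
  dp2 <- dynamics_params(gain = 1e6, threshold = 0.5)
  expect_equal(rate_activation(0.51, dp2), 1)
})

test_that("kWTA allows exactly the top-k units at settling equilibrium", {
  ch <- leabra_channels()
  dp <- dynamics_params()
  # brute-force oracle: the top-k units by drive are the ones whose
  # threshold conductance exceeds the layer inhibition
  equilibrium_active <- function(g_e, g_i) {
    G <- g_e * ch$gbar[["excit"]] + ch$gbar[["leak"]] + g_i * ch$gbar[["inhib"]]
    v <- (g_e * ch$gbar[["excit"]] * ch$E[["excit"]] +
            ch$gbar[["leak"]] * ch$E[["leak"]] +
            g_i * ch$gbar[["inhib"]] * ch$E[["inhib"]]) / G
    v > dp$threshold
  }
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    k <- sample(0:n, 1)
    g_e <- runif(n, 0, 3)
    layer <- apply_kwta(list(g_e = g_e, k = k), ch, dp)
    active <- equilibrium_active(g_e, layer$g_i)
    if (k == 0) {
      expect_false(any(active))
    } else if (k >= n) {
      expect_identical(layer$g_i, 0)
    } else {
      # kWTA only adds inhibition: the active set is the top-k units by
      # drive, minus any that are subthreshold even without inhibition
      oracle_top <- order(g_e, decreasing = TRUE)[seq_len(k)]
      baseline <- equilibrium_active(g_e, 0)
      expect_setequal(which(active), intersect(oracle_top, which(baseline)))
      expect_lte(sum(active), k)
    }
  }
})

test_that("kWTA silences a layer at k = 0 and is inert at k >= n", {
  ch <- leabra_channels()
  dp <- dynamics_params()
  g_e <- c(3, 1, 2)
  silent <- apply_kwta(list(g_e = g_e, k = 0), ch, dp)
  gith <- microzone:::kwta_gi_theta(g_e, 0, ch, dp)
  expect_true(all(gith < silent$g_i))
  open <- apply_kwta(list(g_e = g_e, k = 3), ch, dp)
  expect_identical(open$g_i, 0)
})

test_that("kWTA with k = 1 activates only the maximally driven unit", {
  ch <- leabra_channels()
  dp <- dynamics_params()
  g_e <- c(0.4, 2.2, 1.1, 0.9)
  layer <- apply_kwta(list(g_e = g_e, k = 1), ch, dp)
  gith <- microzone:::kwta_gi_theta(g_e, 0, ch, dp)
  expect_true(sum(gith > layer$g_i) == 1)
  expect_identical(which.max(gith), 2L)
})

test_that("lesioned units are excluded from kWTA counting", {
  ch <- leabra_channels()
  dp <- dynamics_params()
  g_e <- c(5, 4, 3, 2)
  layer <- apply_kwta(list(g_e = g_e, k = 1,
                           lesioned = c(TRUE, FALSE, FALSE, FALSE)), ch, dp)
  gith <- microzone:::kwta_gi_theta(g_e, 0, ch, dp)
  # the lesioned strongest unit does not count; unit 2 is the winner
  expect_true(gith[2] > layer$g_i)
  expect_true(all(gith[3:4] < layer$g_i))
})

test_that("CPCA and GeneRec deltas evaluate per their formulas", {
  expect_equal(cpca_delta(1, 1, 0.25, 0.1), 0.075)
  expect_identical(cpca_delta(0.4, 0, 0.7, 0.5), 0)   # inactive receiver
  expect_identical(cpca_delta(0.6, 0.8, 0.6, 0.5), 0) # weight equals input
  expect_equal(generec_delta(0.2, 0.5, 0.8, 0.5, 0.1), 0.03)
  expect_identical(generec_delta(0.3, 0.7, 0.3, 0.7, 0.5), 0) # phases agree
  expect_lt(generec_delta(0.9, 0.9, 0.1, 0.1, 0.1), 0)  # sign contract
})

test_that("GeneRec delta is exactly antisymmetric under phase swap", {
  set.seed(3)
  for (i in 1:50) {
    x <- runif(4)
    expect_identical(generec_delta(x[1], x[2], x[3], x[4], 0.2),
                     -generec_delta(x[3], x[4], x[1], x[2], 0.2))
  }
})

test_that("settling respects clamps and produces silence without input", {
  cfg <- toy_recurrent_config()
  net <- build_microzone(cfg, seed = 5)
  net$layers$a$bias <- c(0, 0)
  net$layers$b$bias <- c(0, 0)
  out <- settle(net, clamped = list(inp = c(0, 0)), phase = "minus")
  expect_equal(out$layers$a$act, c(0, 0))
  expect_equal(out$layers$b$act, c(0, 0))
  # clamped layers hold their values exactly
  out2 <- settle(net, clamped = list(inp = c(0.3, 0.9), b = c(1, 0)),
                 phase = "plus")
  expect_identical(out2$layers$inp$act, c(0.3, 0.9))
  expect_identical(out2$layers$b$act, c(1, 0))
  expect_identical(out2$layers$b$y_plus, c(1, 0))
})

test_that("settling converges to the independent fixed-point solution", {
  # 2-layer toy network settled far beyond the default cycle count must
  # agree with a hand-rolled fixed-point iteration of the same dynamics
  cfg <- toy_recurrent_config(k1 = 2L, k2 = 2L)
  net <- build_microzone(cfg, seed = 8)
  inp <- c(0.9, 0.6)
  long <- dynamics_params(cycles = 800)
  out <- settle(net, clamped = list(inp = inp), phase = "minus",
                params = long)

  ch <- cfg$channels
  dp <- cfg$dynamics
  scale <- function(src) {
    l <- net$layers[[src]]
    1 / (l$n * l$act_avg)
  }
  W <- function(src, dst) {
    for (p in net$projections) if (p$src == src && p$dst == dst) return(p$W)
  }
  f_act <- function(v) {
    d <- v - dp$threshold
    ifelse(d <= 0, 0, 2 / (1 + exp(-dp$gain * pmax(d, 0))) - 1)
  }
  eq_v <- function(ge) {
    num <- ge * ch$gbar[["excit"]] * ch$E[["excit"]] +
      ch$gbar[["leak"]] * ch$E[["leak"]]
    num / (ge * ch$gbar[["excit"]] + ch$gbar[["leak"]])
  }
  ya <- c(0, 0); yb <- c(0, 0)
  for (i in 1:5000) {
    ge_a <- drop(scale("inp") * crossprod(W("inp", "a"), inp) +
                   scale("b") * crossprod(W("b", "a"), yb))
    ge_b <- drop(scale("a") * crossprod(W("a", "b"), ya))
    ya <- f_act(eq_v(ge_a))
    yb <- f_act(eq_v(ge_b))
  }
  expect_equal(out$layers$a$act, ya, tolerance = 1e-6)
  expect_equal(out$layers$b$act, yb, tolerance = 1e-6)
})

test_that("compiled settling engine matches the plain-R reference", {
  cfg <- tiny_config()
  net <- build_microzone(cfg, seed = 3)
  set <- generate_training_set(cfg, seed = 4)
  ins <- microzone:::set_inputs(net, set)
  a <- microzone:::settle_batch(net, ins)
  b <- microzone:::settle_batch_r(net, ins)
  for (nm in names(a$act)) {
    expect_equal(a$act[[nm]], b$act[[nm]], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})
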