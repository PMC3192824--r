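# Ratchet rule, well-tempered hill bookkeeping, bias evaluation and the
# free-energy estimator.

test_that("ratchet bias fires only on worsening and tracks the prefix minimum", {
  st <- ratchet_state(chi_init = 1, chi0 = 0, k = 10)
  # monotone improvement: never any energy
  for (chi in seq(1, 0.1, by = -0.1)) {
    r <- ratchet_bias(chi, st); st <- r$state
    expect_identical(r$energy, 0)
  }
  # hand case: best 0.2, chi - chi0 = 0.5, k = 10 -> 0.5 * 10 * 0.3^2
  st2 <- ratchet_state(chi_init = 0.2, chi0 = 0, k = 10)
  r2 <- ratchet_bias(0.5, st2)
  expect_equal(r2$energy, 0.45)
  expect_equal(r2$force_coefficient, 3)
  expect_equal(r2$state$running_best, 0.2)
  expect_error(ratchet_state(1, 0, k = -1), class = "actipath_config_error")
})

test_that("replayed chi series reproduces the brute-force prefix minimum", {
  set.seed(21)
  chi <- cumsum(rnorm(500, -0.002, 0.05)) + 2
  st <- ratchet_state(chi[1], chi0 = 0, k = 5)
  best_seen <- numeric(500)
  for (i in seq_along(chi)) {
    r <- ratchet_bias(chi[i], st); st <- r$state
    best_seen[i] <- st$running_best
  }
  expect_identical(best_seen, cummin(chi))
})

test_that("well-tempered hill heights follow the exponential rule and its limits", {
  cfg <- wt_config(w = 0.4, delta_T = 3000, temperature = 300, sigma = c(x = 0.1))
  expect_equal(wt_hill_height(0, cfg), 0.4)
  kBdT <- boltzmann_kcal() * 3000
  expect_equal(wt_hill_height(kBdT, cfg), 0.4 * exp(-1))
  expect_lt(wt_hill_height(1, cfg), wt_hill_height(0.5, cfg))
  inf_cfg <- wt_config(w = 0.4, delta_T = Inf, sigma = c(x = 0.1))
  expect_equal(wt_hill_height(5, inf_cfg), 0.4)
})

test_that("hill deposition composes the height rule with accumulated bias", {
  cfg <- wt_config(w = 0.4, delta_T = 3000, temperature = 300,
                   sigma = c(s = 0.1, z = 1))
  st <- bias_state(cfg)
  st <- deposit_hill(st, c(0.3, 0.5), time = 8)
  expect_equal(st$hills$height, 0.4)
  st <- deposit_hill(st, c(0.3, 0.5), time = 16)
  expect_equal(st$hills$height[2],
               0.4 * exp(-0.4 / (boltzmann_kcal() * 3000)))
  # mutually distant hills all get the full height
  st2 <- bias_state(cfg)
  for (i in 1:4) st2 <- deposit_hill(st2, c(i * 2, i * 20), time = 8 * i)
  expect_equal(st2$hills$height, rep(0.4, 4), tolerance = 1e-9)
  expect_error(deposit_hill(st2, c(NaN, 0), 1), class = "actipath_input_error")
})

test_that("hill heights are non-increasing at a revisited point", {
  cfg <- wt_config(w = 0.4, sigma = c(x = 0.1))
  st <- bias_state(cfg)
  set.seed(5)
  pts <- rnorm(40, sd = 0.15)
  for (i in seq_along(pts)) st <- deposit_hill(st, pts[i], i)
  at0 <- vapply(seq_along(pts), function(i) {
    sub <- st; sub$hills <- st$hills[seq_len(i), , drop = FALSE]
    wt_hill_height(evaluate_bias(sub, 0), cfg)
  }, 0)
  expect_true(all(diff(at0) <= 1e-12))
})

test_that("bias evaluation matches Gaussian arithmetic and finite differences", {
  cfg <- wt_config(w = 0.4, sigma = c(s = 0.1, z = 1))
  st <- bias_state(cfg)
  expect_equal(evaluate_bias(st, c(0, 0)), 0)
  expect_equal(bias_gradient(st, c(0, 0)), c(0, 0))
  st <- deposit_hill(st, c(0.4, 1), time = 8)
  h <- st$hills$height[1]
  expect_equal(evaluate_bias(st, c(0.4, 1)), h)
  expect_equal(evaluate_bias(st, c(0.5, 1)), h * exp(-0.5))
  expect_equal(evaluate_bias(st, c(0.4, 2)), h * exp(-0.5))
  set.seed(6)
  for (i in 1:10) st <- deposit_hill(st, c(rnorm(1, 0.4, 0.2), rnorm(1, 1, 1)), 8 * i)
  for (pt in list(c(0.4, 1), c(0.1, 0.2), c(0.7, 2.5))) {
    g <- bias_gradient(st, pt)
    for (k in 1:2) {
      hstep <- 1e-6
      pp <- pt; pp[k] <- pp[k] + hstep
      pm <- pt; pm[k] <- pm[k] - hstep
      fd <- (evaluate_bias(st, pp) - evaluate_bias(st, pm)) / (2 * hstep)
      expect_equal(g[k], fd, tolerance = 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("free-energy estimator applies exactly -(T+dT)/dT and min-shifts", {
  cfg <- wt_config(w = 0.4, delta_T = 3000, temperature = 300, sigma = c(x = 0.1))
  st <- bias_state(cfg)
  set.seed(8)
  for (i in 1:12) st <- deposit_hill(st, rnorm(1, 0, 0.3), i)
  grid <- list(seq(-1, 1, length.out = 101))
  fes <- free_energy_estimate(st, grid)
  V <- evaluate_bias(st, matrix(grid[[1]], ncol = 1))
  expect_equal(fes$F, -1.1 * V + 1.1 * max(V), tolerance = 1e-10)
  expect_equal(min(fes$F), 0)
  # a single hill maps the bias maximum to the free-energy minimum
  st1 <- deposit_hill(bias_state(cfg), 0.25, 1)
  f1 <- free_energy_estimate(st1, grid)
  expect_equal(f1$axes[[1]]$mids[which.min(f1$F)], 0.24, tolerance = 0.011)
})

test_that("convergence monitor tracks the between-region free-energy difference", {
  cfg <- wt_config(w = 0.4, sigma = c(x = 0.1))
  st <- bias_state(cfg)
  set.seed(9)
  # symmetric fill of two wells at +-1
  for (i in 1:300) st <- deposit_hill(st, rnorm(1, sample(c(-1, 1), 1), 0.2), i)
  mon <- convergence_monitor(st, checkpoints = c(75, 150, 225, 300),
                             region_a = c(-1.4, -0.6), region_b = c(0.6, 1.4))
  expect_equal(nrow(mon$series), 4)
  expect_lt(abs(mon$series$delta_f[4]), 0.6)
  expect_true(is.finite(mon$trailing_amplitude))
  expect_error(convergence_monitor(st, c(30, 60), c(0, -1), c(0.6, 1.4)),
               class = "actipath_input_error")
})
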