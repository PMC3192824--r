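# Frame weights, free-energy projections and basin/barrier detection.

test_that("weights are unit under zero or constant bias", {
  cfg <- wt_config(w = 0.4, sigma = c(x = 0.1))
  empty <- bias_state(cfg)
  frames <- data.frame(time = 1:50, x = rnorm(50), bias = 0)
  expect_equal(frame_weights(frames, empty), rep(1, 50))
  # a single gigantic-width hill is constant over any sane range
  flat_cfg <- wt_config(w = 2, sigma = c(x = 1e8))
  flat <- deposit_hill(bias_state(flat_cfg), 0, 1)
  frames$bias <- evaluate_bias(flat, matrix(frames$x, ncol = 1))
  expect_equal(frame_weights(frames, flat), rep(1, 50), tolerance = 1e-9)
  expect_equal(frame_weights(frames, flat, "time_dependent"), rep(1, 50),
               tolerance = 1e-6)
  bad <- frames; bad$bias[3] <- NaN
  expect_error(frame_weights(bad, flat, "time_dependent"),
               class = "actipath_input_error")
})

test_that("projection of Boltzmann samples recovers the potential", {
  pot <- make_double_well(2, 0.8, 1)
  set.seed(17)
  x <- boltzmann_sample(pot, 2e5)
  f <- project_fes(data.frame(x = x), axes = fes_axis("x", bins = 60,
                                                      range = c(-1.8, 1.8)))
  mid <- f$axes[[1]]$mids
  U <- pot$energy(mid)
  occ <- f$occupied & U - min(U) < 4 * kT300
  resid <- f$F[occ] - U[occ]; resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.1)
})

test_that("projection is invariant to weight scaling and flat for uniform data", {
  set.seed(18)
  df <- data.frame(x = runif(200000, -1, 1))
  w <- runif(200000, 0.5, 2)
  f1 <- project_fes(df, w, fes_axis("x", 20, c(-1, 1)))
  f2 <- project_fes(df, 2 * w, fes_axis("x", 20, c(-1, 1)))
  expect_equal(f1$F, f2$F, tolerance = 1e-12)
  funi <- project_fes(df, NULL, fes_axis("x", 20, c(-1, 1)))
  expect_lt(max(funi$F), 0.05)
})

test_that("2D projection then marginalization equals direct 1D projection", {
  set.seed(19)
  n <- 60000
  df <- data.frame(x = rnorm(n, 0, 0.7), y = rnorm(n, 0, 0.5))
  w <- runif(n, 0.5, 1.5)
  ax <- fes_axis("x", 30, c(-2, 2)); ay <- fes_axis("y", 24, c(-2, 2))
  f2 <- project_fes(df, w, list(ax, ay))
  f1m <- marginalize_fes(f2, over = "y")
  f1 <- project_fes(df, w, ax)
  keep <- f1m$occupied & f1$occupied
  expect_equal(f1m$F[keep], f1$F[keep], tolerance = 0.02)
})

test_that("basin finder matches the analytic double well", {
  pot <- make_double_well(3, 0, 1)
  x <- seq(-1.8, 1.8, length.out = 301)
  F <- pot$energy(x) - min(pot$energy(x))
  fes <- actipath:::new_fes(list(list(name = "x", mids = x)), F,
                            rep(TRUE, 301), kT300, "analytic")
  tab <- find_basins_and_barriers(fes)
  mins <- tab[tab$type == "min", ]
  expect_equal(nrow(mins), 2)
  expect_equal(sort(mins$x), c(-1, 1), tolerance = 0.02)
  expect_equal(tab$barrier[tab$type == "ts"], 3, tolerance = 0.02)
  # symmetric wells: the star goes to the lower coordinate
  expect_true(mins$star[which.min(mins$x)])
  # monotone profile: one minimum, no barriers
  mono <- actipath:::new_fes(list(list(name = "x", mids = x)),
                             0.5 * (x + 2)^2, rep(TRUE, 301), kT300, "")
  tmono <- find_basins_and_barriers(mono)
  expect_equal(sum(tmono$type == "min"), 1)
  expect_equal(sum(tmono$type == "ts"), 0)
})

test_that("persistence pruning removes shallow noise minima", {
  x <- seq(-1.5, 1.5, length.out = 201)
  set.seed(20)
  pot <- make_double_well(2.5, 0.5, 1)
  F <- pot$energy(x) + 0.04 * sin(40 * x)   # corrugation below min_depth
  fes <- actipath:::new_fes(list(list(name = "x", mids = x)), F - min(F),
                            rep(TRUE, 201), kT300, "")
  tab <- find_basins_and_barriers(fes, min_depth = 0.3)
  expect_equal(sum(tab$type == "min"), 2)
})

test_that("2D basin finder locates minima and bottleneck saddles", {
  pot <- make_product_potential(make_double_well(3, 0, 1), k_y = 3)
  gx <- seq(-1.7, 1.7, length.out = 90)
  gy <- seq(-1.2, 1.2, length.out = 70)
  F <- outer(gx, gy, function(x, y)
    mapply(function(a, b) pot$energy(c(a, b)), x, y))
  F <- F - min(F)
  fes <- actipath:::new_fes(list(list(name = "x", mids = gx),
                                 list(name = "y", mids = gy)),
                            F, matrix(TRUE, 90, 70), kT300, "")
  tab <- find_basins_and_barriers(fes, min_depth = 0.5)
  mins <- tab[tab$type == "min", ]
  expect_equal(nrow(mins), 2)
  expect_equal(sort(mins$x), c(-1, 1), tolerance = 0.05)
  expect_equal(abs(mins$y), c(0, 0), tolerance = 0.05)
  ts <- tab[tab$type == "ts", ]
  expect_equal(nrow(ts), 1)
  expect_equal(ts$barrier, 3, tolerance = 0.05)
  expect_equal(ts$x, 0, tolerance = 0.05)
})

test_that("population estimates carry plausible block errors", {
  set.seed(21)
  x <- rnorm(20000)
  p <- population_estimate(x, region = c(0, Inf))
  expect_equal(p$p, 0.5, tolerance = 0.02)
  expect_lt(p$se, 0.05)
  expect_gt(p$se, 0)
})
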