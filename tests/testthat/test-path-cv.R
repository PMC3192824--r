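# Path collective variables: closed forms, numerical stability, rigid
# invariance, monotonicity, and the diagnostic report.

test_that("z closed forms hold to 1e-9", {
  prs <- well_separated_path(n_refs = 3, spacing = 1.2)
  # single reference: z = d exactly
  one <- path_reference_set(prs$refs[1], gamma = 4)
  probe <- prs$refs[[3]]
  expect_equal(path_z(probe, one), path_metric(probe, one, 1),
               tolerance = 1e-9)
  # exactly equidistant from two references: scale the probe cloud about its
  # centroid by (1 +/- eps), which keeps the optimal rotation at identity,
  # so both metrics are (eps * radius_of_gyration)^2 exactly
  set.seed(2)
  base <- matrix(rnorm(90, sd = 3), 30, 3)
  base <- sweep(base, 2, colMeans(base))
  two <- path_reference_set(list(0.8 * base, 1.2 * base), gamma = 4)
  d1 <- path_metric(base, two, 1); d2 <- path_metric(base, two, 2)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_equal(path_z(base, two), d1 - log(2) / two$gamma, tolerance = 1e-9)
  expect_equal(path_s(base, two), 0.5, tolerance = 1e-9)
})

test_that("s and z at the references match the well-separated limits", {
  prs <- well_separated_path(n_refs = 10, spacing = 1.0)
  at <- validate_path(prs)$at_refs
  expect_true(all(abs(at$s - (at$j - 1) / 9) < 0.01))
  expect_true(all(at$z > -0.05 & at$z < 0.05))
})

test_that("log-sum-exp evaluation equals naive summation when it does not underflow", {
  prs <- well_separated_path(n_refs = 6, spacing = 0.8, seed = 5)
  set.seed(9)
  for (i in 1:20) {
    probe <- prs$refs[[sample(6, 1)]] + matrix(rnorm(90, sd = 0.3), 30, 3)
    d <- vapply(seq_len(prs$n), function(j) path_metric(probe, prs, j), 0)
    e <- exp(-prs$gamma * d)
    s_naive <- sum((seq_len(prs$n) - 1) * e) / ((prs$n - 1) * sum(e))
    z_naive <- -log(sum(e)) / prs$gamma
    r <- path_sz(probe, prs)
    expect_equal(r$s, s_naive, tolerance = 1e-12)
    expect_equal(r$z, z_naive, tolerance = 1e-12)
  }
})

test_that("s and z stay finite when every reference is very far", {
  prs <- well_separated_path(n_refs = 5, spacing = 1.0)
  far <- prs$refs[[1]] * 3   # inflated cloud: huge fitted distance to all refs
  r <- path_sz(far, prs)
  expect_true(is.finite(r$s) && is.finite(r$z))
  expect_gt(r$z, 10)
  # at R_1 with gamma * d >= 20 between references, s -> 0 below 1e-6
  wide <- well_separated_path(n_refs = 5, spacing = 2.4)
  expect_lt(path_s(wide$refs[[1]], wide), 1e-6)
  expect_gt(path_s(wide$refs[[5]], wide), 1 - 1e-6)
})

test_that("s and z are invariant under rigid motion of the probe", {
  prs <- well_separated_path(n_refs = 8, spacing = 0.9, seed = 3)
  probe <- prs$refs[[4]] + matrix(rnorm(90, sd = 0.2), 30, 3)
  r0 <- path_sz(probe, prs)
  for (s in 1:4) {
    moved <- random_rigid_motion(conformation(probe), seed = s)
    r <- path_sz(moved, prs)
    expect_equal(r$s, r0$s, tolerance = 1e-8)
    expect_equal(r$z, r0$z, tolerance = 1e-8)
  }
})

test_that("s increases monotonically along an interpolated activation trajectory", {
  mr <- make_mini_receptor(seed = 2)
  traj <- interpolated_trajectory(mr, 25, noise_sigma = 0)
  prs <- path_reference_set(traj[seq(1, 25, by = 3)], gamma = 12,
                            mask = mr$ca_mask)
  s <- vapply(traj, path_s, 0, set = prs)
  expect_gt(suppressWarnings(cor(s, seq_along(s), method = "spearman")), 0.99)
})

test_that("path gradients agree with finite differences", {
  prs <- well_separated_path(n_refs = 5, spacing = 0.8, seed = 8)
  probe <- prs$refs[[2]] + matrix(rnorm(90, sd = 0.3), 30, 3)
  r <- path_sz(probe, prs, grad = TRUE)
  set.seed(10)
  for (k in 1:6) {
    i <- sample(30, 1); j <- sample(3, 1)
    h <- 1e-6
    pp <- probe; pp[i, j] <- pp[i, j] + h
    rp <- path_sz(pp, prs)
    expect_equal((rp$s - r$s) / h, r$grad_s[i, j], tolerance = 1e-4)
    expect_equal((rp$z - r$z) / h, r$grad_z[i, j], tolerance = 1e-4)
  }
})

test_that("the index convention spans 1..n instead of 0..1", {
  prs <- well_separated_path(n_refs = 4, spacing = 1.0)
  expect_equal(path_sz(prs$refs[[1]], prs, convention = "index")$s, 1,
               tolerance = 0.05)
  expect_equal(path_sz(prs$refs[[4]], prs, convention = "index")$s, 4,
               tolerance = 0.05)
})

test_that("validate_path reports equidistance and flags duplicates", {
  prs <- well_separated_path(n_refs = 6, spacing = 1.0)
  rep <- validate_path(prs)
  expect_true(rep$ok)
  expect_lt(rep$cv_consecutive, 0.05)
  expect_equal(rep$gamma_recommended, 1 / mean(rep$consecutive$d),
               tolerance = 1e-9)
  dup <- path_reference_set(prs$refs[c(1, 2, 2, 3)], gamma = 4)
  repd <- validate_path(dup)
  expect_false(repd$ok)
  expect_match(paste(repd$problems, collapse = " "), "duplicate")
})
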