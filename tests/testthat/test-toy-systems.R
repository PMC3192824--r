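# Analytic potentials, the Langevin integrator and the mini-receptor
# fixture.

test_that("double-well energetics are exact", {
  pot <- make_double_well(3, 0, 1)
  expect_equal(pot$energy(1), pot$energy(-1))
  expect_equal(pot$energy(0) - pot$energy(1), 3)
  expect_equal(sort(pot$minima$x), c(-1, 1))
  tilted <- make_double_well(3, 1, 1)
  # exact minima from the cubic agree with direct numerical minimization
  for (k in 1:2) {
    opt <- optimize(tilted$energy, c(-2, 0) + 2 * (k - 1), tol = 1e-10)
    expect_equal(tilted$minima$x[k], opt$minimum, tolerance = 1e-6)
    expect_equal(tilted$minima$energy[k], opt$objective, tolerance = 1e-9)
  }
  expect_equal(tilted$delta_min, 1, tolerance = 0.05)  # first order in the tilt
  # gradient vs finite differences
  set.seed(4)
  for (x in rnorm(10)) {
    fd <- (tilted$energy(x + 1e-6) - tilted$energy(x - 1e-6)) / 2e-6
    expect_equal(tilted$grad(x), fd, tolerance = 1e-5)
  }
})

test_that("langevin sampling satisfies equipartition in a harmonic well", {
  sys <- potential_system(make_harmonic(k = 2), q0 = 0)
  run <- run_langevin(sys, steps = 1500000, dt = 0.02, friction = 1,
                      seed = 42, stride = 5)
  v <- var(run$frames$x[run$frames$time > 20])
  expect_equal(v, kT300 / 2, tolerance = 0.02)
})

test_that("trajectories are bit-identical for a fixed seed", {
  sys <- potential_system(make_double_well(2, 0.5), q0 = -1)
  a <- run_langevin(sys, steps = 3000, dt = 0.01, seed = 7)
  b <- run_langevin(sys, steps = 3000, dt = 0.01, seed = 7)
  expect_identical(a$frames, b$frames)
  c2 <- run_langevin(sys, steps = 3000, dt = 0.01, seed = 8)
  expect_false(identical(a$frames$x, c2$frames$x))
})

test_that("zero temperature with strong friction descends to the nearest minimum", {
  pot <- make_double_well(3, 0, 1)
  sys <- potential_system(pot, q0 = -0.4)
  run <- run_langevin(sys, steps = 4000, dt = 0.002, temperature = 1e-12,
                      friction = 20, integrator = "overdamped", seed = 1)
  expect_equal(tail(run$frames$x, 1), -1, tolerance = 1e-3)
})

test_that("long unbiased sampling reproduces the Boltzmann density", {
  pot <- make_double_well(1.2, 0.5, 1)
  sys <- potential_system(pot, q0 = 1)
  run <- run_langevin(sys, steps = 1000000, dt = 0.005, friction = 1,
                      integrator = "overdamped", seed = 3, stride = 5)
  xs <- run$frames$x[run$frames$time > 50]
  br <- seq(-2.2, 2.2, by = 0.1)
  xs <- xs[xs > br[1] & xs < br[length(br)]]
  h <- hist(xs, breaks = br, plot = FALSE)
  mid <- h$mids
  p_ref <- exp(-pot$energy(mid) / kT300); p_ref <- p_ref / sum(p_ref)
  expect_lt(sum(abs(h$counts / sum(h$counts) - p_ref)), 0.05)
})

test_that("mini-receptor end states hit their descriptor construction targets", {
  mr <- make_mini_receptor(seed = 1)
  di <- activation_descriptors(mr$inactive, mr$inactive, mr$map,
                               align_mask = mr$align_mask)
  da <- activation_descriptors(mr$active, mr$inactive, mr$map,
                               align_mask = mr$align_mask)
  expect_equal(unname(di[c("d_il", "chi_ts", "delta_d_tm6")]), c(3, 163, 0),
               tolerance = 0.01)
  expect_equal(unname(da[c("d_il", "chi_ts", "delta_d_tm6")]), c(12, 55, 5.9),
               tolerance = 0.01)
})

test_that("mini-receptor construction is deterministic and energetically two-state", {
  a <- make_mini_receptor(seed = 3)
  b <- make_mini_receptor(seed = 3)
  expect_identical(a$inactive$coords, b$inactive$coords)
  expect_identical(a$modes, b$modes)
  expect_false(identical(a$modes, make_mini_receptor(seed = 4)$modes))
  # the exact minima of the progress-coordinate double well sit at the end
  # states (up to the small tilt-induced shift), and the transverse modes
  # are orthonormal and free of rigid-body content
  expect_equal(a$potential$minima$x, c(-1, 1), tolerance = 0.06)
  expect_equal(crossprod(a$modes), diag(ncol(a$modes)), tolerance = 1e-9)
  delta <- a$delta_coords / sqrt(sum(a$delta_coords^2))
  expect_lt(max(abs(crossprod(a$modes, delta))), 1e-9)
  sys <- mini_receptor_system(a, observe = FALSE)
  for (u in a$potential$minima$x) {
    g <- sys$grad(c(u, 0, 0, 0))
    expect_lt(max(abs(g)), 1e-6)
  }
})

test_that("interpolated trajectories are linear, ordered and seeded", {
  mr <- make_mini_receptor(seed = 1)
  tr <- interpolated_trajectory(mr, 3, noise_sigma = 0)
  expect_equal(tr[[2]]$coords, (mr$inactive$coords + mr$active$coords) / 2)
  tr2 <- interpolated_trajectory(mr, 15, noise_sigma = 0)
  d_in <- vapply(tr2, rmsd, 0, b = mr$inactive, mask = mr$ca_mask)
  expect_true(all(diff(d_in) > 0))
  n1 <- interpolated_trajectory(mr, 5, noise_sigma = 0.1, seed = 9)
  n2 <- interpolated_trajectory(mr, 5, noise_sigma = 0.1, seed = 9)
  expect_identical(n1[[3]]$coords, n2[[3]]$coords)
  expect_identical(n1[[1]]$coords, mr$inactive$coords)  # endpoints noise-free
  expect_identical(n1[[5]]$coords, mr$active$coords)
})

test_that("descriptor values survive a PDB round trip", {
  mr <- make_mini_receptor(seed = 1)
  tf <- tempfile(fileext = ".pdb")
  write_pdb(mr$active, tf)
  back <- read_pdb(tf)
  da <- activation_descriptors(back, mr$inactive, mr$map,
                               align_mask = mr$align_mask)
  expect_equal(unname(da[c("d_il", "chi_ts", "delta_d_tm6")]), c(12, 55, 5.9),
               tolerance = 0.01)
})
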