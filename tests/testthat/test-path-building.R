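# Pooling, clustering and reference selection.

test_that("pairwise dissimilarities match per-pair RMSD calls", {
  mr <- make_mini_receptor(seed = 1)
  frames <- interpolated_trajectory(mr, 6, noise_sigma = 0.3, seed = 2)
  D <- pairwise_rmsd(frames, mr$ca_mask)
  expect_equal(diag(D), rep(0, 6))
  expect_equal(D, t(D))
  for (pair in list(c(1, 4), c(2, 6), c(3, 5)))
    expect_equal(D[pair[1], pair[2]],
                 rmsd(frames[[pair[1]]], frames[[pair[2]]], mr$ca_mask))
  # duplicate frames have zero off-diagonal distance
  D2 <- pairwise_rmsd(list(frames[[1]], frames[[1]], frames[[3]]), mr$ca_mask)
  expect_lt(D2[1, 2], 1e-10)
  # triangle inequality spot check on frames along a line in conformation space
  expect_lte(D[1, 6], D[1, 3] + D[3, 6] + 1e-9)
})

test_that("average linkage reproduces hand-traced merges", {
  D2 <- matrix(c(0, 3, 3, 0), 2, 2)
  t2 <- average_linkage(D2)
  expect_equal(t2$height, 3)
  # two tight pairs {1,2} and {3,4}, cross distances all 4
  D4 <- matrix(4, 4, 4); diag(D4) <- 0
  D4[1, 2] <- D4[2, 1] <- 1; D4[3, 4] <- D4[4, 3] <- 1.1
  t4 <- average_linkage(D4)
  expect_equal(sort(t4$height), c(1, 1.1, 4))
  expect_true(same_partition(cutree(t4, 2), c(1, 1, 2, 2)))
  expect_error(average_linkage(matrix(0, 1, 1)), class = "actipath_input_error")
})

test_that("average linkage equals the naive O(n^3) recomputation", {
  set.seed(13)
  for (rep in 1:6) {
    n <- 12
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.5, 3)
    D <- D + t(D)
    tree <- average_linkage(D)
    for (k in c(2, 4, 7))
      expect_true(same_partition(cutree(tree, k), naive_upgma_cut(D, k)))
    expect_true(all(diff(tree$height) >= -1e-12))  # monotone linkage
  }
})

test_that("clustering is invariant under frame permutation", {
  set.seed(14)
  n <- 15
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.2, 5)
  D <- D + t(D)
  base <- cutree(average_linkage(D), 5)
  for (rep in 1:3) {
    perm <- sample(n)
    got <- cutree(average_linkage(D[perm, perm]), 5)
    expect_true(same_partition(base[perm], got))
  }
})

test_that("reference selection is ordered, homogeneous and endpoint-anchored", {
  mr <- make_mini_receptor(seed = 1)
  frames <- interpolated_trajectory(mr, 30, noise_sigma = 0)
  D <- pairwise_rmsd(frames, mr$ca_mask)
  tree <- average_linkage(D)
  prs <- select_references(tree, frames, D, k_cut = 30, n_refs = 10,
                           inactive = mr$inactive, active = mr$active,
                           gamma = 12, mask = mr$ca_mask)
  sel <- attr(prs, "selection")
  # on a 30-frame linear interpolation cut into singletons: every 3rd frame
  expect_equal(sel$frame[1], 1)
  expect_equal(sel$frame[10], 30)
  expect_true(all(abs(diff(sel$frame) - 29 / 9) <= 1.5))
  expect_true(all(diff(sel$progression) > 0))
  rep <- validate_path(prs)
  expect_lt(rep$cv_consecutive, 0.5)
  expect_true(all(diff(rep$at_refs$s) > 0))
  # n_refs = 2 degenerates to the endpoint-nearest medoids
  prs2 <- select_references(tree, frames, D, k_cut = 30, n_refs = 2,
                            inactive = mr$inactive, active = mr$active,
                            gamma = 12, mask = mr$ca_mask)
  expect_equal(attr(prs2, "selection")$frame, c(1, 30))
  expect_error(select_references(tree, frames, D, k_cut = 1, n_refs = 10,
                                 inactive = mr$inactive, active = mr$active),
               class = "actipath_input_error")
})

test_that("ratchet runs with k = 0 reproduce plain dynamics bit-exactly", {
  mr <- make_mini_receptor(seed = 1, barrier = 1)
  sys <- mini_receptor_system(mr, observe = FALSE)
  pool <- run_abmd(sys, mr$active, k = 0, n_runs = 1, steps = 1500,
                   dt = 0.01, seed = 6, stride = 10)
  plain <- run_langevin(sys, steps = 1500, dt = 0.01, seed = 6, stride = 10)
  qc <- paste0("q", seq_len(sys$d))
  expect_identical(pool$runs[[1]]$frames[qc], plain$frames[qc])
})

test_that("a low-barrier two-state model is driven to the target", {
  mr <- make_mini_receptor(seed = 2, barrier = 0.8)
  sys <- mini_receptor_system(mr, observe = FALSE)
  pool <- run_abmd(sys, mr$active, k = 10, n_runs = 3, steps = 6000,
                   dt = 0.01, seed = 30, stride = 10)
  chi0 <- pool$runs[[1]]$frames$chi[1]
  best <- vapply(pool$runs, function(r) r$ratchet$running_best, 0)
  expect_true(all(best < 0.1 * chi0))
  confs <- pool_conformations(pool, sys, every = 40)
  expect_gt(length(confs), 10)
  expect_equal(nrow(attr(confs, "provenance")), length(confs))
})
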