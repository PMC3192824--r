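# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive: brute force, closed forms, or
# direct sampling -- never the package's own computational path.

kT300 <- boltzmann_kcal() * 300

# ---- brute-force rotation search -------------------------------------------
# Minimum RMSD over rigid motions by scanning rotations parameterized as
# random unit quaternions (two-stage refinement around the best candidate).
# Uses the identity rmsd^2 = c - 2 tr(R^T C)/N with C the covariance of the
# centered clouds, so each candidate rotation costs a 4-vector quadratic form.
brute_force_rmsd <- function(A, B, n_coarse = 200000L, n_fine = 200000L) {
  n <- nrow(A)
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  C <- crossprod(A0, B0)
  # Davenport K matrix: tr(R(q)^T C) = q^T K q for unit quaternions q
  K <- matrix(c(
    C[1,1]+C[2,2]+C[3,3], C[2,3]-C[3,2],        C[3,1]-C[1,3],        C[1,2]-C[2,1],
    C[2,3]-C[3,2],        C[1,1]-C[2,2]-C[3,3], C[1,2]+C[2,1],        C[1,3]+C[3,1],
    C[3,1]-C[1,3],        C[1,2]+C[2,1],        C[2,2]-C[1,1]-C[3,3], C[2,3]+C[3,2],
    C[1,2]-C[2,1],        C[1,3]+C[3,1],        C[2,3]+C[3,2],        C[3,3]-C[1,1]-C[2,2]),
    4, 4, byrow = TRUE)
  score <- function(Q) rowSums((Q %*% K) * Q)
  rand_q <- function(m) {
    Q <- matrix(rnorm(4 * m), m, 4)
    Q / sqrt(rowSums(Q^2))
  }
  Q <- rand_q(n_coarse)
  s <- score(Q)
  qb <- Q[which.max(s), ]
  # refine: small perturbations around the best coarse quaternion
  Q2 <- matrix(rnorm(4 * n_fine, sd = 0.02), n_fine, 4)
  Q2 <- sweep(Q2, 2, qb, `+`)
  Q2 <- Q2 / sqrt(rowSums(Q2^2))
  best <- max(s, score(Q2))
  msd <- (sum(A0^2) + sum(B0^2) - 2 * best) / n
  sqrt(max(msd, 0))
}

# ---- independent dihedral formula ------------------------------------------
# acos of normal-plane angle with the sign from the scalar triple product.
dihedral_oracle <- function(p1, p2, p3, p4) {
  cross <- function(u, v) c(u[2]*v[3]-u[3]*v[2], u[3]*v[1]-u[1]*v[3], u[1]*v[2]-u[2]*v[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(pmin(pmax(cosphi, -1), 1)) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) phi <- -phi
  phi
}

# ---- naive O(n^3) UPGMA -----------------------------------------------------
# Average linkage where the inter-cluster dissimilarity is recomputed from
# the original matrix at every step (mean over all cross pairs); merges the
# lexicographically smallest pair on ties.
naive_upgma <- function(D) {
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  merges <- list()
  while (length(active) > 1L) {
    best <- NULL; bestd <- Inf
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (bi <= ai) next
      a <- active[ai]; b <- active[bi]
      dd <- mean(D[members[[a]], members[[b]]])
      if (dd < bestd - 1e-12) { bestd <- dd; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    members[[length(members) + 1L]] <- c(members[[a]], members[[b]])
    merges[[length(merges) + 1L]] <- list(height = bestd,
                                          members = members[[length(members)]])
    active <- c(setdiff(active, best), length(members))
  }
  merges
}

# flat clusters at k groups from the naive merge list
naive_upgma_cut <- function(D, k) {
  n <- nrow(D)
  merges <- naive_upgma(D)
  lab <- seq_len(n)
  for (m in merges[seq_len(n - k)]) lab[m$members] <- min(lab[m$members])
  match(lab, unique(lab))
}

# TRUE when two labelings define identical partitions
same_partition <- function(a, b) {
  ta <- split(seq_along(a), a); tb <- split(seq_along(b), b)
  length(ta) == length(tb) &&
    setequal(vapply(ta, paste, "", collapse = ","),
             vapply(tb, paste, "", collapse = ","))
}

# ---- direct Boltzmann sampling ---------------------------------------------
# iid draws from p(x) ~ exp(-U/kT) by discretized inverse CDF with
# within-bin uniform jitter.
boltzmann_sample <- function(pot, n, lo = -2, hi = 2, temperature = 300,
                             ngrid = 4001L) {
  x <- seq(lo, hi, length.out = ngrid)
  p <- exp(-(pot$energy(x) - min(pot$energy(x))) / (boltzmann_kcal() * temperature))
  cdf <- cumsum(p); cdf <- cdf / cdf[length(cdf)]
  u <- runif(n)
  i <- findInterval(u, cdf) + 1L
  x[i] + runif(n, -0.5, 0.5) * (x[2] - x[1])
}

# ---- synthetic well-separated path -----------------------------------------
# n_refs conformations displaced along a fixed random field (rigid motions
# projected out) with `spacing` A of fitted RMSD between neighbours.
well_separated_path <- function(n_refs = 10, spacing = 1.0, n_atoms = 30,
                                seed = 2, gamma = 4) {
  set.seed(seed)
  base <- matrix(rnorm(3 * n_atoms, sd = 8), n_atoms, 3)
  dirn <- matrix(rnorm(3 * n_atoms), n_atoms, 3)
  dirn <- sweep(dirn, 2, colMeans(dirn))      # no net translation
  dirn <- dirn / sqrt(sum(dirn^2)) * sqrt(n_atoms)  # unit per-atom RMS
  refs <- lapply(seq_len(n_refs) - 1L, function(j) base + j * spacing * dirn)
  path_reference_set(refs, gamma = gamma)
}

# ---- labelled single-purpose descriptor fixture ----------------------------
# Minimal conformation carrying exactly the atoms the three descriptors
# need, with every coordinate chosen by hand.
descriptor_fixture <- function(chi = 90) {
  scaffold <- matrix(c(0,0,0, 10,0,0, 0,10,0, 0,0,10, 10,10,0, 10,0,10,
                       0,10,10, 10,10,10, 5,5,12, 12,5,5), ncol = 3,
                     byrow = TRUE)
  nW <- c(20, 1, 1); caW <- c(20, 0, 0); cbW <- c(21.4, -0.5, 0)
  cgW <- actipath:::place_atom(nW, caW, cbW, 1.5, 114, chi)
  coords <- rbind(
    scaffold,                    # residues 1..10, CA scaffold
    c(30, 0, 0),                 # CA  res 11 (2.41)
    c(40, 0, 0),                 # CA  res 12 (3.50)
    c(0, 0, 0) + c(40, 1, 0),    # NH1 res 12
    c(42, -1, 0),                # NH2 res 12
    c(50, 0, 0),                 # CA  res 13 (6.30)
    c(41, 3, 0), c(41, 5, 0),    # OE1/OE2 res 13
    c(36, 8, 0),                 # CA  res 14 (6.35)
    nW, caW, cbW, cgW)           # res 15 (6.48)
  conformation(coords,
               atom_names = c(rep("CA", 12), "NH1", "NH2", "CA", "OE1", "OE2",
                              "CA", "N", "CA", "CB", "CG"),
               residue_ids = c(1:12, 12, 12, 13, 13, 13, 14, 15, 15, 15, 15),
               residue_names = c(rep("GLY", 10), "TYR", rep("ARG", 3),
                                 rep("GLU", 3), "LYS", rep("TRP", 4)))
}

descriptor_fixture_map <- function() {
  residue_map(data.frame(
    bw_label = c("2.41", "3.50", "6.30", "6.35", "6.48"),
    chain = "A", resid = c(11L, 12L, 13L, 14L, 15L),
    resname = c("TYR", "ARG", "GLU", "LYS", "TRP")))
}

random_rigid_motion <- function(conf, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0.3, 2.5)
  Kk <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * Kk + (1 - cos(th)) * Kk %*% Kk
  conf$coords <- conf$coords %*% R + matrix(rnorm(3, sd = 5),
                                            nrow(conf$coords), 3, byrow = TRUE)
  conf
}
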