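# Synthetic systems with exactly known energetics: analytic potentials for
# the Langevin engine, and a labelled "mini-receptor" bead model with
# inactive/active end states on which every descriptor, the clustering, the
# path CVs and the full biasing pipeline can be exercised.

#' Analytic one-dimensional double-well potential
#'
#' `U(x) = barrier * ((x/width)^2 - 1)^2 + asymmetry * x / (2 width)`:
#' minima near +/- width; with no tilt the barrier measured from either
#' minimum is exactly `barrier`; the tilt shifts the minima slightly, so
#' the exact stationary points and energies are solved from the cubic
#' `dU/dx = 0` and stored.
#'
#' @param barrier barrier height in kcal/mol (> 0).
#' @param asymmetry energy offset between the wells in kcal/mol (first
#'   order); positive lowers the left (-width) well.
#' @param width half-separation of the wells.
#' @return object of class `"analytic_potential"` with vectorized `energy`
#'   and `grad` closures, a `minima` data.frame (x, energy), `saddle`
#'   (x, energy), `delta_min` (exact energy difference right minus left)
#'   and `barriers` (exact, from each minimum to the saddle).
#' @export
make_double_well <- function(barrier = 3, asymmetry = 0, width = 1) {
  check_scalar(barrier, "barrier"); check_scalar(asymmetry, "asymmetry")
  if (barrier <= 0) abort_ap("'barrier' must be positive")
  b <- barrier; a <- asymmetry; w <- width
  energy <- function(x) b * ((x / w)^2 - 1)^2 + a * x / (2 * w)
  grad <- function(x) 4 * b * x * (x^2 - w^2) / w^4 + a / (2 * w)
  # stationary points: 4b/w^4 x^3 - 4b/w^2 x + a/(2w) = 0
  rt <- polyroot(c(a / (2 * w), -4 * b / w^2, 0, 4 * b / w^4))
  rt <- sort(Re(rt[abs(Im(rt)) < 1e-8 * (1 + abs(Re(rt)))]))
  curv <- function(x) 4 * b * (3 * x^2 - w^2) / w^4
  st <- data.frame(x = rt, energy = energy(rt), curvature = curv(rt))
  minima <- st[st$curvature > 0, c("x", "energy")]
  saddle <- st[st$curvature < 0, c("x", "energy")]
  delta_min <- if (nrow(minima) == 2L) diff(minima$energy) else NA_real_
  barriers <- if (nrow(saddle) == 1L) saddle$energy[1] - minima$energy else NULL
  structure(list(dim = 1L, energy = energy, grad = grad, minima = minima,
                 saddle = saddle, delta_min = delta_min, barriers = barriers,
                 params = list(barrier = b, asymmetry = a, width = w)),
            class = "analytic_potential")
}

#' Analytic harmonic well
#' @param k spring constant in kcal/(mol A^2).
#' @param x0 minimum position.
#' @return an `"analytic_potential"` (1D).
#' @export
make_harmonic <- function(k = 1, x0 = 0) {
  structure(list(dim = 1L,
                 energy = function(x) 0.5 * k * (x - x0)^2,
                 grad = function(x) k * (x - x0),
                 minima = data.frame(x = x0, energy = 0),
                 saddle = data.frame(x = numeric(0), energy = numeric(0)),
                 delta_min = NA_real_, barriers = NULL,
                 params = list(k = k, x0 = x0)),
            class = "analytic_potential")
}

#' Separable 2D potential: a 1D profile times a harmonic transverse mode
#'
#' `U(x, y) = U1(x) + 0.5 k_y y^2`; useful as a 2D test surface with known
#' minima and saddles.
#'
#' @param pot1d an `"analytic_potential"` acting on the first coordinate.
#' @param k_y transverse spring constant.
#' @return an `"analytic_potential"` with `dim = 2`.
#' @export
make_product_potential <- function(pot1d, k_y = 2) {
  structure(list(dim = 2L,
                 energy = function(q) pot1d$energy(q[1]) + 0.5 * k_y * q[2]^2,
                 grad = function(q) c(pot1d$grad(q[1]), k_y * q[2]),
                 minima = cbind(pot1d$minima["x"], y = 0,
                                energy = pot1d$minima$energy),
                 saddle = cbind(pot1d$saddle["x"], y = 0,
                                energy = pot1d$saddle$energy),
                 delta_min = pot1d$delta_min, barriers = pot1d$barriers,
                 params = list(k_y = k_y, pot1d = pot1d$params)),
            class = "analytic_potential")
}

#' Wrap an analytic potential as a simulatable system
#'
#' @param pot an `"analytic_potential"`.
#' @param q0 initial coordinates.
#' @param cv_dims which coordinates are exposed as collective variables for
#'   biasing (default: all of them).
#' @param cv_names names of those CVs (default "x", "y").
#' @return object of class `"dynamics_system"` consumed by [run_langevin()],
#'   [run_metadynamics()] and [run_abmd()].
#' @export
potential_system <- function(pot, q0 = pot$minima$x[1], cv_dims = NULL,
                             cv_names = NULL) {
  d <- pot$dim
  q0 <- rep_len(as.numeric(q0), d)
  cv_dims <- as.integer(cv_dims %||% seq_len(d))
  cv_names <- cv_names %||% c("x", "y")[cv_dims]
  gradf <- pot$grad
  energyf <- pot$energy
  grad_full <- if (d == 1L) function(q) gradf(q) else gradf
  structure(list(d = d, q0 = q0, masses = 1,
                 energy = energyf, grad = grad_full,
                 cv_dims = cv_dims, cv_names = cv_names, cv = NULL,
                 observe = NULL, conformation = NULL,
                 info = list(kind = "analytic_potential")),
            class = "dynamics_system")
}

# ---------------------------------------------------------------------------
# Mini-receptor: a 31-atom, 24-pseudo-residue bead model with BW-labelled
# residues 2.41, 3.50 (Arg), 6.30 (Glu), 6.35 (Lys), 6.48 (Trp), one
# flexible "IL3-like" residue excluded from all masks, and inactive/active
# end states constructed to hit the canonical descriptor values
# (d_IL 3 -> 12 A, chi_TS 163 -> 55 deg, delta d_TM6 0 -> 5.9 A).
# ---------------------------------------------------------------------------

mini_receptor_scaffold <- function() {
  # four pseudo-helices of 6 CA beads around a bundle axis, gentle spiral so
  # no selection is collinear
  centers <- list(`2` = c(-5, 5), `3` = c(-5, -5), `6` = c(5, -5), `7` = c(5, 5))
  coords <- NULL
  for (h in seq_along(centers)) {
    ctr <- centers[[h]]
    for (k in 1:6) {
      phi <- 2 * pi * (k - 1) / 6 + h
      coords <- rbind(coords, c(ctr[1] + 1.6 * cos(phi),
                                ctr[2] + 1.6 * sin(phi),
                                3 * (k - 3.5)))
    }
  }
  coords
}

#' Build the labelled mini-receptor fixture
#'
#' Deterministic construction (given `seed`, which only drives the
#' transverse noise modes) of a two-state bead receptor:
#' \itemize{
#'   \item the inactive state has `d_IL = 3` A, `chi_TS = 163` deg and
#'     `delta d_TM6 = 0` by definition;
#'   \item the active state has `d_IL = 12` A, `chi_TS = 55` deg and an
#'     outward motion of the intracellular TM6 beads calibrated (by root
#'     finding on the post-alignment displacement) so that
#'     `delta d_TM6 = 5.9` A exactly.
#' }
#' Conformations along the activation mode are linear interpolations of the
#' end states; the conformational energy is a double well in the progress
#' coordinate plus stiff harmonic transverse modes, so both end states are
#' local minima.
#'
#' @param seed integer seed for the transverse noise modes.
#' @param barrier double-well barrier between the end states, kcal/mol.
#' @param asymmetry energy of the inactive minus the active state, kcal/mol
#'   (default 1: the active state is more stable, as for a full agonist).
#' @param n_modes number of transverse harmonic modes (default 3).
#' @param mode_stiffness stiffness of those modes, kcal/(mol A^2).
#' @return object of class `"mini_receptor"`: `inactive`/`active`
#'   conformations, `map` (residue map), `ca_mask`, `align_mask`,
#'   `loop_residues`, `modes`, `potential` (the exact double well on the
#'   progress coordinate u in [-1, 1]), and construction `targets`.
#' @export
make_mini_receptor <- function(seed = 1, barrier = 3, asymmetry = 1,
                               n_modes = 3, mode_stiffness = 50) {
  ca <- mini_receptor_scaffold()
  n_res <- nrow(ca) # 24
  # atom bookkeeping: one CA per residue, plus sidechain pseudo-atoms
  atom_names <- rep("CA", n_res)
  residue_ids <- seq_len(n_res)
  residue_names <- rep("GLY", n_res)
  res_bw <- c(`2.41` = 3L, `3.50` = 9L, `6.30` = 13L, `6.35` = 14L, `6.48` = 17L)
  residue_names[res_bw] <- c("TYR", "ARG", "GLU", "LYS", "TRP")
  loop_residues <- 12L # flexible linker bead, excluded from all masks
  add <- function(tab, name, rid, xyz)
    rbind(tab, data.frame(name = name, rid = rid, x = xyz[1], y = xyz[2], z = xyz[3]))
  extra <- data.frame(name = character(0), rid = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0))
  # R3.50 eta-nitrogens flanking a point 2 A from its CA
  caR <- ca[res_bw["3.50"], ]
  pR <- caR + c(1.6, 0.9, -0.8)
  extra <- add(extra, "NH1", res_bw[["3.50"]], pR + c(0, 1.1, 0))
  extra <- add(extra, "NH2", res_bw[["3.50"]], pR - c(0, 1.1, 0))
  # E6.30 carboxylate oxygens: centroid placed at the exact ionic-lock
  # distance from the nitrogen centroid
  u_il <- c(1, 0, 0) # direction from R3.50 toward TM6
  place_glu <- function(d_il) {
    pE <- pR + d_il * u_il
    rbind(pE + c(0, 0, 1.05), pE - c(0, 0, 1.05))
  }
  oe_in <- place_glu(3)
  extra <- add(extra, "OE1", res_bw[["6.30"]], oe_in[1, ])
  extra <- add(extra, "OE2", res_bw[["6.30"]], oe_in[2, ])
  # W6.48 chi1 frame: N and CB around its CA; CG placed at the target chi1
  caW <- ca[res_bw["6.48"], ]
  nW <- caW + c(0.0, 1.2, 0.9)
  cbW <- caW + c(1.2, -0.6, 0.6)
  place_trp <- function(chi) place_atom(nW, caW, cbW, 1.52, 114, chi)
  extra <- add(extra, "N", res_bw[["6.48"]], nW)
  extra <- add(extra, "CB", res_bw[["6.48"]], cbW)
  extra <- add(extra, "CG", res_bw[["6.48"]], place_trp(163))
  coords <- rbind(ca, as.matrix(extra[, c("x", "y", "z")]))
  atom_names <- c(atom_names, extra$name)
  residue_ids <- c(residue_ids, extra$rid)
  residue_names <- c(residue_names, residue_names[extra$rid])
  masses <- ifelse(substr(atom_names, 1, 1) == "N", 14.007,
                   ifelse(substr(atom_names, 1, 1) == "O", 15.999, 12.011))
  inactive <- conformation(coords, atom_names, residue_ids, residue_names,
                           "A", masses)
  map <- residue_map(data.frame(bw_label = names(res_bw), chain = "A",
                                resid = as.integer(res_bw),
                                resname = residue_names[res_bw]))
  ca_mask <- which(atom_names == "CA" & !(residue_ids %in% loop_residues))
  n_atoms <- nrow(coords)
  # active state: outward swing of the intracellular TM6 beads (residues
  # 13..16), magnitude calibrated so the post-alignment TM6 displacement is
  # exactly the 5.9 A target
  out_dir <- c(1, -1, 0) / sqrt(2)  # horizontal, away from the bundle core
  tm6_amp <- c(`13` = 1.0, `14` = 1.0, `15` = 0.7, `16` = 0.4)
  active_coords <- function(alpha) {
    xyz <- coords
    for (r in names(tm6_amp)) {
      ri <- as.integer(r)
      sel <- which(residue_ids == ri & atom_names == "CA")
      xyz[sel, ] <- xyz[sel, ] + alpha * 5.9 * tm6_amp[[r]] *
        rep(out_dir, each = length(sel))
    }
    # broken ionic lock and flipped toggle switch
    xyz[atom_names %in% c("OE1", "OE2"), ] <- place_glu(12)
    xyz[atom_names == "CG" & residue_ids == res_bw[["6.48"]], ] <- place_trp(55)
    xyz
  }
  mk_active <- function(alpha)
    conformation(active_coords(alpha), atom_names, residue_ids,
                 residue_names, "A", masses)
  delta_of <- function(alpha)
    tm6_displacement(mk_active(alpha), inactive, map, align_mask = ca_mask)$delta
  alpha <- uniroot(function(a) delta_of(a) - 5.9, c(0.5, 2.5), tol = 1e-9)$root
  active <- mk_active(alpha)
  # transverse noise modes: seeded, orthogonal to rigid motions and to the
  # activation mode, unit norm in 3N coordinate space
  delta <- as.numeric(t(active$coords - inactive$coords))
  # joint orthonormal basis of rigid motions + the activation mode, so the
  # noise modes are orthogonal to all of them
  basis <- qr.Q(qr(cbind(rigid_motion_basis(inactive$coords),
                         delta / sqrt(sum(delta^2)))))
  set.seed(as.integer(seed))
  modes <- matrix(rnorm(3 * n_atoms * n_modes), ncol = n_modes)
  for (j in seq_len(n_modes)) {
    v <- modes[, j]
    v <- v - basis %*% crossprod(basis, v)
    if (j > 1) {
      prev <- modes[, seq_len(j - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    modes[, j] <- v / sqrt(sum(v^2))
  }
  structure(list(inactive = inactive, active = active, map = map,
                 ca_mask = ca_mask, align_mask = ca_mask,
                 loop_residues = loop_residues,
                 delta_coords = delta, modes = modes,
                 # negative tilt lowers the right (active, u = +1) well by
                 # `asymmetry` kcal/mol
                 potential = make_double_well(barrier, -asymmetry, width = 1),
                 mode_stiffness = mode_stiffness,
                 targets = list(inactive = c(d_il = 3, chi_ts = 163, delta_d_tm6 = 0),
                                active = c(d_il = 12, chi_ts = 55, delta_d_tm6 = 5.9)),
                 seed = seed),
            class = "mini_receptor")
}

# orthonormal basis of the 6 rigid-body motions (3 translations + 3
# infinitesimal rotations about the centroid) in 3N coordinate space
rigid_motion_basis <- function(coords) {
  n <- nrow(coords)
  c0 <- sweep(coords, 2L, colMeans(coords))
  B <- matrix(0, 3 * n, 6)
  for (k in 1:3) B[seq(k, 3 * n, by = 3), k] <- 1
  ax <- diag(3)
  for (k in 1:3) {
    rot <- t(vapply(seq_len(n), function(i) {
      v <- c0[i, ]; a <- ax[k, ]
      c(a[2] * v[3] - a[3] * v[2], a[3] * v[1] - a[1] * v[3],
        a[1] * v[2] - a[2] * v[1])
    }, numeric(3)))
    B[, 3 + k] <- as.numeric(t(rot))
  }
  qr.Q(qr(B))
}

#' @export
print.mini_receptor <- function(x, ...) {
  cat(sprintf("<mini_receptor: %d atoms, barrier %.2g kcal/mol, asymmetry %.2g kcal/mol, %d noise modes>\n",
              nrow(x$inactive$coords), x$potential$params$barrier,
              x$potential$params$asymmetry, ncol(x$modes)))
  invisible(x)
}

#' Simulatable system over the mini-receptor's reduced coordinates
#'
#' Dynamical coordinates are `q = (u, y_1..y_m)`: `u` in \[-1, 1\] is the
#' activation progress (the double-well coordinate; the inactive state is
#' u = -1, the active u = +1) and `y` are the transverse mode amplitudes in
#' A.  Cartesian conformations are reconstructed linearly:
#' `x(q) = x_inactive + (u+1)/2 * delta + modes %*% y`.
#'
#' @param mr a [make_mini_receptor()] object.
#' @param observe if `TRUE`, record the three activation descriptors at
#'   every stored frame.
#' @return a `"dynamics_system"`.
#' @export
mini_receptor_system <- function(mr, observe = TRUE) {
  m <- ncol(mr$modes)
  d <- 1L + m
  pot <- mr$potential
  ks <- mr$mode_stiffness
  x0 <- as.numeric(t(mr$inactive$coords))
  n_atoms <- nrow(mr$inactive$coords)
  # 3N x d Jacobian of the (linear) coordinate map
  J <- cbind(mr$delta_coords / 2, mr$modes)
  tmpl <- mr$inactive
  conf_of <- function(q) {
    # J[, 1] holds delta/2, so (u + 1) * J[, 1] = delta * (u + 1)/2
    x <- x0 + drop(J %*% c(q[1] + 1, q[-1]))
    tmpl$coords <- matrix(x, ncol = 3, byrow = TRUE)
    tmpl
  }
  obs_fun <- if (observe) {
    function(q) {
      cf <- conf_of(q)
      activation_descriptors(cf, mr$inactive, mr$map,
                             align_mask = mr$align_mask)[c("d_il", "chi_ts", "delta_d_tm6")]
    }
  } else NULL
  structure(list(d = d, q0 = c(-1, rep(0, m)), masses = 1,
                 energy = function(q) pot$energy(q[1]) + 0.5 * ks * sum(q[-1]^2),
                 grad = function(q) c(pot$grad(q[1]), ks * q[-1]),
                 cv_dims = NULL, cv_names = NULL, cv = NULL,
                 observe = obs_fun,
                 conformation = conf_of, coord_jacobian = J,
                 mini_receptor = mr,
                 info = list(kind = "mini_receptor")),
            class = "dynamics_system")
}

#' Expose the path variables (s, z) as the system's biasing CVs
#'
#' Attaches a closure computing s, z and their exact gradients with respect
#' to the reduced coordinates (chain rule through the linear coordinate
#' map), enabling metadynamics on the path variables.
#'
#' @param system a `"dynamics_system"` with a `conformation` map (e.g. from
#'   [mini_receptor_system()]).
#' @param set a [path_reference_set()].
#' @return the system with `cv` installed (`cv_names = c("s", "z")`).
#' @export
attach_path_cv <- function(system, set) {
  if (is.null(system$conformation))
    abort_ap("system has no Cartesian conformation map")
  J <- system$coord_jacobian
  system$cv <- function(q) {
    cf <- system$conformation(q)
    r <- path_sz(cf$coords, set, grad = TRUE)
    gs <- as.numeric(t(r$grad_s)); gz <- as.numeric(t(r$grad_z))
    list(value = c(s = r$s, z = r$z),
         jac = rbind(s = drop(crossprod(J, gs)), z = drop(crossprod(J, gz))))
  }
  system$cv_names <- c("s", "z")
  system$cv_dims <- NULL
  system
}

#' Linearly interpolated trajectory between the end states
#'
#' Frame 1 is the exact inactive state and frame `n_frames` the exact
#' active state; interior frames add seeded Gaussian coordinate noise of
#' width `noise_sigma`.
#'
#' @param mr a [make_mini_receptor()].
#' @param n_frames number of frames (>= 2).
#' @param noise_sigma per-coordinate noise in A (default 0).
#' @param seed RNG seed for the noise.
#' @return list of [conformation()]s.
#' @export
interpolated_trajectory <- function(mr, n_frames, noise_sigma = 0, seed = 1) {
  if (n_frames < 2L) abort_ap("need at least two frames")
  set.seed(as.integer(seed))
  lam <- seq(0, 1, length.out = n_frames)
  lapply(seq_len(n_frames), function(i) {
    cf <- mr$inactive
    cf$coords <- (1 - lam[i]) * mr$inactive$coords + lam[i] * mr$active$coords
    if (noise_sigma > 0 && i > 1L && i < n_frames)
      cf$coords <- cf$coords + matrix(rnorm(length(cf$coords), sd = noise_sigma),
                                      ncol = 3)
    cf
  })
}
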