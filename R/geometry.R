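# Coordinate-level kernels: conformations, optimal superposition, RMSD,
# dihedrals, centroids.  Everything downstream (path CVs, descriptors,
# clustering) is built on these.

#' Labelled conformation
#'
#' A single frame of atomic coordinates with parallel per-atom annotation
#' vectors, the basic currency of the package.
#'
#' @param coords numeric N x 3 matrix of positions in Angstrom.
#' @param atom_names character vector of PDB-style atom names (default "CA").
#' @param residue_ids integer residue identifiers (default 1..N).
#' @param residue_names character residue names (default "GLY").
#' @param chain_ids character chain identifiers, recycled (default "A").
#' @param masses atomic masses in amu, recycled (default 1).
#' @return An object of class `"conformation"`.
#' @export
conformation <- function(coords, atom_names = NULL, residue_ids = NULL,
                         residue_names = NULL, chain_ids = "A", masses = 1) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    abort_ap("'coords' must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  n <- nrow(coords)
  if (n < 1L) abort_ap("a conformation needs at least one atom")
  if (!all(is.finite(coords))) abort_ap("coordinates must be finite")
  atom_names <- rep_len(as.character(atom_names %||% "CA"), n)
  residue_ids <- rep_len(as.integer(residue_ids %||% seq_len(n)), n)
  residue_names <- rep_len(as.character(residue_names %||% "GLY"), n)
  chain_ids <- rep_len(as.character(chain_ids), n)
  masses <- rep_len(as.numeric(masses), n)
  for (v in list(atom_names, residue_ids, residue_names, chain_ids, masses))
    if (length(v) != n) abort_ap("annotation vectors must have length N")
  structure(list(coords = coords, atom_names = atom_names,
                 residue_ids = residue_ids, residue_names = residue_names,
                 chain_ids = chain_ids, masses = masses),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation: %d atoms, %d residues, chains %s>\n",
              nrow(x$coords), length(unique(x$residue_ids)),
              paste(unique(x$chain_ids), collapse = ",")))
  invisible(x)
}

# Accept a conformation or a bare N x 3 matrix.
as_coords <- function(x) {
  if (inherits(x, "conformation")) return(x$coords)
  m <- as.matrix(x)
  if (ncol(m) != 3L) abort_ap("expected a conformation or an N x 3 matrix")
  storage.mode(m) <- "double"
  m
}

resolve_mask <- function(mask, n) {
  if (is.null(mask)) return(seq_len(n))
  if (is.logical(mask)) mask <- which(mask)
  mask <- as.integer(mask)
  if (length(mask) == 0L) abort_ap("mask selects no atoms")
  if (any(mask < 1L | mask > n))
    abort_ap(sprintf("mask index out of range 1..%d", n))
  mask
}

#' Optimal rigid-body superposition (Kabsch fit)
#'
#' Least-squares rigid transform mapping `mobile` onto `reference` over the
#' masked atoms, with reflection correction so the returned rotation is
#' always proper (det = +1).  Row-vector convention: aligned coordinates are
#' `coords %*% rotation + translation` (translation recycled over rows).
#'
#' @param mobile,reference conformations (or N x 3 matrices) with
#'   corresponding atoms.
#' @param mask optional integer/logical selection applied to both structures.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   and `rmsd` (post-fit RMSD over the masked atoms, in A).
#' @export
superpose <- function(mobile, reference, mask = NULL) {
  A <- as_coords(mobile); B <- as_coords(reference)
  if (nrow(A) != nrow(B))
    abort_ap("mobile and reference must have the same number of atoms")
  idx <- resolve_mask(mask, nrow(A))
  if (length(idx) < 3L)
    abort_ap("superposition needs at least 3 atoms", "actipath_geometry_error")
  A <- A[idx, , drop = FALSE]; B <- B[idx, , drop = FALSE]
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2L, cA); B0 <- sweep(B, 2L, cB)
  sv <- svd(crossprod(A0, B0)) # 3x3 covariance
  # degenerate selection: all masked atoms (near-)collinear in either frame
  rankish <- function(M) { s <- svd(M, nu = 0, nv = 0)$d; sum(s > 1e-8 * max(s, 1e-300)) }
  if (rankish(A0) < 2L || rankish(B0) < 2L)
    abort_ap("degenerate (collinear) atom selection", "actipath_geometry_error")
  s3 <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, s3)) %*% t(sv$v)
  Afit <- A0 %*% R
  rmsd <- sqrt(mean(rowSums((Afit - B0)^2)))
  list(rotation = R, translation = as.numeric(cB - drop(cA %*% R)), rmsd = rmsd)
}

#' Apply a rigid transform from [superpose()] to a conformation
#'
#' @param x conformation or N x 3 matrix.
#' @param fit list with `rotation` and `translation` as returned by
#'   [superpose()].
#' @return object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, fit) {
  co <- as_coords(x)
  out <- sweep(co %*% fit$rotation, 2L, -fit$translation)
  if (inherits(x, "conformation")) { x$coords <- out; x } else out
}

#' Root mean square deviation between two conformations
#'
#' @param a,b conformations (or N x 3 matrices) with corresponding atoms.
#' @param mask optional atom selection applied to both.
#' @param fit if `TRUE` (default) superpose `a` onto `b` over the mask first.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, mask = NULL, fit = TRUE) {
  A <- as_coords(a); B <- as_coords(b)
  if (nrow(A) != nrow(B))
    abort_ap("conformations must have the same number of atoms")
  idx <- resolve_mask(mask, nrow(A))
  if (fit) return(superpose(A, B, idx)$rmsd)
  d <- A[idx, , drop = FALSE] - B[idx, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: cis = 0 degrees, trans = 180 degrees; result in
#' (-180, 180].  Invariant under global rotation and translation.
#'
#' @param p1,p2,p3,p4 length-3 numeric vectors.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (min(sqrt(sum(b1^2)), sqrt(sum(b2^2)), sqrt(sum(b3^2))) < 1e-10)
    abort_ap("coincident consecutive points", "actipath_geometry_error")
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    abort_ap("collinear consecutive points", "actipath_geometry_error")
  m1 <- cross(b2 / sqrt(sum(b2^2)), n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Weighted centroid of selected atoms
#'
#' @param x conformation (or matrix; mass weighting then requires `masses`).
#' @param mask optional atom selection.
#' @param weighting `"uniform"` (default) or `"mass"`.
#' @param masses optional masses when `x` is a bare matrix.
#' @return length-3 position.
#' @export
centroid <- function(x, mask = NULL, weighting = c("uniform", "mass"),
                     masses = NULL) {
  weighting <- match.arg(weighting)
  co <- as_coords(x)
  idx <- resolve_mask(mask, nrow(co))
  w <- if (weighting == "mass") {
    m <- if (inherits(x, "conformation")) x$masses else masses
    if (is.null(m)) abort_ap("mass weighting requires masses")
    rep_len(m, nrow(co))[idx]
  } else rep(1, length(idx))
  drop(crossprod(co[idx, , drop = FALSE], w)) / sum(w)
}

# Gradient of the fitted RMSD between conf and ref over masked atoms, with
# respect to the masked coordinates of conf (envelope theorem at the optimal
# rotation).  Returns list(rmsd, grad) with grad an length(mask) x 3 matrix.
rmsd_fit_grad <- function(coords, ref_coords, mask) {
  A <- coords[mask, , drop = FALSE]; B <- ref_coords[mask, , drop = FALSE]
  fit <- superpose(A, B)
  Afit <- apply_transform(A, fit)
  n <- nrow(A)
  r <- fit$rmsd
  g <- if (r < 1e-10) matrix(0, n, 3) else ((Afit - B) %*% t(fit$rotation)) / (n * r)
  list(rmsd = r, grad = g, fit = fit)
}

# Gradient of squared fitted RMSD (the path-CV metric) wrt masked coords.
msd_fit_grad <- function(coords, ref_coords, mask) {
  A <- coords[mask, , drop = FALSE]; B <- ref_coords[mask, , drop = FALSE]
  fit <- superpose(A, B)
  Afit <- apply_transform(A, fit)
  n <- nrow(A)
  list(d = fit$rmsd^2, grad = (2 / n) * ((Afit - B) %*% t(fit$rotation)))
}

# NeRF-style internal-coordinate atom placement: position a new atom at
# distance `bond` from c, with angle `angle` (deg) at c relative to b-c, and
# dihedral `torsion` (deg) about the b-c axis relative to a.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
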