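# Path collective variables: progress s along, and distance z from, an
# ordered set of reference conformations R_1..R_n, with the squared fitted
# Calpha RMSD as metric:
#   s = sum_j (j-1) exp(-gamma d_j) / ((n-1) Z),  Z = sum_j exp(-gamma d_j)
#   z = -(1/gamma) log Z
# Both are evaluated through log-sum-exp so that well-separated references
# (gamma d >> 1) never underflow to non-finite values.

#' Ordered set of path reference conformations
#'
#' @param refs list of [conformation()]s (or N x 3 matrices), ordered from
#'   the inactive end (j = 1) to the active end (j = n).
#' @param gamma metric exponent in 1/A^2; default 4 (= 1/0.25).
#' @param mask atom selection used by the RMSD metric (e.g. CA atoms minus
#'   flexible loops); default all atoms.
#' @return object of class `"path_reference_set"`.
#' @export
path_reference_set <- function(refs, gamma = 4, mask = NULL) {
  if (!is.list(refs) || length(refs) < 1L)
    abort_ap("'refs' must be a non-empty list of conformations")
  check_scalar(gamma, "gamma")
  if (gamma <= 0) abort_ap("'gamma' must be positive")
  coords <- lapply(refs, as_coords)
  n_atoms <- vapply(coords, nrow, 1L)
  if (length(unique(n_atoms)) != 1L)
    abort_ap("all references must have the same number of atoms")
  idx <- resolve_mask(mask, n_atoms[1])
  # precompute centered masked reference coordinates for the fit kernel
  B0 <- lapply(coords, function(m) {
    b <- m[idx, , drop = FALSE]
    sweep(b, 2L, colMeans(b))
  })
  structure(list(refs = refs, coords = coords, gamma = gamma, mask = idx,
                 n = length(refs), B0 = B0),
            class = "path_reference_set")
}

#' @export
print.path_reference_set <- function(x, ...) {
  cat(sprintf("<path_reference_set: n = %d references, gamma = %g 1/A^2, %d masked atoms>\n",
              x$n, x$gamma, length(x$mask)))
  invisible(x)
}

# Vector of metric values d(conf, R_j) for all j (squared fitted RMSD, A^2);
# optionally with gradients wrt the masked coordinates.  Tight Kabsch kernel
# against the precomputed centered references (the reference set is
# validated once at construction, so no degeneracy checks here).
path_dists <- function(coords, set, grad = FALSE) {
  A <- coords[set$mask, , drop = FALSE]
  A0 <- sweep(A, 2L, colMeans(A))
  n <- nrow(A0)
  d <- numeric(set$n)
  grads <- if (grad) vector("list", set$n)
  for (j in seq_len(set$n)) {
    B0 <- set$B0[[j]]
    sv <- svd(crossprod(A0, B0))
    s3 <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(1, 1, s3)) %*% t(sv$v)
    diffm <- A0 %*% R - B0
    d[j] <- sum(diffm * diffm) / n
    if (grad) grads[[j]] <- (2 / n) * diffm %*% t(R)
  }
  list(d = d, grads = grads)
}

#' Metric underlying the path variables
#'
#' Squared fitted RMSD (over the set's mask) between a conformation and the
#' j-th reference.
#'
#' @param conf conformation or N x 3 matrix.
#' @param set a [path_reference_set()].
#' @param j reference index.
#' @return squared RMSD in A^2.
#' @export
path_metric <- function(conf, set, j) {
  j <- as.integer(j)
  if (j < 1L || j > set$n) abort_ap("reference index out of range")
  co <- as_coords(conf)
  superpose(co[set$mask, , drop = FALSE],
            set$coords[[j]][set$mask, , drop = FALSE])$rmsd^2
}

#' Path collective variables s and z of a conformation
#'
#' @param conf conformation or N x 3 matrix.
#' @param set a [path_reference_set()].
#' @param grad also return gradients of s and z with respect to the full
#'   coordinate matrix (zero rows off the mask).
#' @param convention `"span01"` (default; s = sum (j-1) e / ((n-1) Z), so
#'   s runs from 0 at R_1 to 1 at R_n) or `"index"` (unnormalized
#'   s = sum j e / Z, running from 1 to n).
#' @return list with `s` (dimensionless), `z` (A^2), `d` (per-reference
#'   metric values) and, if requested, `grad_s`/`grad_z` (N x 3 matrices).
#' @export
path_sz <- function(conf, set, grad = FALSE,
                    convention = c("span01", "index")) {
  convention <- match.arg(convention)
  co <- as_coords(conf)
  pd <- path_dists(co, set, grad = grad)
  d <- pd$d
  n <- set$n
  a <- -set$gamma * d
  m <- max(a)
  e <- exp(a - m)          # stable weights, max = 1
  Zs <- sum(e)
  p <- e / Zs              # normalized weights p_j
  jw <- if (convention == "span01") (seq_len(n) - 1) else seq_len(n)
  sbar <- sum(jw * p)
  s <- if (convention == "span01" && n > 1) sbar / (n - 1) else sbar
  z <- -(m + log(Zs)) / set$gamma
  out <- list(s = s, z = z, d = d)
  if (grad) {
    # ds/dd_j = gamma p_j (sbar - jw_j) / norm ; dz/dd_j = p_j
    norm <- if (convention == "span01" && n > 1) (n - 1) else 1
    dsdd <- set$gamma * p * (sbar - jw) / norm
    dzdd <- p
    nr <- nrow(co)
    gs <- matrix(0, nr, 3); gz <- matrix(0, nr, 3)
    for (j in seq_len(n)) {
      gs[set$mask, ] <- gs[set$mask, ] + dsdd[j] * pd$grads[[j]]
      gz[set$mask, ] <- gz[set$mask, ] + dzdd[j] * pd$grads[[j]]
    }
    out$grad_s <- gs; out$grad_z <- gz
  }
  out
}

#' Progress coordinate s along the path
#' @inheritParams path_sz
#' @return s, dimensionless (0 at R_1, 1 at R_n for the default convention).
#' @export
path_s <- function(conf, set, convention = "span01") {
  if (set$n < 2L) abort_ap("s needs at least two references")
  path_sz(conf, set, convention = convention)$s
}

#' Distance coordinate z from the path
#' @inheritParams path_sz
#' @return z in A^2 (can dip below 0 where references overlap).
#' @export
path_z <- function(conf, set) path_sz(conf, set)$z

#' Diagnostic report on a path reference set
#'
#' Checks that consecutive references are distinct and roughly equidistant,
#' recommends a metric exponent gamma of the order of the inverse mean
#' consecutive metric, and evaluates s and z at every reference.
#'
#' @param set a [path_reference_set()].
#' @return list of class `"path_report"` with elements `ok`, `problems`,
#'   `consecutive` (data.frame j, d), `cv_consecutive` (coefficient of
#'   variation of consecutive distances), `gamma_recommended`, and
#'   `at_refs` (data.frame j, s, z).
#' @export
validate_path <- function(set) {
  if (set$n < 2L) abort_ap("a path needs at least two references")
  dcons <- vapply(seq_len(set$n - 1L),
                  function(j) path_metric(set$coords[[j]], set, j + 1L), 0)
  problems <- character()
  if (any(dcons < 1e-10))
    problems <- c(problems, sprintf(
      "duplicate consecutive references (zero metric) at j = %s",
      paste(which(dcons < 1e-10), collapse = ",")))
  cvc <- stats::sd(dcons) / mean(dcons)
  at <- do.call(rbind, lapply(seq_len(set$n), function(j) {
    r <- path_sz(set$coords[[j]], set)
    data.frame(j = j, s = r$s, z = r$z)
  }))
  if (any(at$z < -0.05))
    problems <- c(problems, "z dips below -0.05 A^2 at some references (overlapping references)")
  if (any(diff(at$s) <= 0))
    problems <- c(problems, "s is not strictly increasing over the ordered references")
  structure(list(ok = length(problems) == 0L, problems = problems,
                 consecutive = data.frame(j = seq_len(set$n - 1L), d = dcons),
                 cv_consecutive = cvc,
                 gamma_recommended = 1 / mean(dcons),
                 at_refs = at),
            class = "path_report")
}

#' @export
print.path_report <- function(x, ...) {
  cat(sprintf("<path_report: %s>\n", if (x$ok) "OK" else "PROBLEMS"))
  for (p in x$problems) cat(" - ", p, "\n", sep = "")
  cat(sprintf("  consecutive metric: mean %.4g A^2 (cv %.3g); recommended gamma %.3g 1/A^2\n",
              mean(x$consecutive$d), x$cv_consecutive, x$gamma_recommended))
  invisible(x)
}
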