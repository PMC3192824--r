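# From ratchet-driven transition trajectories to an ordered set of path
# reference states: pool frames, build the fit-RMSD dissimilarity matrix,
# cluster by average linkage, cut the tree, and pick medoids homogeneously
# covering the pathway.

#' Pairwise fitted-RMSD dissimilarity matrix
#'
#' @param frames list of [conformation()]s (consistent atom ordering).
#' @param mask atom selection used for the fit and the RMSD.
#' @return symmetric n x n matrix of RMSDs in A, zero diagonal, with the
#'   frame names as dimnames.
#' @export
pairwise_rmsd <- function(frames, mask = NULL) {
  n <- length(frames)
  if (n < 2L) abort_ap("need at least two frames")
  co <- lapply(frames, as_coords)
  idx <- resolve_mask(mask, nrow(co[[1]]))
  sel <- lapply(co, function(m) m[idx, , drop = FALSE])
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- superpose(sel[[i]], sel[[j]])$rmsd
  dimnames(D) <- list(names(frames), names(frames))
  D
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' At each step the pair of clusters with the smallest mean inter-cluster
#' dissimilarity is merged; linkage heights are non-decreasing (average
#' linkage is monotone).  Flat clusters are obtained with
#' [stats::cutree()].
#'
#' @param dmat symmetric dissimilarity matrix (e.g. from [pairwise_rmsd()]).
#' @return an object of class `"hclust"`.
#' @export
average_linkage <- function(dmat) {
  dmat <- as.matrix(dmat)
  if (nrow(dmat) < 2L) abort_ap("clustering needs at least two items")
  if (max(abs(dmat - t(dmat))) > 1e-8 || any(diag(dmat) != 0))
    abort_ap("dissimilarity matrix must be symmetric with zero diagonal")
  stats::hclust(stats::as.dist(dmat), method = "average")
}

#' Select ordered path reference states from a cluster tree
#'
#' Cuts the tree into `k_cut` flat clusters, represents each by its medoid
#' (member with the smallest mean dissimilarity to its cluster), orders the
#' medoids by the progression coordinate `rmsd(., inactive) -
#' rmsd(., active)`, and picks `n_refs` medoids approximately equally
#' spaced in cumulative consecutive-RMSD arc length -- always including
#' the medoids nearest the two end states.  Reference j = 1 is nearest the
#' inactive state, j = n_refs nearest the active state.
#'
#' @param tree `"hclust"` object from [average_linkage()].
#' @param frames the clustered list of [conformation()]s.
#' @param dmat the dissimilarity matrix used for clustering.
#' @param k_cut number of flat clusters (default 30).
#' @param n_refs number of references to select (default 10).
#' @param inactive,active the end-state [conformation()]s.
#' @param gamma metric exponent for the returned reference set (1/A^2).
#' @param mask atom selection for the path metric (default the mask used
#'   implicitly by `dmat`, i.e. all atoms).
#' @return a [path_reference_set()] with attribute `"selection"` (data.frame
#'   of chosen frames, cluster ids and progression coordinates).
#' @export
select_references <- function(tree, frames, dmat, k_cut = 30L, n_refs = 10L,
                              inactive, active, gamma = 4, mask = NULL) {
  if (k_cut < n_refs || n_refs < 2L)
    abort_ap("need k_cut >= n_refs >= 2")
  dmat <- as.matrix(dmat)
  cl <- stats::cutree(tree, k = k_cut)
  ids <- sort(unique(cl))
  if (length(ids) < n_refs)
    abort_ap(sprintf("only %d occupied clusters for %d references",
                     length(ids), n_refs))
  medoid <- vapply(ids, function(g) {
    mem <- which(cl == g)
    mem[which.min(rowMeans(dmat[mem, mem, drop = FALSE]))]
  }, 1L)
  prog <- vapply(medoid, function(i)
    rmsd(frames[[i]], inactive, mask) - rmsd(frames[[i]], active, mask), 0)
  ord <- order(prog)
  medoid <- medoid[ord]; ids <- ids[ord]; prog <- prog[ord]
  # cumulative arc length over ordered medoids
  steps <- vapply(seq_len(length(medoid) - 1L),
                  function(i) dmat[medoid[i], medoid[i + 1L]], 0)
  arc <- c(0, cumsum(steps))
  # nearest-to-endpoint clusters are mandatory
  i_first <- which.min(vapply(medoid, function(i) rmsd(frames[[i]], inactive, mask), 0))
  i_last <- which.min(vapply(medoid, function(i) rmsd(frames[[i]], active, mask), 0))
  targets <- seq(arc[i_first], arc[i_last], length.out = n_refs)
  sel <- integer(n_refs)
  sel[1] <- i_first; sel[n_refs] <- i_last
  taken <- c(i_first, i_last)
  for (p in (if (n_refs > 2L) 2:(n_refs - 1L) else integer(0))) {
    cand <- order(abs(arc - targets[p]))
    cand <- cand[!(cand %in% taken)]
    sel[p] <- cand[1]
    taken <- c(taken, cand[1])
  }
  sel <- sort(sel)
  refs <- frames[medoid[sel]]
  out <- path_reference_set(refs, gamma = gamma, mask = mask)
  attr(out, "selection") <- data.frame(j = seq_len(n_refs),
                                       frame = medoid[sel],
                                       cluster = ids[sel],
                                       progression = prog[sel],
                                       arc = arc[sel])
  out
}

# chi(q) closure for ratchet runs: fitted CA RMSD (in nm) from the target,
# with the exact gradient chained through the system's linear coordinate map
make_chi <- function(system, target, mask) {
  if (is.null(system$conformation))
    abort_ap("ratchet runs need a system with a Cartesian conformation map")
  J <- system$coord_jacobian
  tco <- as_coords(target)
  function(q) {
    cf <- system$conformation(q)
    rg <- rmsd_fit_grad(cf$coords, tco, mask)
    g3n <- matrix(0, nrow(cf$coords), 3)
    g3n[mask, ] <- rg$grad
    list(value = rg$rmsd / 10,
         grad = drop(crossprod(J, as.numeric(t(g3n)))) / 10)
  }
}

#' Ratchet-driven (adiabatic biased) transition runs
#'
#' Runs `n_runs` independent Langevin simulations with the ratchet bias on
#' `chi`, the fitted CA RMSD (in nm) from the target conformation, steering
#' the system toward `chi0` (default 0, i.e. the target itself) without
#' ever pushing downhill motion.  Runs that stagnate (no improvement of the
#' running best over the final quarter of the trajectory while still far
#' from the target) are flagged but retained.
#'
#' @param system a `"dynamics_system"` with a conformation map.
#' @param target target [conformation()] (the active end state).
#' @param k ratchet elastic constant in kcal/(mol nm^2); k = 0 gives plain
#'   unbiased dynamics.
#' @param n_runs number of independent runs.
#' @param steps,dt,temperature,friction,integrator,stride see [run_langevin()].
#' @param seed base seed; run r uses `seed + r - 1`.
#' @param chi0 ratchet target value in nm.
#' @param mask atom selection defining chi (default: CA atoms of the
#'   system's mini-receptor excluding flexible-loop residues, or all atoms).
#' @return object of class `"abmd_pool"`: `runs` (list of `"abmd_run"`s),
#'   `frames` (pooled frame table with a `run` column), `flagged` (logical
#'   per run), plus the chi definition.
#' @export
run_abmd <- function(system, target, k = 10, n_runs = 10, steps = 20000L,
                     dt = 0.01, temperature = 300, friction = 1,
                     integrator = "baoab", seed = 1, stride = 10L,
                     chi0 = 0, mask = NULL) {
  if (is.null(mask))
    mask <- system$mini_receptor$ca_mask %||%
      seq_len(nrow(as_coords(target)))
  chi <- make_chi(system, target, mask)
  runs <- vector("list", n_runs)
  flagged <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    res <- .simulate(system, steps, dt, temperature, friction, integrator,
                     seed = seed + r - 1L, stride = stride,
                     ratchet = list(chi = chi, k = k, chi0 = chi0),
                     record_observables = FALSE)
    ch <- res$frames$chi
    n4 <- max(2L, length(ch) %/% 4L)
    tail_best <- min(utils::tail(ch, n4))
    earlier_best <- min(utils::head(ch, length(ch) - n4))
    flagged[r] <- k > 0 && tail_best >= earlier_best && ch[length(ch)] > 0.25 * ch[1]
    runs[[r]] <- res
  }
  pooled <- do.call(rbind, lapply(seq_len(n_runs), function(r)
    cbind(run = r, runs[[r]]$frames)))
  structure(list(runs = runs, frames = pooled, flagged = flagged,
                 chi0 = chi0, k = k, mask = mask, seed = seed),
            class = "abmd_pool")
}

#' Materialize pooled ratchet frames as conformations
#'
#' @param pool an `"abmd_pool"`.
#' @param system the `"dynamics_system"` the pool was generated with.
#' @param every keep every `every`-th pooled frame (default 1).
#' @return list of [conformation()]s with a `"provenance"` attribute
#'   (data.frame run, time).
#' @export
pool_conformations <- function(pool, system, every = 1L) {
  fr <- pool$frames[seq(1L, nrow(pool$frames), by = every), , drop = FALSE]
  qcols <- grep("^q[0-9]+$", names(fr), value = TRUE)
  confs <- lapply(seq_len(nrow(fr)), function(i)
    system$conformation(as.numeric(fr[i, qcols])))
  attr(confs, "provenance") <- fr[, c("run", "time")]
  confs
}
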