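# Unbiasing metadynamics trajectories: per-frame statistical weights that
# undo the applied bias, so free energies can be projected onto order
# parameters that were never biased directly.

#' Per-frame reweighting factors for a metadynamics trajectory
#'
#' Two schemes are provided and cross-validated in the test suite:
#' \describe{
#'   \item{`final_bias`}{`w_i` proportional to `exp(+V_final(cv_i)/kT)`, with
#'     the converged final bias evaluated at each frame's CV values.  Valid
#'     once the well-tempered bias has stopped evolving appreciably.}
#'   \item{`time_dependent`}{`w_i` proportional to
#'     `exp(+(V(cv_i, t_i) - c(t_i))/kT)`, using the instantaneous bias
#'     recorded with each frame and the running offset
#'     `c(t) = kT log( int e^{(g/(g-1)) V/kT} / int e^{V/((g-1) kT)} )`
#'     (g the bias factor) that keeps the normalization consistent while the
#'     bias still grows.  The integrals run over a grid spanning the
#'     deposited hills.}
#' }
#' Both sets of weights are normalized to mean 1.
#'
#' @param frames frame table from [run_metadynamics()]: must contain the CV
#'   columns named in the bias state, a `bias` column (instantaneous bias at
#'   the frame, kcal/mol) and a `time` column.
#' @param state the [bias_state()] of the run.
#' @param scheme `"final_bias"` (default) or `"time_dependent"`.
#' @return numeric vector of weights, mean 1.
#' @export
frame_weights <- function(frames, state,
                          scheme = c("final_bias", "time_dependent")) {
  scheme <- match.arg(scheme)
  kT <- .kB * state$cfg$temperature
  cvm <- as.matrix(frames[, state$cv_names, drop = FALSE])
  if (scheme == "final_bias") {
    V <- evaluate_bias(state, cvm)
    if (any(!is.finite(V))) abort_ap("non-finite bias at some frames")
    logw <- V / kT
  } else {
    V <- frames$bias
    if (is.null(V) || any(!is.finite(V)))
      abort_ap("time_dependent scheme needs a finite 'bias' column")
    ct <- ct_offset(state, frames$time)
    logw <- (V - ct) / kT
  }
  w <- exp(logw - max(logw))
  w / mean(w)
}

# Running well-tempered normalization offset c(t), evaluated at the given
# times by replaying the hills over a grid spanning their support.
ct_offset <- function(state, times, n = 120L) {
  cfg <- state$cfg
  kT <- .kB * cfg$temperature
  g <- cfg$bias_factor
  a <- if (is.infinite(g)) 1 else g / (g - 1)   # = (T+dT)/dT
  b <- if (is.infinite(g)) 0 else 1 / (g - 1)   # = T/dT
  centers <- hill_centers(state)
  if (nrow(centers) == 0L) return(rep(0, length(times)))
  sig <- as.numeric(cfg$sigma)
  k <- ncol(centers)
  npts <- if (k == 1L) n else 60L
  grid <- lapply(seq_len(k), function(i)
    seq(min(centers[, i]) - 3 * sig[i], max(centers[, i]) + 3 * sig[i],
        length.out = npts))
  V <- if (k == 1L) numeric(npts) else matrix(0, npts, npts)
  ord <- order(times)
  out <- numeric(length(times))
  htimes <- state$hills$time
  hseq <- order(htimes)
  hptr <- 0L
  for (fi in ord) {
    tt <- times[fi]
    while (hptr < length(hseq) && htimes[hseq[hptr + 1L]] <= tt) {
      hptr <- hptr + 1L
      m <- hseq[hptr]
      V <- V + bias_on_grid(centers[m, , drop = FALSE],
                            state$hills$height[m], sig, grid)
    }
    v <- as.numeric(V)
    out[fi] <- kT * (logsumexp(a * v / kT) - logsumexp(b * v / kT))
  }
  out
}

#' Population of a region of an order parameter, with a block-based error
#'
#' Weighted fraction of frames falling inside `region`, with a standard
#' error from non-overlapping block averages (accounts for the serial
#' correlation of trajectory frames).
#'
#' @param x per-frame order-parameter values.
#' @param weights per-frame weights (default uniform).
#' @param region `c(lo, hi)`.
#' @param nblocks number of blocks (default 20).
#' @return list with `p` (weighted population) and `se` (block standard
#'   error).
#' @export
population_estimate <- function(x, weights = NULL, region, nblocks = 20L) {
  n <- length(x)
  w <- weights %||% rep(1, n)
  ind <- as.numeric(x >= region[1] & x <= region[2])
  p <- sum(w * ind) / sum(w)
  bl <- pmin(ceiling(seq_len(n) / (n / nblocks)), nblocks)
  pb <- vapply(seq_len(nblocks), function(b) {
    sel <- bl == b
    if (!any(sel) || sum(w[sel]) == 0) return(NA_real_)
    sum(w[sel] * ind[sel]) / sum(w[sel])
  }, 0)
  pb <- pb[is.finite(pb)]
  list(p = p, se = stats::sd(pb) / sqrt(length(pb)))
}
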