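# The two bias rules: the ratchet-and-pawl (adiabatic biased MD) harmonic
# bias, and well-tempered metadynamics hill bookkeeping with the standard
# free-energy estimator F = -(T + dT)/dT * V.

#' Well-tempered metadynamics configuration
#'
#' @param w initial (maximum) Gaussian hill height, kcal/mol.  `w = 0`
#'   switches the bias off (useful for unbiased control runs).
#' @param tau hill deposition interval in ps.
#' @param delta_T well-tempering temperature offset dT in K; default
#'   `10 * temperature`.  `Inf` recovers standard (non-tempered)
#'   metadynamics with constant hill height.
#' @param temperature simulation temperature T in K.
#' @param sigma named vector of Gaussian widths per collective variable,
#'   default `c(s = 0.1, z = 1)` (dimensionless and A^2 respectively).
#' @return object of class `"wt_config"` with derived `bias_factor`
#'   `(T + dT)/T`.
#' @export
wt_config <- function(w = 0.4, tau = 8, delta_T = NULL, temperature = 300,
                      sigma = c(s = 0.1, z = 1)) {
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0)
    abort_ap("'w' must be a single number >= 0", "actipath_config_error")
  check_scalar(tau, "tau"); check_scalar(temperature, "temperature")
  if (tau <= 0 || temperature <= 0)
    abort_ap("'tau' and 'temperature' must be positive", "actipath_config_error")
  delta_T <- delta_T %||% (10 * temperature)
  if (!is.numeric(delta_T) || length(delta_T) != 1L || delta_T <= 0)
    abort_ap("'delta_T' must be positive (possibly Inf)", "actipath_config_error")
  if (any(sigma <= 0)) abort_ap("'sigma' must be positive", "actipath_config_error")
  structure(list(w = w, tau = tau, delta_T = delta_T,
                 temperature = temperature, sigma = sigma,
                 bias_factor = (temperature + delta_T) / temperature),
            class = "wt_config")
}

# prefactor (T + dT)/dT relating free energy to the converged bias
wt_prefactor <- function(cfg) {
  if (is.infinite(cfg$delta_T)) 1 else
    (cfg$temperature + cfg$delta_T) / cfg$delta_T
}

#' Ratchet (adiabatic bias) state
#'
#' Tracks the running minimum of `chi - chi0`; the harmonic penalty acts
#' only when the order parameter exceeds its best value so far.
#'
#' @param chi_init initial value of the order parameter chi.
#' @param chi0 target value chi_0 (default 0).
#' @param k elastic constant in kcal/(mol unit^2); `k = 0` disables the
#'   bias, negative values are rejected.
#' @return object of class `"ratchet_state"`.
#' @export
ratchet_state <- function(chi_init, chi0 = 0, k = 10) {
  check_scalar(chi_init, "chi_init"); check_scalar(chi0, "chi0")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0)
    abort_ap("ratchet elastic constant k must be >= 0", "actipath_config_error")
  structure(list(chi0 = chi0, k = k, running_best = chi_init - chi0),
            class = "ratchet_state")
}

#' One ratchet-bias evaluation
#'
#' If `chi - chi0` is no worse than the running best, the bias is zero and
#' the running best is updated; otherwise a harmonic penalty
#' `0.5 k (chi - chi0 - best)^2` applies and the best is unchanged.
#'
#' @param chi current order-parameter value.
#' @param state a [ratchet_state()].
#' @return list with `energy` (kcal/mol), `force_coefficient`
#'   (`dE/dchi = k * excess`), and the updated `state`.
#' @export
ratchet_bias <- function(chi, state) {
  excess <- (chi - state$chi0) - state$running_best
  if (excess <= 0) {
    state$running_best <- chi - state$chi0
    list(energy = 0, force_coefficient = 0, state = state)
  } else {
    list(energy = 0.5 * state$k * excess^2,
         force_coefficient = state$k * excess, state = state)
  }
}

#' Well-tempered hill height
#'
#' `w * exp(-V(center)/(kB dT))`: strictly decreasing in the bias already
#' accumulated at the deposition point.
#'
#' @param bias_at_center accumulated bias at the new hill's center, kcal/mol.
#' @param cfg a [wt_config()].
#' @return hill height in kcal/mol.
#' @export
wt_hill_height <- function(bias_at_center, cfg) {
  if (bias_at_center < 0) abort_ap("bias_at_center must be >= 0")
  cfg$w * exp(-bias_at_center / (.kB * cfg$delta_T))
}

#' Empty metadynamics bias state
#'
#' @param cfg a [wt_config()].
#' @param cv_names names of the biased collective variables (defaults to the
#'   names of `cfg$sigma`).
#' @return object of class `"bias_state"` holding an (initially empty)
#'   ordered hill list.
#' @export
bias_state <- function(cfg, cv_names = names(cfg$sigma)) {
  k <- length(cfg$sigma)
  cv_names <- cv_names %||% paste0("cv", seq_len(k))
  hills <- as.data.frame(matrix(numeric(0), 0, 2 * k + 3))
  names(hills) <- c("time", cv_names, paste0("sigma_", cv_names),
                    "height", "biasf")
  structure(list(cfg = cfg, cv_names = cv_names, hills = hills),
            class = "bias_state")
}

hill_centers <- function(state) {
  as.matrix(state$hills[, state$cv_names, drop = FALSE])
}

#' Deposit one Gaussian hill
#'
#' The height follows the well-tempered rule evaluated at the accumulated
#' bias at the new center (exact hill summation).
#'
#' @param state a [bias_state()].
#' @param cv numeric vector of current collective-variable values.
#' @param time deposition time in ps.
#' @return the updated [bias_state()].
#' @export
deposit_hill <- function(state, cv, time) {
  cv <- as.numeric(cv)
  if (length(cv) != length(state$cv_names) || !all(is.finite(cv)))
    abort_ap("non-finite or wrong-length CV vector for hill deposition")
  h <- wt_hill_height(evaluate_bias(state, cv), state$cfg)
  row <- as.data.frame(as.list(c(time, cv, as.numeric(state$cfg$sigma), h,
                                 state$cfg$bias_factor)))
  names(row) <- names(state$hills)
  state$hills <- rbind(state$hills, row)
  state
}

#' Evaluate the metadynamics bias potential
#'
#' Exact summation over all deposited Gaussians.
#'
#' @param state a [bias_state()].
#' @param cv numeric vector of CV values, or a matrix with one point per row.
#' @return bias in kcal/mol (vector for matrix input).
#' @export
evaluate_bias <- function(state, cv) {
  centers <- hill_centers(state)
  sig <- as.numeric(state$cfg$sigma)
  pts <- if (is.matrix(cv)) cv else matrix(as.numeric(cv), nrow = 1)
  if (ncol(pts) != length(state$cv_names))
    abort_ap("CV dimension mismatch with bias state")
  out <- numeric(nrow(pts))
  if (nrow(centers) == 0L) return(if (is.matrix(cv)) out else out[1])
  h <- state$hills$height
  for (i in seq_len(nrow(pts))) {
    z2 <- 0
    for (k in seq_along(sig))
      z2 <- z2 + ((centers[, k] - pts[i, k]) / sig[k])^2
    out[i] <- sum(h * exp(-0.5 * z2))
  }
  if (is.matrix(cv)) out else out[1]
}

#' Analytic gradient of the bias potential
#'
#' @inheritParams evaluate_bias
#' @param cv numeric vector (single point).
#' @return gradient dV/dcv, one component per collective variable.
#' @export
bias_gradient <- function(state, cv) {
  centers <- hill_centers(state)
  sig <- as.numeric(state$cfg$sigma)
  cv <- as.numeric(cv)
  g <- numeric(length(sig))
  if (nrow(centers) == 0L) return(g)
  z2 <- 0
  for (k in seq_along(sig))
    z2 <- z2 + ((centers[, k] - cv[k]) / sig[k])^2
  gauss <- state$hills$height * exp(-0.5 * z2)
  for (k in seq_along(sig))
    g[k] <- sum(gauss * (centers[, k] - cv[k]) / sig[k]^2)
  g
}

#' Free-energy estimate from the accumulated bias
#'
#' Well-tempered estimator `F(cv) = -(T + dT)/dT * V(cv, t_final)`, shifted
#' so the minimum over the evaluated grid is zero.
#'
#' @param state a [bias_state()] with at least one hill.
#' @param grid list of per-CV axis vectors at which to evaluate; default a
#'   regular grid spanning the hills +/- 3 sigma (200 points per axis in 1D,
#'   80 in 2D).
#' @param average_tail fraction of the run (by hill time, from the end) over
#'   which to time-average the bias before applying the estimator.  The
#'   default 0 uses the instantaneous final bias, `F = -(T+dT)/dT * V(t_end)`
#'   exactly; a value like 0.5 damps the slowly decaying deposition
#'   transient and the hill-by-hill ripple of well-tempered runs (a standard
#'   convergence device) without changing the asymptotic estimate.
#' @return a `"fes"` object (see [project_fes()]).
#' @export
free_energy_estimate <- function(state, grid = NULL, average_tail = 0) {
  if (nrow(state$hills) == 0L)
    abort_ap("free_energy_estimate needs at least one hill")
  if (average_tail < 0 || average_tail >= 1)
    abort_ap("'average_tail' must be in [0, 1)")
  centers <- hill_centers(state)
  sig <- as.numeric(state$cfg$sigma)
  k <- length(sig)
  if (is.null(grid)) {
    npts <- if (k == 1L) 200L else 80L
    grid <- lapply(seq_len(k), function(i)
      seq(min(centers[, i]) - 3 * sig[i], max(centers[, i]) + 3 * sig[i],
          length.out = npts))
  }
  heights <- state$hills$height
  if (average_tail > 0) {
    # <V>_t over the window [t1, t_end]: hill m contributes for the fraction
    # of the window during which it already existed
    tend <- max(state$hills$time)
    win <- average_tail * tend
    heights <- heights * pmin(pmax((tend - state$hills$time) / win, 0), 1)
  }
  V <- bias_on_grid(centers, heights, sig, grid)
  F <- -wt_prefactor(state$cfg) * V
  F <- F - min(F)
  new_fes(axes = lapply(seq_len(k), function(i)
            list(name = state$cv_names[i], mids = grid[[i]])),
          F = F, occupied = array(TRUE, dim(as.array(F)) %||% length(F)),
          kT = .kB * state$cfg$temperature,
          origin = "well-tempered bias estimate")
}

# Sum hills on a separable grid (1D vector or 2D matrix result).
bias_on_grid <- function(centers, heights, sig, grid) {
  k <- length(grid)
  if (k == 1L) {
    V <- numeric(length(grid[[1]]))
    for (m in seq_along(heights))
      V <- V + heights[m] * exp(-0.5 * ((grid[[1]] - centers[m, 1]) / sig[1])^2)
    V
  } else if (k == 2L) {
    V <- matrix(0, length(grid[[1]]), length(grid[[2]]))
    for (m in seq_along(heights)) {
      ex <- exp(-0.5 * ((grid[[1]] - centers[m, 1]) / sig[1])^2)
      ey <- exp(-0.5 * ((grid[[2]] - centers[m, 2]) / sig[2])^2)
      V <- V + heights[m] * outer(ex, ey)
    }
    V
  } else abort_ap("bias grids support 1 or 2 collective variables")
}

#' Convergence of a free-energy difference between two CV regions
#'
#' Re-estimates the free energy from the hills deposited up to each
#' checkpoint time and reports the Boltzmann-integrated free-energy
#' difference between two regions along one collective variable, plus the
#' trailing fluctuation amplitude (max deviation from the final value over
#' the second half of the checkpoints).
#'
#' @param state a [bias_state()].
#' @param checkpoints vector of times (ps), at least 2.
#' @param region_a,region_b length-2 ranges `c(lo, hi)` of the monitored CV.
#' @param dim index of the monitored CV (default 1).
#' @param n grid resolution (default 200).
#' @return list with `series` (data.frame time, delta_f) and
#'   `trailing_amplitude` (kcal/mol).
#' @export
convergence_monitor <- function(state, checkpoints, region_a, region_b,
                                dim = 1L, n = 200L) {
  if (length(checkpoints) < 2L) abort_ap("need at least two checkpoints")
  if (diff(region_a) <= 0 || diff(region_b) <= 0)
    abort_ap("regions must be non-empty ranges c(lo, hi)")
  centers <- hill_centers(state)
  sig <- as.numeric(state$cfg$sigma)
  ax <- seq(min(centers[, dim]) - 3 * sig[dim],
            max(centers[, dim]) + 3 * sig[dim], length.out = n)
  kT <- .kB * state$cfg$temperature
  pref <- wt_prefactor(state$cfg)
  dF <- vapply(checkpoints, function(tc) {
    keep <- state$hills$time <= tc
    if (!any(keep)) return(NA_real_)
    # marginal bias along the monitored CV: other CVs integrated by
    # projecting hills (separable Gaussians integrate to a constant factor)
    V <- bias_on_grid(centers[keep, dim, drop = FALSE],
                      state$hills$height[keep], sig[dim], list(ax))
    F <- -pref * V
    fa <- F[ax >= region_a[1] & ax <= region_a[2]]
    fb <- F[ax >= region_b[1] & ax <= region_b[2]]
    if (!length(fa) || !length(fb)) abort_ap("empty CV region")
    (-kT * logsumexp(-fa / kT)) - (-kT * logsumexp(-fb / kT))
  }, 0)
  tailn <- max(2L, ceiling(length(dF) / 2))
  trailing <- max(abs(utils::tail(dF, tailn) - dF[length(dF)]), na.rm = TRUE)
  list(series = data.frame(time = checkpoints, delta_f = dF),
       trailing_amplitude = trailing)
}
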