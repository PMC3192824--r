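# Seedable Langevin dynamics over low-dimensional toy systems, with
# optional well-tempered metadynamics or ratchet biasing.  One code path
# serves every bias setting and consumes the random-number stream
# identically, so w = 0 (metadynamics) and k = 0 (ratchet) reproduce the
# unbiased trajectory bit-exactly at a fixed seed.
#
# The per-step bias force is interpolated from fine gradient grids
# (spacing sigma/5, auto-expanding so hills are never truncated silently);
# hill heights and all recorded bias values use exact hill summation.

.simulate <- function(system, steps, dt, temperature = 300, friction = 1,
                      integrator = c("baoab", "overdamped"), seed = 1,
                      stride = 10L, metad = NULL, ratchet = NULL,
                      walls = NULL, record_observables = TRUE) {
  integrator <- match.arg(integrator)
  if (steps < 0 || dt <= 0) abort_ap("'steps' must be >= 0 and 'dt' > 0")
  d <- system$d
  q <- as.numeric(system$q0)
  mvec <- rep_len(as.numeric(system$masses %||% 1), d)
  kT <- .kB * temperature
  gradU <- system$grad
  obsfun <- if (record_observables) system$observe else NULL
  stride <- max(1L, as.integer(stride))
  steps <- as.integer(steps)

  # ---- collective variables -------------------------------------------
  cv_closure <- system$cv
  cv_dims <- if (is.null(cv_closure)) system$cv_dims else NULL
  use_cv <- !is.null(cv_closure) || !is.null(cv_dims)
  cv_names <- if (!is.null(cv_closure)) system$cv_names
              else if (!is.null(cv_dims)) (system$cv_names %||% paste0("q", cv_dims))
              else character()
  k_cv <- length(cv_names)
  cur_cv <- rep(NA_real_, k_cv); cur_jac <- NULL
  eval_cv <- function() {
    if (!is.null(cv_closure)) {
      r <- cv_closure(q); cur_cv <<- as.numeric(r$value); cur_jac <<- r$jac
    } else cur_cv <<- q[cv_dims]
  }

  # ---- walls on CVs ----------------------------------------------------
  use_walls <- !is.null(walls) && use_cv
  if (use_walls) {
    wlo <- rep(-Inf, k_cv); whi <- rep(Inf, k_cv)
    for (i in seq_len(k_cv)) {
      v <- walls$lo[cv_names[i]]
      wlo[i] <- if (length(v) == 0L || is.na(v)) -Inf else v
      v <- walls$hi[cv_names[i]]
      whi[i] <- if (length(v) == 0L || is.na(v)) Inf else v
    }
    wk <- walls$k %||% 100
    wall_grad <- function(cc) {
      g <- numeric(k_cv)
      below <- cc < wlo; above <- cc > whi
      if (any(below)) g[below] <- -4 * wk * (wlo[below] - cc[below])^3
      if (any(above)) g[above] <- 4 * wk * (cc[above] - whi[above])^3
      g
    }
  }

  # ---- metadynamics bookkeeping ---------------------------------------
  use_metad <- !is.null(metad)
  nh <- 0L
  if (use_metad) {
    cfg <- metad$cfg
    if (!use_cv) abort_ap("metadynamics needs collective variables")
    sigv <- as.numeric(rep_len(cfg$sigma, k_cv))
    pace <- max(1L, as.integer(metad$pace %||% round(cfg$tau / dt)))
    maxh <- as.integer(steps %/% pace) + 1L
    Cmat <- matrix(NA_real_, max(maxh, 1L), k_cv)
    Hvec <- numeric(max(maxh, 1L)); Tvec <- numeric(max(maxh, 1L))
    gdx <- sigv / 5
    gax <- vector("list", k_cv)
    eval_cv()
    for (i in seq_len(k_cv)) {
      lo <- cur_cv[i] - 8 * sigv[i]; hi <- cur_cv[i] + 8 * sigv[i]
      if (use_walls) {
        if (is.finite(wlo[i])) lo <- min(lo, wlo[i] - 3 * sigv[i])
        if (is.finite(whi[i])) hi <- max(hi, whi[i] + 3 * sigv[i])
      }
      gax[[i]] <- seq(lo, hi, by = gdx[i])
    }
    gn <- vapply(gax, length, 1L)
    dV <- lapply(seq_len(k_cv), function(i)
      if (k_cv == 1L) numeric(gn[1]) else matrix(0, gn[1], gn[2]))
    add_hill_grid <- function(cc, h) {
      if (k_cv == 1L) {
        e <- h * exp(-0.5 * ((gax[[1]] - cc[1]) / sigv[1])^2)
        dV[[1]] <<- dV[[1]] + e * (cc[1] - gax[[1]]) / sigv[1]^2
      } else {
        ex <- h * exp(-0.5 * ((gax[[1]] - cc[1]) / sigv[1])^2)
        ey <- exp(-0.5 * ((gax[[2]] - cc[2]) / sigv[2])^2)
        dV[[1]] <<- dV[[1]] + outer(ex * (cc[1] - gax[[1]]) / sigv[1]^2, ey)
        dV[[2]] <<- dV[[2]] + outer(ex, ey * (cc[2] - gax[[2]]) / sigv[2]^2)
      }
    }
    expand_grid <- function(i, cvi) {
      span <- diff(range(gax[[i]]))
      lo <- min(gax[[i]][1], cvi - 0.25 * span)
      hi <- max(gax[[i]][gn[i]], cvi + 0.25 * span)
      gax[[i]] <<- seq(lo, hi, by = gdx[i])
      gn <<- vapply(gax, length, 1L)
      for (j in seq_len(k_cv))
        dV[[j]] <<- if (k_cv == 1L) numeric(gn[1]) else matrix(0, gn[1], gn[2])
      for (m in seq_len(nh)) add_hill_grid(Cmat[m, ], Hvec[m])
    }
    exact_bias <- function(cc) {
      if (nh == 0L) return(0)
      z2 <- 0
      for (i in seq_len(k_cv))
        z2 <- z2 + ((Cmat[seq_len(nh), i] - cc[i]) / sigv[i])^2
      sum(Hvec[seq_len(nh)] * exp(-0.5 * z2))
    }
    kBdT <- .kB * cfg$delta_T
    deposit <- function(tnow) {
      cc <- cur_cv
      if (any(!is.finite(cc)))
        abort_ap(sprintf("non-finite CV at t = %g ps", tnow),
                 "actipath_integration_error")
      h <- cfg$w * exp(-exact_bias(cc) / kBdT)
      nh <<- nh + 1L
      Cmat[nh, ] <<- cc; Hvec[nh] <<- h; Tvec[nh] <<- tnow
      if (h != 0) add_hill_grid(cc, h)
    }
    grid_grad <- function(cc) {
      for (i in seq_len(k_cv))
        if (cc[i] <= gax[[i]][1] || cc[i] >= gax[[i]][gn[i]])
          expand_grid(i, cc[i])
      if (k_cv == 1L) {
        tt <- (cc[1] - gax[[1]][1]) / gdx[1]
        i0 <- min(max(floor(tt), 0), gn[1] - 2)
        u <- tt - i0
        dV[[1]][i0 + 1] * (1 - u) + dV[[1]][i0 + 2] * u
      } else {
        t1 <- (cc[1] - gax[[1]][1]) / gdx[1]
        i1 <- min(max(floor(t1), 0), gn[1] - 2); u1 <- t1 - i1
        t2 <- (cc[2] - gax[[2]][1]) / gdx[2]
        i2 <- min(max(floor(t2), 0), gn[2] - 2); u2 <- t2 - i2
        vapply(dV, function(A) {
          A[i1 + 1, i2 + 1] * (1 - u1) * (1 - u2) +
          A[i1 + 2, i2 + 1] * u1 * (1 - u2) +
          A[i1 + 1, i2 + 2] * (1 - u1) * u2 +
          A[i1 + 2, i2 + 2] * u1 * u2
        }, 0)
      }
    }
  } else pace <- NA_integer_

  # ---- ratchet ---------------------------------------------------------
  use_ratchet <- !is.null(ratchet)
  if (use_ratchet) {
    chi_fun <- ratchet$chi   # function(q) -> list(value, grad [length d])
    r_k <- ratchet$k; r_chi0 <- ratchet$chi0 %||% 0
    if (!is.numeric(r_k) || r_k < 0)
      abort_ap("ratchet elastic constant k must be >= 0", "actipath_config_error")
    r_best <- chi_fun(q)$value - r_chi0
  }
  cur_chi <- NA_real_

  # ---- force -----------------------------------------------------------
  f <- numeric(d)
  compute_force <- function() {
    ff <- -gradU(q)
    if (use_cv) {
      eval_cv()
      if (use_metad || use_walls) {
        dEdcv <- numeric(k_cv)
        if (use_metad && nh > 0L) dEdcv <- dEdcv + grid_grad(cur_cv)
        if (use_walls) dEdcv <- dEdcv + wall_grad(cur_cv)
        if (any(dEdcv != 0)) {
          if (!is.null(cv_closure)) ff <- ff - drop(crossprod(cur_jac, dEdcv))
          else ff[cv_dims] <- ff[cv_dims] - dEdcv
        }
      }
    }
    if (use_ratchet) {
      ch <- chi_fun(q)
      cur_chi <<- ch$value
      excess <- (ch$value - r_chi0) - r_best
      if (excess <= 0) r_best <<- ch$value - r_chi0
      else if (r_k > 0) ff <- ff - (r_k * excess) * ch$grad
    }
    f <<- ff
  }

  # ---- frame storage ---------------------------------------------------
  nfr <- steps %/% stride + 1L
  Ft <- numeric(nfr); Fq <- matrix(NA_real_, nfr, d)
  Fcv <- if (k_cv) matrix(NA_real_, nfr, k_cv) else NULL
  Fb <- if (use_metad) numeric(nfr) else NULL
  Fchi <- if (use_ratchet) numeric(nfr) else NULL
  obs0 <- if (!is.null(obsfun)) obsfun(q) else NULL
  Fobs <- if (!is.null(obs0)) matrix(NA_real_, nfr, length(obs0)) else NULL
  ifr <- 0L
  record <- function(tnow) {
    ifr <<- ifr + 1L
    Ft[ifr] <<- tnow; Fq[ifr, ] <<- q
    if (k_cv) Fcv[ifr, ] <<- cur_cv
    if (use_metad) Fb[ifr] <<- exact_bias(cur_cv)
    if (use_ratchet) Fchi[ifr] <<- cur_chi
    if (!is.null(Fobs)) Fobs[ifr, ] <<- obsfun(q)
  }

  # ---- noise stream (chunked, independent of bias settings) ------------
  set.seed(as.integer(seed))
  CH <- 16384L
  nbuf <- NULL; nptr <- CH
  next_noise <- function() {
    if (nptr == CH) { nbuf <<- matrix(rnorm(d * CH), d, CH); nptr <<- 0L }
    nptr <<- nptr + 1L
    nbuf[, nptr]
  }

  compute_force()
  record(0)

  if (integrator == "baoab") {
    p <- numeric(d)
    aa <- exp(-friction * dt)
    bb <- sqrt(kT * (1 - aa * aa) * mvec)
    half <- 0.5 * dt
    for (s in seq_len(steps)) {
      p <- p + half * f
      q <- q + half * p / mvec
      p <- aa * p + bb * next_noise()
      q <- q + half * p / mvec
      compute_force()
      p <- p + half * f
      if (use_metad && s %% pace == 0L) deposit(s * dt)
      if (s %% stride == 0L) record(s * dt)
      if (s %% 512L == 0L && !all(is.finite(q)))
        abort_ap(sprintf("integration diverged near t = %g ps", s * dt),
                 "actipath_integration_error")
    }
  } else {
    mob <- 1 / (mvec * friction)
    pref <- mob * dt
    nsd <- sqrt(2 * kT * mob * dt)
    for (s in seq_len(steps)) {
      q <- q + pref * f + nsd * next_noise()
      compute_force()
      if (use_metad && s %% pace == 0L) deposit(s * dt)
      if (s %% stride == 0L) record(s * dt)
      if (s %% 512L == 0L && !all(is.finite(q)))
        abort_ap(sprintf("integration diverged near t = %g ps", s * dt),
                 "actipath_integration_error")
    }
  }
  if (!all(is.finite(q)))
    abort_ap("integration diverged (non-finite final coordinates)",
             "actipath_integration_error")

  frames <- data.frame(time = Ft[seq_len(ifr)])
  if (k_cv) for (i in seq_len(k_cv)) frames[[cv_names[i]]] <- Fcv[seq_len(ifr), i]
  if (use_metad) frames$bias <- Fb[seq_len(ifr)]
  if (use_ratchet) frames$chi <- Fchi[seq_len(ifr)]
  if (!is.null(Fobs))
    for (i in seq_along(obs0)) frames[[names(obs0)[i]]] <- Fobs[seq_len(ifr), i]
  for (i in seq_len(d)) frames[[paste0("q", i)]] <- Fq[seq_len(ifr), i]

  out <- list(frames = frames, seed = as.integer(seed), dt = dt,
              steps = steps, stride = stride, temperature = temperature,
              friction = friction, integrator = integrator,
              system_info = system$info)
  if (use_metad) {
    st <- bias_state(cfg, cv_names)
    if (nh > 0L) {
      hdf <- data.frame(time = Tvec[seq_len(nh)])
      for (i in seq_len(k_cv)) hdf[[cv_names[i]]] <- Cmat[seq_len(nh), i]
      for (i in seq_len(k_cv)) hdf[[paste0("sigma_", cv_names[i])]] <- sigv[i]
      hdf$height <- Hvec[seq_len(nh)]
      hdf$biasf <- cfg$bias_factor
      st$hills <- hdf
    }
    out$bias <- st
    out$hills <- st$hills
    out$cfg <- cfg
    out$pace <- pace
    out$walls <- walls
    class(out) <- c("metad_run", "sim_run")
  } else if (use_ratchet) {
    out$ratchet <- list(k = r_k, chi0 = r_chi0, running_best = r_best)
    class(out) <- c("abmd_run", "sim_run")
  } else class(out) <- c("langevin_run", "sim_run")
  out
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<%s: %d steps, dt %g ps, T %g K, seed %d, %d frames%s>\n",
              class(x)[1], x$steps, x$dt, x$temperature, x$seed,
              nrow(x$frames),
              if (!is.null(x$hills)) sprintf(", %d hills", nrow(x$hills)) else ""))
  invisible(x)
}

#' Unbiased Langevin dynamics of a toy system
#'
#' BAOAB (inertial, default) or Euler-Maruyama overdamped integration at
#' constant temperature; fully reproducible for a given seed (the same
#' seed yields a bit-identical trajectory).
#'
#' @param system a `"dynamics_system"` (from [potential_system()] or
#'   [mini_receptor_system()]).
#' @param steps number of integration steps.
#' @param dt time step in ps.
#' @param temperature temperature in K.
#' @param friction friction in 1/ps.
#' @param integrator `"baoab"` or `"overdamped"`.
#' @param seed integer RNG seed.
#' @param stride store every `stride`-th frame.
#' @return object of class `"langevin_run"` with a `frames` data.frame.
#' @export
run_langevin <- function(system, steps, dt = 0.01, temperature = 300,
                         friction = 1, integrator = "baoab", seed = 1,
                         stride = 10L) {
  .simulate(system, steps, dt, temperature, friction, integrator, seed,
            stride)
}

#' Well-tempered metadynamics of a toy system
#'
#' Langevin dynamics with a history-dependent Gaussian bias on the system's
#' collective variables: every `pace` steps (defaults to `cfg$tau / dt`) a
#' hill is deposited whose height decays with the bias already accumulated
#' there (well-tempered rule).  When the biased CVs include the path
#' variable `s`, quartic restraining walls confine it to \[-0.2, 1.2\] by
#' default.
#'
#' @inheritParams run_langevin
#' @param cfg a [wt_config()].
#' @param pace deposition interval in steps (default `round(cfg$tau / dt)`).
#' @param walls `NULL`, or list with named vectors `lo`, `hi` and constant
#'   `k` (quartic wall, kcal/mol per unit^4).
#' @return object of class `"metad_run"`: `frames` (time, CVs, instantaneous
#'   bias, observables, coordinates), `hills`, and `bias` (a [bias_state()]).
#' @export
run_metadynamics <- function(system, cfg = wt_config(), steps, dt = 0.01,
                             friction = 1, integrator = "baoab", seed = 1,
                             stride = 10L, pace = NULL, walls = NULL) {
  cvn <- system$cv_names %||% (if (!is.null(system$cv_dims)) paste0("q", system$cv_dims))
  if (is.null(walls) && "s" %in% (cvn %||% character()))
    walls <- list(lo = c(s = -0.2), hi = c(s = 1.2), k = 100)
  .simulate(system, steps, dt, cfg$temperature, friction, integrator, seed,
            stride, metad = list(cfg = cfg, pace = pace), walls = walls)
}
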