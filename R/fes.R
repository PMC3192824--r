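# Binned free-energy surfaces over one or two order parameters, plus basin
# and barrier detection.

new_fes <- function(axes, F, occupied, kT, origin = "") {
  F <- if (length(axes) == 1L) as.numeric(F) else as.matrix(F)
  structure(list(axes = axes, F = F, occupied = occupied, kT = kT,
                 origin = origin),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  nm <- vapply(x$axes, `[[`, "", "name")
  cat(sprintf("<fes over (%s): %s bins, %d occupied, range %.3g..%.3g kcal/mol>\n",
              paste(nm, collapse = ", "),
              paste(vapply(x$axes, function(a) length(a$mids), 1L), collapse = " x "),
              sum(x$occupied), min(x$F[x$occupied]), max(x$F[x$occupied])))
  invisible(x)
}

#' Axis specification for free-energy projections
#'
#' @param name column name of the order parameter in the frame table.
#' @param bins number of bins (default 100 for 1D use, 60 for 2D).
#' @param range optional `c(lo, hi)`; default the data range.
#' @return list consumed by [project_fes()].
#' @export
fes_axis <- function(name, bins = 100L, range = NULL) {
  list(name = name, bins = as.integer(bins), range = range)
}

#' Project weighted frames onto a free-energy surface
#'
#' `F_bin = -kT log(sum of weights in bin / total weight)`, shifted so the
#' minimum over occupied bins is zero.  Unoccupied bins are flagged and set
#' to `NA`, never extrapolated.
#'
#' @param frames data.frame holding the order-parameter columns (a
#'   trajectory frame table from the simulation engine, or any table).
#' @param weights per-frame statistical weights; default uniform.
#' @param axes list of one or two [fes_axis()] specs.
#' @param temperature temperature in K defining kT (default 300).
#' @return object of class `"fes"`.
#' @export
project_fes <- function(frames, weights = NULL, axes, temperature = 300) {
  if (inherits(axes, "list") && !is.null(axes$name)) axes <- list(axes)
  k <- length(axes)
  if (k < 1L || k > 2L) abort_ap("1 or 2 axes supported")
  nfr <- nrow(frames)
  w <- weights %||% rep(1, nfr)
  if (length(w) != nfr || any(!is.finite(w)) || any(w < 0))
    abort_ap("weights must be finite, non-negative, one per frame")
  kT <- .kB * temperature
  binof <- vector("list", k); axinfo <- vector("list", k)
  for (i in seq_len(k)) {
    v <- frames[[axes[[i]]$name]]
    if (is.null(v)) abort_ap(sprintf("no column '%s' in frames", axes[[i]]$name))
    rg <- axes[[i]]$range %||% range(v)
    if (diff(rg) <= 0) rg <- rg + c(-0.5, 0.5)
    nb <- axes[[i]]$bins
    breaks <- seq(rg[1], rg[2], length.out = nb + 1L)
    bi <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    binof[[i]] <- bi
    axinfo[[i]] <- list(name = axes[[i]]$name,
                        mids = 0.5 * (breaks[-1] + breaks[-(nb + 1L)]),
                        breaks = breaks)
  }
  if (k == 1L) {
    nb <- length(axinfo[[1]]$mids)
    wsum <- vapply(seq_len(nb), function(b) sum(w[binof[[1]] == b]), 0)
  } else {
    nb1 <- length(axinfo[[1]]$mids); nb2 <- length(axinfo[[2]]$mids)
    flat <- (binof[[2]] - 1L) * nb1 + binof[[1]]
    acc <- rowsum(w, flat)
    wsum <- matrix(0, nb1, nb2)
    wsum[as.integer(rownames(acc))] <- acc[, 1]
  }
  occ <- wsum > 0
  if (sum(occ) < 1L) abort_ap("no occupied bins")
  if (sum(occ) == 1L && length(wsum) > 1L)
    warning("all weight falls in a single bin")
  F <- array(NA_real_, dim = dim(as.array(wsum)))
  F[occ] <- -kT * log(wsum[occ] / sum(w))
  F[occ] <- F[occ] - min(F[occ])
  if (k == 1L) F <- as.numeric(F)
  new_fes(axes = axinfo, F = F, occupied = occ, kT = kT,
          origin = "reweighted histogram")
}

#' Boltzmann-marginalize a 2D surface to 1D
#'
#' `F1(x) = -kT log sum_y exp(-F(x, y)/kT)` over occupied bins, min-shifted.
#'
#' @param fes a 2D `"fes"` object.
#' @param over which axis to integrate out: index 2 (default) or 1, or the
#'   axis name.
#' @return a 1D `"fes"` object.
#' @export
marginalize_fes <- function(fes, over = 2L) {
  if (length(fes$axes) != 2L) abort_ap("marginalize_fes needs a 2D surface")
  if (is.character(over))
    over <- match(over, vapply(fes$axes, `[[`, "", "name"))
  keep <- if (over == 2L) 1L else 2L
  M <- fes$F; occ <- fes$occupied
  if (over == 1L) { M <- t(M); occ <- t(occ) }
  n <- nrow(M)
  F1 <- rep(NA_real_, n); occ1 <- logical(n)
  for (i in seq_len(n)) {
    f <- M[i, occ[i, ]]
    if (length(f)) { occ1[i] <- TRUE; F1[i] <- -fes$kT * logsumexp(-f / fes$kT) }
  }
  F1[occ1] <- F1[occ1] - min(F1[occ1])
  new_fes(axes = fes$axes[keep], F = F1, occupied = occ1, kT = fes$kT,
          origin = paste0(fes$origin, " (marginalized)"))
}

# local minima of a 1D profile with NA gaps; first index of any plateau
local_minima_1d <- function(F) {
  n <- length(F)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (!is.finite(F[i])) next
    l <- if (i > 1 && is.finite(F[i - 1])) F[i - 1] else Inf
    r <- if (i < n && is.finite(F[i + 1])) F[i + 1] else Inf
    if (F[i] < l && F[i] <= r) out <- c(out, i)
  }
  out
}

#' Locate basins and barriers of a free-energy surface
#'
#' For 1D surfaces: local minima (after persistence pruning of features
#' shallower than `min_depth`) and, between each adjacent pair, the
#' transition-state bin (maximum F along the segment).  The most stable
#' basin is starred; when two basins lie within 0.05 kcal/mol the one at the
#' lower coordinate wins the star (deterministic tie-break).  For 2D
#' surfaces the barrier between basins is the min-max (bottleneck) path
#' saddle found by flooding the grid in order of increasing F.
#'
#' @param fes a `"fes"` object.
#' @param min_depth minimum prominence (kcal/mol) for a basin to be kept
#'   (default 0.25).
#' @return data.frame with columns `type` ("min"/"ts"), coordinate columns
#'   named after the axes, `F`, `barrier` (ts rows: saddle minus the lower
#'   flanking minimum), and `star`.
#' @export
find_basins_and_barriers <- function(fes, min_depth = 0.25) {
  if (length(fes$axes) == 1L)
    basins_1d(fes, min_depth)
  else
    basins_2d(fes, min_depth)
}

basins_1d <- function(fes, min_depth) {
  F <- fes$F; x <- fes$axes[[1]]$mids
  mins <- local_minima_1d(F)
  if (!length(mins))
    return(empty_basin_table(fes$axes[[1]]$name))
  # persistence pruning: repeatedly merge the pair whose separating saddle
  # is closest above the shallower minimum
  saddle_between <- function(i, j) {
    seg <- F[i:j]
    k <- which.max(seg)
    c(idx = i + k - 1L, F = seg[k])
  }
  repeat {
    if (length(mins) < 2L) break
    prom <- rep(Inf, length(mins) - 1L)
    sads <- matrix(0, length(mins) - 1L, 2)
    for (p in seq_len(length(mins) - 1L)) {
      sd <- saddle_between(mins[p], mins[p + 1L])
      sads[p, ] <- sd
      prom[p] <- sd["F"] - max(F[mins[p]], F[mins[p + 1L]])
    }
    pmin <- which.min(prom)
    if (prom[pmin] >= min_depth) break
    drop_side <- if (F[mins[pmin]] >= F[mins[pmin + 1L]]) pmin else pmin + 1L
    mins <- mins[-drop_side]
  }
  rows <- list()
  for (p in seq_along(mins)) {
    rows[[length(rows) + 1L]] <-
      data.frame(type = "min", x = x[mins[p]], F = F[mins[p]],
                 barrier = NA_real_, star = FALSE)
    if (p < length(mins)) {
      sd <- saddle_between(mins[p], mins[p + 1L])
      rows[[length(rows) + 1L]] <-
        data.frame(type = "ts", x = x[sd["idx"]], F = sd["F"],
                   barrier = sd["F"] - min(F[mins[p]], F[mins[p + 1L]]),
                   star = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  names(tab)[2] <- fes$axes[[1]]$name
  star_basins(tab, fes$axes[[1]]$name)
}

empty_basin_table <- function(axis_name, axis2 = NULL) {
  tab <- data.frame(type = character(0), x = numeric(0), F = numeric(0),
                    barrier = numeric(0), star = logical(0))
  names(tab)[2] <- axis_name
  if (!is.null(axis2)) { tab$y <- numeric(0); names(tab)[6] <- axis2 }
  tab
}

star_basins <- function(tab, coord) {
  rownames(tab) <- NULL
  im <- which(tab$type == "min")
  if (!length(im)) return(tab)
  best <- min(tab$F[im])
  cand <- im[tab$F[im] <= best + 0.05]
  star <- cand[which.min(tab[[coord]][cand])]
  tab$star[star] <- TRUE
  tab
}

basins_2d <- function(fes, min_depth) {
  # watershed-by-flooding with union-find: visiting cells in order of
  # increasing F, the cell at which two basins first touch is their
  # bottleneck (min-max path) saddle.
  F <- fes$F; occ <- fes$occupied
  nr <- nrow(F); nc <- ncol(F)
  idx <- which(occ & is.finite(F))
  ord <- idx[order(F[idx])]
  parent <- integer(nr * nc)        # 0 = not yet flooded
  root_basin <- integer(nr * nc)    # basin id, valid at component roots
  minima <- integer(0)              # cell index of each basin minimum
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  sad <- list()
  for (cell in ord) {
    r <- (cell - 1L) %% nr + 1L; cc <- (cell - 1L) %/% nr + 1L
    nbr <- c(if (r > 1L) cell - 1L, if (r < nr) cell + 1L,
             if (cc > 1L) cell - nr, if (cc < nc) cell + nr)
    nbr <- nbr[parent[nbr] != 0L]
    parent[cell] <- cell
    if (!length(nbr)) {
      minima <- c(minima, cell)
      root_basin[cell] <- length(minima)
    } else {
      roots <- unique(vapply(nbr, find, 1L))
      bs <- root_basin[roots]
      keep <- bs[which.min(F[minima[bs]])]
      for (b in setdiff(bs, keep))   # b is absorbed here, once and for all
        sad[[length(sad) + 1L]] <- c(a = keep, b = b, cell = cell,
                                     F = F[cell],
                                     depth = F[cell] - F[minima[b]])
      parent[roots] <- cell          # the new cell becomes the root
      root_basin[cell] <- keep
    }
  }
  sadtab <- if (length(sad)) as.data.frame(do.call(rbind, sad)) else
    data.frame(a = integer(0), b = integer(0), cell = integer(0),
               F = numeric(0), depth = numeric(0))
  keep_min <- sort(unique(c(
    which.min(F[minima]),
    which(vapply(seq_along(minima), function(b) {
      dep <- sadtab$depth[sadtab$b == b]
      length(dep) > 0 && min(dep) >= min_depth
    }, TRUE)))))
  ax1 <- fes$axes[[1]]; ax2 <- fes$axes[[2]]
  cell_xy <- function(cell) {
    r <- (cell - 1L) %% nr + 1L; cc <- (cell - 1L) %/% nr + 1L
    c(ax1$mids[r], ax2$mids[cc])
  }
  rows <- list()
  for (b in keep_min) {
    xy <- cell_xy(minima[b])
    rows[[length(rows) + 1L]] <- data.frame(type = "min", x = xy[1], y = xy[2],
                                            F = F[minima[b]],
                                            barrier = NA_real_, star = FALSE)
  }
  for (i in seq_len(nrow(sadtab))) {
    if (!(sadtab$a[i] %in% keep_min && sadtab$b[i] %in% keep_min)) next
    xy <- cell_xy(sadtab$cell[i])
    rows[[length(rows) + 1L]] <-
      data.frame(type = "ts", x = xy[1], y = xy[2], F = sadtab$F[i],
                 barrier = sadtab$F[i] -
                   min(F[minima[sadtab$a[i]]], F[minima[sadtab$b[i]]]),
                 star = FALSE)
  }
  if (!length(rows)) return(empty_basin_table(ax1$name, ax2$name))
  tab <- do.call(rbind, rows)
  names(tab)[2:3] <- c(ax1$name, ax2$name)
  star_basins(tab, ax1$name)
}

#' Write / read a free-energy surface as plain text
#'
#' Two (1D) or three (2D) whitespace-separated columns: axis value(s) and F
#' in kcal/mol; header comment lines record axes, bins, kT and the
#' minimum-shift convention.  Unoccupied bins are written as NA.
#'
#' @param fes a `"fes"` object.
#' @param path file path.
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w"); on.exit(close(con))
  nm <- vapply(fes$axes, `[[`, "", "name")
  writeLines(sprintf("# fes axes: %s", paste(nm, collapse = " ")), con)
  writeLines(sprintf("# bins: %s; kT = %.9g kcal/mol; min-shifted to 0; %s",
                     paste(vapply(fes$axes, function(a) length(a$mids), 1L),
                           collapse = " x "),
                     fes$kT, fes$origin), con)
  if (length(fes$axes) == 1L) {
    df <- data.frame(fes$axes[[1]]$mids, fes$F)
  } else {
    g <- expand.grid(fes$axes[[1]]$mids, fes$axes[[2]]$mids)
    df <- data.frame(g[[1]], g[[2]], as.numeric(fes$F))
  }
  utils::write.table(format(df, digits = 9, trim = TRUE, scientific = NA),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
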