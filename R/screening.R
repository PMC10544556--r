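# Residency screening and excursion removal.
#
# Home-range estimation assumes range residency; tracks are screened with an
# empirical variogram, an ambiguous track can be checked for a range shift,
# and within-range excursions are removed with a one-sided Hampel filter on
# Tukey-transformed distances to the track centroid:
#   upper bound = median(transformed distance) + 3 * MAD (unscaled).

#' Empirical semi-variogram of a trajectory
#'
#' Mean squared half-displacement of fix pairs, binned by time lag. A plateau
#' at long lags indicates range residency; unbounded growth indicates
#' dispersal or nomadism.
#'
#' @param traj projected `traj` with at least 10 fixes.
#' @param bin_width lag bin width in hours.
#' @param max_lag maximum lag in hours.
#' @return Class `"variogram"`: data frame with `lag` (bin centre, hours),
#'   `semivariance` (m^2) and `n_pairs`. Empty bins are omitted.
#' @export
empirical_variogram <- function(traj, bin_width = 12, max_lag = 24 * 45) {
  stopifnot(bin_width > 0, max_lag > 0)
  f <- traj$fixes
  n <- nrow(f)
  if (n < 10) stop("need at least 10 fixes for a variogram")
  if (n > 4000) {  # cap the O(n^2) pair set; schedule-regular tracks are far smaller
    idx <- round(seq(1, n, length.out = 4000))
    f <- f[idx, , drop = FALSE]
    n <- nrow(f)
  }
  tt <- as.numeric(f$t) / 3600
  dt <- abs(outer(tt, tt, "-"))
  keep <- upper.tri(dt) & dt <= max_lag & dt > 0
  lag <- dt[keep]
  sq <- (outer(f$x, f$x, "-")^2 + outer(f$y, f$y, "-")^2)[keep] / 2
  bin <- floor(lag / bin_width)
  sv <- tapply(sq, bin, mean)
  np <- tapply(sq, bin, length)
  out <- data.frame(lag = (as.numeric(names(sv)) + 0.5) * bin_width,
                    semivariance = as.numeric(sv),
                    n_pairs = as.integer(np))
  out <- out[order(out$lag), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variogram", "data.frame")
  out
}

#' @export
plot.variogram <- function(x, ...) {
  graphics::plot(x$lag / 24, x$semivariance / 1e6, type = "b", pch = 16,
                 xlab = "lag (days)", ylab = expression(semivariance~(km^2)),
                 ...)
  invisible(x)
}

#' Judge range residency from a variogram
#'
#' Resident if the long-lag (tail) mean semivariance has converged to the
#' plateau mean: tail <= (1 + tol) * plateau.
#'
#' @param vg a [empirical_variogram()] result.
#' @param plateau_window,tail_window lag ranges in hours, `c(lo, hi)`.
#'   Defaults: 5--10 days and 25--40 days.
#' @param tol relative tolerance (default 0.5).
#' @return List of class `"residency"`: `verdict` (`"resident"` or
#'   `"non_resident"`), `plateau_mean`, `tail_mean`, `ratio`.
#' @export
assess_residency <- function(vg, plateau_window = c(5, 10) * 24,
                             tail_window = c(25, 40) * 24, tol = 0.5) {
  pw <- vg$lag >= plateau_window[1] & vg$lag <= plateau_window[2]
  tw <- vg$lag >= tail_window[1] & vg$lag <= tail_window[2]
  if (!any(pw) || !any(tw)) {
    stop("inconclusive: a residency window contains no variogram bins")
  }
  pm <- mean(vg$semivariance[pw])
  tm <- mean(vg$semivariance[tw])
  ratio <- if (pm > 0) tm / pm else if (tm == 0) 1 else Inf
  structure(list(verdict = if (ratio <= 1 + tol) "resident" else "non_resident",
                 plateau_mean = pm, tail_mean = tm, ratio = ratio, tol = tol),
            class = "residency")
}

#' @export
print.residency <- function(x, ...) {
  cat("Residency:", x$verdict,
      sprintf("(tail/plateau = %.2f, tol = %.2f)\n", x$ratio, x$tol))
  invisible(x)
}

#' Tukey ladder-of-powers exponent by normality
#'
#' Selects the power lambda on the grid [-5, 5] step 0.025 whose transform
#' (`x^lambda` for lambda > 0, `log x` for lambda = 0, `-x^lambda` for
#' lambda < 0 — monotone increasing throughout) maximizes the Shapiro--Wilk W
#' of the transformed sample.
#'
#' @param values positive numbers (zeros are replaced by half the smallest
#'   positive value, as distances to a centroid legitimately approach zero).
#' @param grid candidate lambdas.
#' @return Selected lambda (numeric scalar with attribute `"W"`).
#' @export
tukey_lambda <- function(values, grid = seq(-5, 5, by = 0.025)) {
  v <- values[is.finite(values)]
  if (length(v) < 3) stop("need at least 3 values")
  if (any(v < 0)) stop("values must be non-negative")
  if (any(v == 0)) {
    pos <- v[v > 0]
    if (!length(pos)) {
      warning("constant sample; lambda = 1")
      return(structure(1, W = NA_real_))
    }
    v[v == 0] <- min(pos) / 2
  }
  if (stats::sd(v) == 0) {
    warning("constant sample; lambda = 1")
    return(structure(1, W = NA_real_))
  }
  if (length(v) > 5000) {  # shapiro.test limit; deterministic thinning
    v <- stats::quantile(v, probs = seq(0, 1, length.out = 5000), names = FALSE,
                         type = 8)
  }
  W <- vapply(grid, function(l) {
    tv <- tukey_transform(v, l)
    if (!all(is.finite(tv)) || stats::sd(tv) == 0) return(-Inf)
    suppressWarnings(stats::shapiro.test(tv)$statistic)
  }, numeric(1))
  best <- which.max(W)
  structure(grid[best], W = unname(W[best]))
}

tukey_transform <- function(x, lambda) {
  if (lambda > 0) x^lambda else if (lambda == 0) log(x) else -(x^lambda)
}

#' One-sided Hampel upper bound
#'
#' `median(v) + 3 * median(|v - median(v)|)` with the *unscaled* median
#' absolute deviation (no 1.4826 consistency constant).
#'
#' @param transformed numeric vector (length >= 3).
#' @param k MAD multiplier (default 3).
#' @return The threshold.
#' @export
hampel_upper_bound <- function(transformed, k = 3) {
  if (length(transformed) < 3) stop("need at least 3 values")
  med <- stats::median(transformed)
  med + k * stats::median(abs(transformed - med))
}

#' Remove excursions from a resident trajectory
#'
#' Distances to the track centroid are Tukey-transformed
#' ([tukey_lambda()]) and fixes above the one-sided Hampel bound
#' ([hampel_upper_bound()]) are flagged; maximal runs of flagged fixes become
#' excursion segments. The kept trajectory is re-centroided once.
#'
#' @param traj projected `traj` (should already be judged resident).
#' @param k Hampel multiplier (default 3).
#' @return Class `"excursion_filter"`: `kept` (filtered `traj`), `excursions`
#'   (data frame: start/end times, fix indices, n_fixes, max distance),
#'   `lambda`, `upper_bound` (transformed scale), `flagged` (logical mask on
#'   the input fixes).
#' @export
remove_excursions <- function(traj, k = 3) {
  f <- traj$fixes
  cx <- mean(f$x); cy <- mean(f$y)
  d <- sqrt((f$x - cx)^2 + (f$y - cy)^2)
  lam <- tukey_lambda(d)
  dpos <- d
  if (any(dpos == 0)) {
    pos <- dpos[dpos > 0]
    dpos[dpos == 0] <- if (length(pos)) min(pos) / 2 else 1e-6
  }
  tv <- tukey_transform(dpos, as.numeric(lam))
  ub <- hampel_upper_bound(tv, k = k)
  flagged <- tv > ub
  if (mean(flagged) > 0.5) {
    stop("filter degenerate: >50% of fixes flagged; trajectory is likely ",
         "non-resident")
  }
  segs <- flagged_runs(flagged)
  exc <- if (nrow(segs)) {
    data.frame(animal_id = traj$animal_id,
               start_fix = segs$start, end_fix = segs$end,
               start_time = f$t[segs$start], end_time = f$t[segs$end],
               n_fixes = segs$end - segs$start + 1L,
               max_dist_m = vapply(seq_len(nrow(segs)), function(i) {
                 max(d[segs$start[i]:segs$end[i]])
               }, numeric(1)))
  } else {
    data.frame(animal_id = character(), start_fix = integer(),
               end_fix = integer(), start_time = as.POSIXct(character()),
               end_time = as.POSIXct(character()), n_fixes = integer(),
               max_dist_m = numeric())
  }
  kept <- traj
  kept$fixes <- f[!flagged, , drop = FALSE]
  rownames(kept$fixes) <- NULL
  kept$centroid <- c(mean(kept$fixes$x), mean(kept$fixes$y))
  structure(list(kept = kept, excursions = exc, lambda = as.numeric(lam),
                 upper_bound = ub, flagged = flagged),
            class = "excursion_filter")
}

flagged_runs <- function(flagged) {
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' @export
print.excursion_filter <- function(x, ...) {
  cat("Excursion filter (lambda =", round(x$lambda, 3), ")\n")
  cat("  removed", sum(x$flagged), "of", length(x$flagged), "fixes in",
      nrow(x$excursions), "segment(s)\n")
  invisible(x)
}

#' Least-squares change-point test for a range shift
#'
#' Scans all splits and picks the one minimizing the total within-segment
#' squared distance to the segment centroids. A shift is declared when the
#' distance between the two segment centroids exceeds the larger of the two
#' segment RMS radii. This is a deliberately simple surrogate for
#' likelihood-based range-shift models; see the methods vignette.
#'
#' @param traj projected `traj`.
#' @param min_segment minimum fixes per segment (default 30).
#' @return `NULL` when no shift is detected, else a list with `index` (last
#'   fix of the first segment), `time`, `centroid_distance` and the two
#'   segment RMS radii.
#' @export
detect_range_shift <- function(traj, min_segment = 30) {
  f <- traj$fixes
  n <- nrow(f)
  if (n < 2 * min_segment) stop("need at least 2 * min_segment fixes")
  cx <- cumsum(f$x); cy <- cumsum(f$y)
  cx2 <- cumsum(f$x^2); cy2 <- cumsum(f$y^2)
  ks <- min_segment:(n - min_segment)
  # within-segment SS around each segment mean, via cumulative sums
  ss1 <- (cx2[ks] - cx[ks]^2 / ks) + (cy2[ks] - cy[ks]^2 / ks)
  n2 <- n - ks
  ss2 <- (cx2[n] - cx2[ks] - (cx[n] - cx[ks])^2 / n2) +
         (cy2[n] - cy2[ks] - (cy[n] - cy[ks])^2 / n2)
  k <- ks[which.min(ss1 + ss2)]
  c1 <- c(cx[k] / k, cy[k] / k)
  c2 <- c((cx[n] - cx[k]) / (n - k), (cy[n] - cy[k]) / (n - k))
  dcc <- sqrt(sum((c1 - c2)^2))
  r1 <- sqrt((ss1[match(k, ks)]) / k)
  r2 <- sqrt((ss2[match(k, ks)]) / (n - k))
  if (dcc > max(r1, r2)) {
    list(index = k, time = f$t[k], centroid_distance = dcc,
         rms1 = r1, rms2 = r2)
  } else {
    NULL
  }
}
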