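# Time-local convex hulls (T-LoCoH).
#
# Around every fix a local convex hull is built from its nearest neighbours
# under the time-scaled distance (TSD)
#
#     TSD_ij = sqrt( dx^2 + dy^2 + (s * v_max * dt)^2 ),
#
# where s is a dimensionless factor weighting time against space (s = 0
# ignores time) and v_max is the animal's maximum observed velocity.
# Neighbours are chosen with the adaptive a-method: points are taken in order
# of TSD while the cumulative TSD stays <= a. Hulls carry the number of
# enclosed fixes (a density proxy) and two time-use metrics driven by the
# inter-visit gap (IVG): the number of separate visits (NSV, revisitation)
# and the mean number of locations per visit (MNLV, duration of use).
# Sorting hulls by one of these metrics and accumulating their union until a
# stated fraction of fixes is enclosed yields isopleths: 95% = home range,
# 50% = core area.

#' Time-scaled distance between two fixes
#'
#' @param dx,dy planar separations in metres.
#' @param dt time separation in seconds.
#' @param s dimensionless time-scaling factor (s = 0 ignores time).
#' @param v_max maximum observed velocity (m/s), see [compute_vmax()].
#' @return Distance in metres.
#' @export
tsd_distance <- function(dx, dy, dt, s, v_max) {
  stopifnot(s >= 0, v_max >= 0)
  sqrt(dx^2 + dy^2 + (s * v_max * abs(dt))^2)
}

# TSD from fix i to all fixes of the trajectory.
tsd_to_all <- function(f, i, s, v_max) {
  tsd_distance(f$x - f$x[i], f$y - f$y[i],
               as.numeric(f$t) - as.numeric(f$t[i]), s, v_max)
}

#' Adaptive (a-method) nearest-neighbour selection
#'
#' Fixes sorted by TSD from the parent are taken while their cumulative TSD
#' stays within `a`. At least the two nearest neighbours are always retained,
#' since a hull needs three points.
#'
#' @param traj projected `traj` (>= 3 fixes).
#' @param parent parent fix index.
#' @param s,a,v_max TSD parameters; `a` is the cumulative-distance threshold
#'   in metres.
#' @return Integer vector of neighbour fix indices (parent excluded).
#' @export
select_neighbors_adaptive <- function(traj, parent, s, a, v_max) {
  stopifnot(a > 0)
  f <- traj$fixes
  if (nrow(f) < 3) stop("need at least 3 fixes")
  tsd <- tsd_to_all(f, parent, s, v_max)
  ord <- order(tsd)
  ord <- ord[ord != parent]
  keep <- cumsum(tsd[ord]) <= a
  keep[1:2] <- TRUE  # floor rule: hulls need 3 points
  ord[keep]
}

#' Fit a time-local convex hull set
#'
#' The package's core estimator: builds one local hull per fix, counts
#' enclosed fixes (boundary-inclusive, over the full trajectory) and derives
#' the NSV/MNLV time-use metrics.
#'
#' @param traj projected, excursion-filtered `traj`.
#' @param s time-scaling factor; default [suggest_s()].
#' @param a cumulative TSD threshold in metres; default [suggest_a()].
#' @param ivg inter-visit gap in seconds (default 43200 s = 12 h).
#' @param v_max maximum velocity (m/s); default [compute_vmax()].
#' @param max_skip_frac error if more than this fraction of fixes yields no
#'   valid hull (degenerate geometry; default 0.2).
#' @return Object of class `"tlocoh"`: list with `hulls` (per-hull polygons
#'   and enclosed-fix index sets), `metrics` (data frame: parent, area m^2,
#'   n_enclosed, nsv, mnlv), `skipped` (data frame of parentless fixes and
#'   reasons), the parameters, and the trajectory.
#' @export
tlocoh <- function(traj, s = NULL, a = NULL, ivg = 43200, v_max = NULL,
                   max_skip_frac = 0.2) {
  f <- traj$fixes
  n <- nrow(f)
  if (n < 3) stop("need at least 3 fixes")
  if (is.null(v_max)) v_max <- compute_vmax(traj)
  if (is.null(s)) s <- suggest_s(traj, v_max = v_max)
  if (is.null(a)) a <- suggest_a(traj, s = s, v_max = v_max)
  stopifnot(s >= 0, a > 0, ivg > 0)

  tt <- as.numeric(f$t)
  hulls <- vector("list", n)
  skipped <- character(n)
  area <- n_enc <- nsv <- mnlv <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    nbrs <- select_neighbors_adaptive(traj, i, s, a, v_max)
    idx <- c(i, nbrs)
    poly <- convex_poly(f$x[idx], f$y[idx])
    if (is.null(poly)) {
      skipped[i] <- "degenerate"
      next
    }
    cand <- which(f$x >= min(poly[, 1]) & f$x <= max(poly[, 1]) &
                  f$y >= min(poly[, 2]) & f$y <= max(poly[, 2]))
    enc <- cand[points_in_convex(f$x[cand], f$y[cand], poly)]
    tu <- visit_metrics(tt[enc], ivg)
    hulls[[i]] <- list(parent = i, nbrs = nbrs, poly = poly, enclosed = enc)
    area[i] <- poly_area(poly)
    n_enc[i] <- length(enc)
    nsv[i] <- tu[1]
    mnlv[i] <- tu[2]
  }

  bad <- which(nzchar(skipped))
  if (length(bad) / n > max_skip_frac) {
    stop("degenerate geometry: ", length(bad), " of ", n,
         " fixes yielded no hull")
  }
  ok <- which(!nzchar(skipped))
  metrics <- data.frame(parent = ok, t = f$t[ok], area = area[ok],
                        n_enclosed = as.integer(n_enc[ok]),
                        nsv = as.integer(nsv[ok]), mnlv = mnlv[ok])
  structure(list(hulls = hulls[ok], metrics = metrics,
                 skipped = data.frame(fix = bad,
                                      reason = skipped[bad]),
                 params = list(s = s, a = a, ivg = ivg, v_max = v_max),
                 traj = traj),
            class = "tlocoh")
}

# nsv / mnlv for the time-sorted enclosed fixes of one hull: a new visit
# starts when the gap since the previous enclosed fix is >= ivg.
visit_metrics <- function(times, ivg) {
  if (!length(times)) return(c(0, 0))
  times <- sort(times)
  nsv <- 1L + sum(diff(times) >= ivg)
  c(nsv, length(times) / nsv)
}

#' @export
print.tlocoh <- function(x, ...) {
  p <- x$params
  cat("T-LoCoH hullset:", x$traj$animal_id, "\n")
  cat(sprintf("  %d hulls (%d fixes skipped), s = %.4g, a = %.0f m, ivg = %.0f s, v_max = %.3g m/s\n",
              nrow(x$metrics), nrow(x$skipped), p$s, p$a, p$ivg, p$v_max))
  invisible(x)
}

#' @export
summary.tlocoh <- function(object, ...) {
  m <- object$metrics
  cat("T-LoCoH hullset:", object$traj$animal_id, "—", nrow(m), "hulls\n")
  print(rbind(area_m2 = summary(m$area),
              n_enclosed = summary(as.numeric(m$n_enclosed)),
              nsv = summary(as.numeric(m$nsv)),
              mnlv = summary(m$mnlv)))
  invisible(object)
}

#' @export
plot.tlocoh <- function(x, levels = c(0.5, 0.95), ordering = "density", ...) {
  f <- x$traj$fixes
  graphics::plot(f$x, f$y, pch = 16, cex = 0.3, col = "grey50", asp = 1,
                 xlab = "x (m)", ylab = "y (m)", main = x$traj$animal_id, ...)
  iso <- isopleths(x, ordering = ordering, levels = levels)
  cols <- grDevices::hcl.colors(length(iso$levels), "viridis")
  for (i in seq_along(iso$levels)) {
    for (ring in iso$isopleths[[i]]$rings) {
      graphics::lines(ring[, 1], ring[, 2], col = cols[i], lwd = 2)
    }
  }
  graphics::legend("topright", legend = paste0(iso$levels * 100, "%"),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Isopleths of a hullset
#'
#' Hulls are sorted in descending order of the chosen metric (ties: smaller
#' area first, then earlier parent time) and their union accumulated until
#' the fraction of unique trajectory fixes enclosed reaches each level.
#' Union areas and boundary rings are computed on a regular grid of cell
#' centres; fix membership is always tested exactly against the member hulls.
#'
#' @param fit a [tlocoh()] object.
#' @param ordering `"density"` (enclosed-fix count), `"nsv"` or `"mnlv"`.
#' @param levels isopleth fractions in (0, 1], default `c(0.5, 0.95)`.
#' @param grid_n grid resolution (cells along the larger extent).
#' @return Class `"isopleth_set"`: list with `levels`, `ordering` and
#'   `isopleths`, one per level, each of class `"isopleth"` with `hull_ids`,
#'   `polys`, `area` (m^2), `n_fixes`, `frac`, `partial`, `rings`.
#' @export
isopleths <- function(fit, ordering = c("density", "nsv", "mnlv"),
                      levels = c(0.5, 0.95), grid_n = 256) {
  ordering <- match.arg(ordering)
  stopifnot(all(levels > 0), all(levels <= 1))
  m <- fit$metrics
  metric <- switch(ordering, density = m$n_enclosed, nsv = m$nsv,
                   mnlv = m$mnlv)
  ord <- order(-metric, m$area, as.numeric(m$t))
  hulls <- fit$hulls[ord]
  n_total <- nrow(fit$traj$fixes)

  # cumulative count of unique enclosed fixes along the hull ordering
  seen <- logical(n_total)
  cumu <- integer(length(hulls))
  cnt <- 0L
  for (k in seq_along(hulls)) {
    e <- hulls[[k]]$enclosed
    new <- e[!seen[e]]
    cnt <- cnt + length(new)
    seen[new] <- TRUE
    cumu[k] <- cnt
  }

  levels <- sort(levels)
  out <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    need <- levels[li] * n_total
    k <- match(TRUE, cumu >= need - 1e-9)
    partial <- is.na(k)
    if (partial) k <- length(hulls)
    member <- hulls[seq_len(k)]
    polys <- lapply(member, `[[`, "poly")
    xr <- range(vapply(polys, function(p) range(p[, 1]), numeric(2)))
    yr <- range(vapply(polys, function(p) range(p[, 2]), numeric(2)))
    grid <- make_grid(xr, yr, n = grid_n)
    mm <- grid_membership(grid, polys)
    out[[li]] <- structure(
      list(level = levels[li], ordering = ordering,
           hull_ids = vapply(member, `[[`, integer(1), "parent"),
           polys = polys, area = grid_area(grid, mm),
           n_fixes = cumu[k], frac = cumu[k] / n_total, partial = partial,
           rings = grid_outline(grid, mm), grid_n = grid_n),
      class = "isopleth")
    if (partial) {
      warning(sprintf("level %.2f unreachable: all hulls enclose %.3f of fixes",
                      levels[li], cumu[k] / n_total))
    }
  }
  structure(list(levels = levels, ordering = ordering,
                 animal_id = fit$traj$animal_id, isopleths = out),
            class = "isopleth_set")
}

#' @export
print.isopleth <- function(x, ...) {
  cat(sprintf("Isopleth %.0f%% (%s): %.2f km^2, %d fixes (%.1f%%), %d hulls%s\n",
              x$level * 100, x$ordering, x$area / 1e6, x$n_fixes,
              x$frac * 100, length(x$polys),
              if (x$partial) " [partial]" else ""))
  invisible(x)
}

#' @export
print.isopleth_set <- function(x, ...) {
  cat("Isopleths for", x$animal_id, "(", x$ordering, "ordering )\n")
  for (iso in x$isopleths) print(iso)
  invisible(x)
}

#' Exact point-in-isopleth membership
#'
#' @param iso an `"isopleth"` object.
#' @param x,y planar coordinates.
#' @return Logical vector: inside any member hull (boundary-inclusive).
#' @export
in_isopleth <- function(iso, x, y) {
  inside <- rep(FALSE, length(x))
  for (p in iso$polys) {
    todo <- which(!inside &
                  x >= min(p[, 1]) & x <= max(p[, 1]) &
                  y >= min(p[, 2]) & y <= max(p[, 2]))
    if (!length(todo)) next
    inside[todo] <- points_in_convex(x[todo], y[todo], p)
  }
  inside
}

#' Suggest the time-scaling factor s
#'
#' For fix pairs separated by roughly the period of interest, returns the s
#' at which the median time term `s * v_max * dt` balances the median spatial
#' separation — i.e. the median of the per-pair ratios `d / (v_max * dt)`,
#' clamped to [0.001, 1]. A diagnostic surrogate for the visual selection
#' tools of the reference workflow.
#'
#' @param traj projected `traj` (>= 100 fixes).
#' @param period period of interest in seconds (default 43200 s = 12 h).
#' @param v_max maximum velocity; default [compute_vmax()].
#' @return Suggested s.
#' @export
suggest_s <- function(traj, period = 43200, v_max = NULL) {
  f <- traj$fixes
  if (nrow(f) < 100) stop("need at least 100 fixes to suggest s")
  if (is.null(v_max)) v_max <- compute_vmax(traj)
  tt <- as.numeric(f$t)
  dt <- abs(outer(tt, tt, "-"))
  sel <- upper.tri(dt) & abs(dt - period) <= 0.25 * period
  d <- sqrt(outer(f$x, f$x, "-")^2 + outer(f$y, f$y, "-")^2)[sel]
  dtv <- dt[sel]
  if (!length(d)) stop("no fix pairs near the period of interest")
  if (stats::median(d) == 0 || v_max == 0) {
    warning("spatial term is zero; clamping s to 0.001")
    return(0.001)
  }
  min(max(stats::median(d / (v_max * dtv)), 0.001), 1)
}

#' Default cumulative-TSD threshold a
#'
#' The median over parents of the cumulative TSD of their `k` nearest
#' neighbours: a neutral starting value giving hulls of about `k` points.
#' Fine-tuning belongs to [a_diagnostic()].
#'
#' @param traj projected `traj`.
#' @param s time-scaling factor.
#' @param k target neighbour count (default 15).
#' @param v_max maximum velocity; default [compute_vmax()].
#' @return Suggested a in metres.
#' @export
suggest_a <- function(traj, s, k = 15, v_max = NULL) {
  f <- traj$fixes
  if (is.null(v_max)) v_max <- compute_vmax(traj)
  n <- nrow(f)
  k <- min(k, n - 1)
  probe <- unique(round(seq(1, n, length.out = min(n, 200))))
  acc <- vapply(probe, function(i) {
    tsd <- sort(tsd_to_all(f, i, s, v_max))[-1]  # drop self
    sum(tsd[seq_len(k)])
  }, numeric(1))
  stats::median(acc)
}

#' Diagnostic curve for choosing a
#'
#' Fraction of fixes enclosed by the 95% density isopleth, and its area, as a
#' function of the threshold `a`: the graphical aid used to balance excluding
#' used areas against including unused ones.
#'
#' @param traj projected `traj`.
#' @param s time-scaling factor.
#' @param a_values candidate thresholds (metres).
#' @param level isopleth level to monitor (default 0.95).
#' @return Data frame with `a`, `area_m2`, `frac_enclosed`.
#' @export
a_diagnostic <- function(traj, s, a_values, level = 0.95) {
  rows <- lapply(a_values, function(a) {
    fit <- tlocoh(traj, s = s, a = a)
    iso <- isopleths(fit, levels = level)$isopleths[[1]]
    data.frame(a = a, area_m2 = iso$area, frac_enclosed = iso$frac)
  })
  do.call(rbind, rows)
}
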