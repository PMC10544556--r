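# Dyadic overlap and Minta spatio-temporal interaction coefficients.
#
# Two animals form a dyad when their 95%-isopleth home-range boundaries lie
# within a neighbour threshold (default 3200 m, the radius of a red fox home
# range). Static overlap is the geometric mean of the two directed overlap
# fractions. Within the shared area (the intersection of the two home
# ranges), Minta's coefficients compare observed to expected use:
#   spatial  L = ln[ (k / (n q)) / (m / (n (1 - q))) ],  q = shared/range area
#   temporal L_ixn = ln[ (odds_AB + odds_00) / (odds_A0 + odds_0B) ]
# with odds_c = n_c / (n p_c) over the four joint-presence cells of the
# simultaneous fix pairs.

#' Find neighbouring dyads among home-range isopleths
#'
#' @param ranges named list of 95% `"isopleth"` objects (one per animal).
#' @param threshold boundary-distance threshold in metres (default 3200).
#' @param species optional named character vector of species labels.
#' @return Data frame with one row per dyad: `a`, `b`, `species_pair`,
#'   `distance_m` (0 when the ranges overlap).
#' @export
find_dyads <- function(ranges, threshold = 3200, species = NULL) {
  ids <- names(ranges)
  stopifnot(length(ids) >= 2)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      d <- isopleth_distance(ranges[[ids[i]]], ranges[[ids[j]]])
      if (d < threshold) {
        sp <- if (is.null(species)) NA_character_ else
          paste(sort(c(species[[ids[i]]], species[[ids[j]]])), collapse = "-")
        out[[length(out) + 1L]] <- data.frame(
          a = ids[j], b = ids[i], species_pair = sp, distance_m = d)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(a = character(), b = character(),
                      species_pair = character(), distance_m = numeric()))
  }
  do.call(rbind, out)
}

# Boundary distance between two hull-union isopleths: zero when any member
# hulls overlap, otherwise the minimum convex-polygon pair distance.
isopleth_distance <- function(iso_a, iso_b) {
  bb <- function(polys, f, col) f(vapply(polys, function(p) f(p[, col]),
                                         numeric(1)))
  # bounding-box gap is a lower bound on the true distance
  gapx <- max(bb(iso_b$polys, min, 1) - bb(iso_a$polys, max, 1),
              bb(iso_a$polys, min, 1) - bb(iso_b$polys, max, 1), 0)
  gapy <- max(bb(iso_b$polys, min, 2) - bb(iso_a$polys, max, 2),
              bb(iso_a$polys, min, 2) - bb(iso_b$polys, max, 2), 0)
  best <- Inf
  for (p in iso_a$polys) {
    for (q in iso_b$polys) {
      # cheap bbox prune
      dx <- max(min(q[, 1]) - max(p[, 1]), min(p[, 1]) - max(q[, 1]), 0)
      dy <- max(min(q[, 2]) - max(p[, 2]), min(p[, 2]) - max(q[, 2]), 0)
      if (sqrt(dx^2 + dy^2) >= best) next
      best <- min(best, convex_dist(p, q))
      if (best == 0) return(0)
    }
  }
  max(best, sqrt(gapx^2 + gapy^2) * 0)  # best is exact; gap kept for clarity
}

#' Geometric-mean home-range overlap index
#'
#' `sqrt((area_AB / area_A) * (area_AB / area_B))`, the geometric mean of the
#' two directed overlap fractions; 0 for disjoint ranges, 1 for coincident
#' ones.
#'
#' @param a,b two `"isopleth"` objects, or two convex polygons (two-column
#'   CCW matrices).
#' @param grid_n grid resolution for hull-union areas (isopleth method).
#' @return List of class `"overlap"`: `index`, `area_ab`, `area_a`, `area_b`,
#'   `frac_a`, `frac_b`.
#' @export
overlap_index <- function(a, b, grid_n = 384) {
  if (is.matrix(a) && is.matrix(b)) {
    area_a <- poly_area(a); area_b <- poly_area(b)
    if (area_a <= 0 || area_b <= 0) stop("zero-area polygon")
    inter <- clip_convex(a, b)
    area_ab <- if (is.null(inter)) 0 else poly_area(inter)
  } else if (inherits(a, "isopleth") && inherits(b, "isopleth")) {
    xr <- range(unlist(lapply(c(a$polys, b$polys), function(p) range(p[, 1]))))
    yr <- range(unlist(lapply(c(a$polys, b$polys), function(p) range(p[, 2]))))
    grid <- make_grid(xr, yr, n = grid_n)
    ma <- grid_membership(grid, a$polys)
    mb <- grid_membership(grid, b$polys)
    area_a <- grid_area(grid, ma); area_b <- grid_area(grid, mb)
    if (area_a <= 0 || area_b <= 0) stop("zero-area isopleth")
    area_ab <- grid_area(grid, ma & mb)
  } else {
    stop("a and b must both be isopleths or both polygon matrices")
  }
  fa <- area_ab / area_a; fb <- area_ab / area_b
  structure(list(index = sqrt(fa * fb), area_ab = area_ab,
                 area_a = area_a, area_b = area_b,
                 frac_a = fa, frac_b = fb),
            class = "overlap")
}

#' @export
print.overlap <- function(x, ...) {
  cat(sprintf("Overlap index %.3f (directed fractions %.3f, %.3f)\n",
              x$index, x$frac_a, x$frac_b))
  invisible(x)
}

#' Match simultaneous fixes of two trajectories
#'
#' Greedy one-to-one matching in time order: each fix of A is matched to the
#' nearest unmatched fix of B within the buffer. Greediness prevents
#' double-pairing when schedules drift within the buffer.
#'
#' @param traj_a,traj_b projected `traj` objects.
#' @param buffer maximum time difference in seconds (default 300 s = 5 min,
#'   the collars' location-timing jitter).
#' @return Data frame with `i` (A fix), `j` (B fix), `dt` (seconds) and the
#'   paired coordinates `xa`, `ya`, `xb`, `yb`.
#' @export
simultaneous_pairs <- function(traj_a, traj_b, buffer = 300) {
  ta <- as.numeric(traj_a$fixes$t)
  tb <- as.numeric(traj_b$fixes$t)
  used <- logical(length(tb))
  ii <- jj <- integer(0)
  lo <- 1L
  for (i in seq_along(ta)) {
    while (lo <= length(tb) && (tb[lo] < ta[i] - buffer || used[lo])) {
      lo <- lo + 1L
    }
    k <- lo
    best <- 0L; bestdt <- Inf
    while (k <= length(tb) && tb[k] <= ta[i] + buffer) {
      if (!used[k] && abs(tb[k] - ta[i]) < bestdt) {
        best <- k; bestdt <- abs(tb[k] - ta[i])
      }
      k <- k + 1L
    }
    if (best > 0L) {
      used[best] <- TRUE
      ii <- c(ii, i); jj <- c(jj, best)
    }
  }
  data.frame(i = ii, j = jj, dt = tb[jj] - ta[ii],
             xa = traj_a$fixes$x[ii], ya = traj_a$fixes$y[ii],
             xb = traj_b$fixes$x[jj], yb = traj_b$fixes$y[jj])
}

#' Minta spatial coefficient from use counts
#'
#' With `q` the areal fraction of the home range occupied by the shared zone,
#' `k` fixes observed inside the shared zone and `m` inside the range but
#' outside it, `L = ln[(k/(n q)) / (m/(n (1-q)))]`. Significance is an exact
#' two-sided binomial test of `k` successes in `k + m` trials at probability
#' `q`. Zero cells yield infinite sentinels, never silent drops.
#'
#' @param k fixes in the shared zone.
#' @param m fixes in the range but outside the shared zone.
#' @param q areal proportion of the shared zone (0 < q < 1).
#' @param alpha significance level for the response label (default 0.05).
#' @return List: `L`, `p`, `response` (`"attraction"`, `"avoidance"` or
#'   `"random"`), `k`, `m`, `q`.
#' @export
minta_spatial_counts <- function(k, m, q, alpha = 0.05) {
  stopifnot(q > 0, q < 1, k >= 0, m >= 0)
  if (k + m == 0) stop("no fixes inside the home range; L undefined")
  L <- log((k / q) / (m / (1 - q)))  # n cancels
  p <- stats::binom.test(k, k + m, p = q)$p.value
  response <- if (p < alpha && L > 0) "attraction"
              else if (p < alpha && L < 0) "avoidance"
              else "random"
  list(L = L, p = p, response = response, k = k, m = m, q = q)
}

#' Minta spatial coefficient of one animal towards a shared area
#'
#' Geometric wrapper around [minta_spatial_counts()]: counts the animal's
#' fixes inside its home-range isopleth and inside the shared region, and
#' takes `q` from the two areas.
#'
#' @param traj the animal's projected `traj`.
#' @param hr its 95% `"isopleth"`.
#' @param shared the shared region from [shared_region()].
#' @param alpha significance level.
#' @return As [minta_spatial_counts()].
#' @export
minta_spatial <- function(traj, hr, shared, alpha = 0.05) {
  if (shared$area <= 0) stop("shared area must have positive area")
  f <- traj$fixes
  in_hr <- in_isopleth(hr, f$x, f$y)
  in_sh <- in_shared(shared, f$x, f$y)
  k <- sum(in_hr & in_sh)
  m <- sum(in_hr & !in_sh)
  q <- min(max(shared$area / hr$area, 1e-12), 1 - 1e-12)
  minta_spatial_counts(k, m, q, alpha = alpha)
}

#' Shared region of two home ranges
#'
#' @param iso_a,iso_b 95% `"isopleth"` objects.
#' @param grid_n grid resolution for the intersection area.
#' @return Class `"shared_region"`: member hull sets of both animals, the
#'   intersection `area` (m^2) and outline `rings`.
#' @export
shared_region <- function(iso_a, iso_b, grid_n = 384) {
  xr <- range(unlist(lapply(c(iso_a$polys, iso_b$polys),
                            function(p) range(p[, 1]))))
  yr <- range(unlist(lapply(c(iso_a$polys, iso_b$polys),
                            function(p) range(p[, 2]))))
  grid <- make_grid(xr, yr, n = grid_n)
  ma <- grid_membership(grid, iso_a$polys)
  mb <- grid_membership(grid, iso_b$polys)
  mm <- ma & mb
  structure(list(polys_a = iso_a$polys, polys_b = iso_b$polys,
                 area = grid_area(grid, mm), rings = grid_outline(grid, mm)),
            class = "shared_region")
}

#' Exact membership test for a shared region
#'
#' @param shared a `"shared_region"`.
#' @param x,y planar coordinates.
#' @return Logical: inside both animals' home-range hull unions.
#' @export
in_shared <- function(shared, x, y) {
  in_any <- function(polys) {
    inside <- rep(FALSE, length(x))
    for (p in polys) {
      todo <- which(!inside & x >= min(p[, 1]) & x <= max(p[, 1]) &
                    y >= min(p[, 2]) & y <= max(p[, 2]))
      if (length(todo)) {
        inside[todo] <- points_in_convex(x[todo], y[todo], p)
      }
    }
    inside
  }
  in_any(shared$polys_a) & in_any(shared$polys_b)
}

#' Minta temporal interaction coefficient
#'
#' From the joint presence/absence of the two animals in the shared area at
#' their simultaneous fixes. Marginal presence probabilities are estimated
#' from the pairs themselves (the independence null), expected cell
#' probabilities are their products, `odds_c = n_c / (n p_c)` and
#' `L_ixn = ln[(odds_AB + odds_00) / (odds_A0 + odds_0B)]`. The default p is
#' a chi-square goodness-of-fit with 1 df; `p_method = "rotation"` replaces
#' it with a circular time-rotation null (all n circular shifts of B's
#' presence sequence, computed via FFT cross-correlation), which preserves
#' each series' autocorrelation and is the robust choice for telemetry
#' schedules.
#'
#' @param in_a,in_b logical vectors over the simultaneous pairs: animal in
#'   the shared area.
#' @param p_method `"chisq"` or `"rotation"`.
#' @param alpha significance level for the label.
#' @param trend_threshold |L_ixn| below which a non-significant result is
#'   labelled `"random"` rather than a trend (default 0.25).
#' @return List: `L_ixn`, `p`, `label`, `odds` (named AB, A0, 0B, 00),
#'   `observed`, `expected`, `n`, `p_method`.
#' @export
minta_temporal <- function(in_a, in_b, p_method = c("chisq", "rotation"),
                           alpha = 0.05, trend_threshold = 0.25) {
  p_method <- match.arg(p_method)
  stopifnot(length(in_a) == length(in_b))
  n <- length(in_a)
  if (n < 1) stop("need at least one simultaneous pair")
  obs <- c(AB = sum(in_a & in_b), A0 = sum(in_a & !in_b),
           `0B` = sum(!in_a & in_b), `00` = sum(!in_a & !in_b))
  pa <- (obs["AB"] + obs["A0"]) / n
  pb <- (obs["AB"] + obs["0B"]) / n
  pexp <- c(AB = pa * pb, A0 = pa * (1 - pb), `0B` = (1 - pa) * pb,
            `00` = (1 - pa) * (1 - pb))
  names(pexp) <- names(obs)
  if (any(pexp == 0)) {
    stop("degenerate margin: an expected cell probability is zero")
  }
  odds <- obs / (n * pexp)
  L <- lixn_from_odds(odds)
  p <- if (p_method == "chisq") {
    x2 <- sum((obs - n * pexp)^2 / (n * pexp))
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  } else {
    rotation_p(in_a, in_b)
  }
  list(L_ixn = L, p = p,
       label = temporal_label(L, p, alpha, trend_threshold),
       odds = odds, observed = obs, expected = n * pexp, n = n,
       p_method = p_method)
}

# ln((AB + 00) / (A0 + 0B)) with infinite sentinels for zero denominators.
lixn_from_odds <- function(odds) {
  num <- odds[["AB"]] + odds[["00"]]
  den <- odds[["A0"]] + odds[["0B"]]
  if (den == 0) return(Inf)
  if (num == 0) return(-Inf)
  log(num / den)
}

# Two-sided circular-rotation p for L_ixn. Margins are rotation-invariant,
# so every cell is a function of nAB alone and all n shifts are evaluated at
# once through an FFT circular cross-correlation.
rotation_p <- function(in_a, in_b) {
  n <- length(in_a)
  a <- as.numeric(in_a); b <- as.numeric(in_b)
  nab <- round(Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)),
                             inverse = TRUE)) / n)
  na <- sum(a); nb <- sum(b)
  pa <- na / n; pb <- nb / n
  pexp <- c(pa * pb, pa * (1 - pb), (1 - pa) * pb, (1 - pa) * (1 - pb))
  Lk <- vapply(nab, function(k) {
    odds <- c(AB = k, A0 = na - k, `0B` = nb - k, `00` = n - na - nb + k) /
      (n * pexp)
    lixn_from_odds(odds)
  }, numeric(1))
  obs <- Lk[1]  # shift 0
  mean(abs(Lk) >= abs(obs) - 1e-12)
}

temporal_label <- function(L, p, alpha, trend_threshold) {
  if (is.finite(p) && p < alpha && L > 0) return("Simultaneous")
  if (is.finite(p) && p < alpha && L < 0) return("Solitary")
  if (L >= trend_threshold) return("Simultaneous trend")
  if (L <= -trend_threshold) return("Solitary trend")
  "Random"
}

#' Classify a dyad from its Minta coefficients
#'
#' Spatial: symmetric when both animals respond significantly with the same
#' sign, asymmetric with opposite signs, singular when exactly one responds,
#' random otherwise. The temporal label is passed through.
#'
#' @param spatial_a,spatial_b results of [minta_spatial()].
#' @param temporal result of [minta_temporal()].
#' @return List with `spatial` and `temporal` labels.
#' @export
classify_dyad <- function(spatial_a, spatial_b, temporal) {
  ra <- spatial_a$response; rb <- spatial_b$response
  sig_a <- ra != "random"; sig_b <- rb != "random"
  spatial <- if (sig_a && sig_b && ra == rb) {
    paste("Symmetric", ra)
  } else if (sig_a && sig_b) {
    "Asymmetric"
  } else if (sig_a || sig_b) {
    paste("Singular", if (sig_a) ra else rb)
  } else {
    "Random"
  }
  list(spatial = spatial, temporal = temporal$label)
}

#' Full Minta analysis of one dyad
#'
#' @param traj_a,traj_b projected `traj` objects of the two neighbours.
#' @param hr_a,hr_b their 95% `"isopleth"` home ranges.
#' @param buffer simultaneity buffer in seconds (default 300).
#' @param p_method temporal p-value method, see [minta_temporal()].
#' @param alpha significance level.
#' @return Object of class `"minta"`: `spatial_a`, `spatial_b`, `temporal`,
#'   `labels`, `odds`, `shared` (the [shared_region()]), `n_pairs`.
#' @export
minta <- function(traj_a, traj_b, hr_a, hr_b, buffer = 300,
                  p_method = c("chisq", "rotation"), alpha = 0.05) {
  p_method <- match.arg(p_method)
  shared <- shared_region(hr_a, hr_b)
  if (shared$area <= 0) stop("home ranges do not overlap; no shared area")
  sa <- minta_spatial(traj_a, hr_a, shared, alpha = alpha)
  sb <- minta_spatial(traj_b, hr_b, shared, alpha = alpha)
  pairs <- simultaneous_pairs(traj_a, traj_b, buffer = buffer)
  if (!nrow(pairs)) stop("no simultaneous fixes within the buffer")
  in_a <- in_shared(shared, pairs$xa, pairs$ya)
  in_b <- in_shared(shared, pairs$xb, pairs$yb)
  tmp <- minta_temporal(in_a, in_b, p_method = p_method, alpha = alpha)
  structure(list(a = traj_a$animal_id, b = traj_b$animal_id,
                 spatial_a = sa, spatial_b = sb, temporal = tmp,
                 labels = classify_dyad(sa, sb, tmp),
                 odds = tmp$odds, shared = shared, n_pairs = nrow(pairs)),
            class = "minta")
}

#' @export
print.minta <- function(x, ...) {
  cat("Minta dyad:", x$a, "-", x$b, "\n")
  cat(sprintf("  L_A:A' = %6.2f (p = %.3f)   L_B:B' = %6.2f (p = %.3f)\n",
              x$spatial_a$L, x$spatial_a$p, x$spatial_b$L, x$spatial_b$p))
  cat(sprintf("  L_ixn  = %6.2f (p = %.3f, %s, n = %d pairs)\n",
              x$temporal$L_ixn, x$temporal$p, x$temporal$p_method, x$n_pairs))
  cat(sprintf("  odds (AB, A0, 0B, 00): %s\n",
              paste(sprintf("%.2f", x$odds), collapse = ", ")))
  cat("  response:", x$labels$spatial, "/", x$labels$temporal, "\n")
  invisible(x)
}

#' @export
summary.minta <- function(object, ...) {
  print(object)
  cat("  shared area:", sprintf("%.3f km^2", object$shared$area / 1e6), "\n")
  invisible(object)
}
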