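# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored data.

# Trajectory from planar coordinates with an hourly (or custom) schedule.
make_traj <- function(x, y, t = NULL, id = "T1", dt = 3600) {
  n <- length(x)
  if (is.null(t)) {
    t <- as.POSIXct("2019-03-15", tz = "UTC") + (seq_len(n) - 1) * dt
  }
  trajectory(id, t, x = x, y = y)
}

# Axis-aligned rectangle as a CCW polygon.
rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# Wrap a bare polygon as a minimal isopleth-like object so dyad-level
# functions can be exercised on exactly-known geometry.
fake_iso <- function(...) {
  polys <- list(...)
  structure(list(level = 0.95, ordering = "density", polys = polys,
                 area = sum(vapply(polys, poly_area, numeric(1))),
                 n_fixes = NA_integer_, frac = NA_real_, partial = FALSE,
                 rings = polys, grid_n = NA_integer_),
            class = "isopleth")
}

# Independent convex-hull oracle: Jarvis gift-wrapping plus triangle-fan
# area, sharing no code with the package's chull/shoelace path.
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
            (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) break
  }
  if (length(hull) < 3) return(0)
  v <- pts[hull, , drop = FALSE]
  a <- 0
  for (i in 2:(nrow(v) - 1)) {
    a <- a + ((v[i, 1] - v[1, 1]) * (v[i + 1, 2] - v[1, 2]) -
              (v[i, 2] - v[1, 2]) * (v[i + 1, 1] - v[1, 1])) / 2
  }
  as.numeric(abs(a))
}

# Exact Fisher p for an r x c table by full enumeration over tables with the
# observed margins (conditional multivariate hypergeometric), two-sided by
# summing probabilities <= that of the observed table.
oracle_fisher_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  lfact <- lfactorial
  log_prob <- function(m) {
    sum(lfact(rs)) + sum(lfact(cs)) - lfact(sum(m)) - sum(lfact(m))
  }
  tables <- list()
  fill <- function(m, r, c) {
    if (r == nrow(tab)) {
      last_row <- cs - colSums(m[seq_len(r - 1), , drop = FALSE])
      if (all(last_row >= 0) && sum(last_row) == rs[r]) {
        m[r, ] <- last_row
        tables[[length(tables) + 1L]] <<- m
      }
      return(invisible())
    }
    if (c == ncol(tab)) {
      rem <- rs[r] - sum(m[r, seq_len(c - 1)])
      if (rem >= 0 && rem <= cs[c]) {
        m[r, c] <- rem
        fill(m, r + 1L, 1L)
      }
      return(invisible())
    }
    maxv <- min(rs[r] - sum(m[r, seq_len(c - 1)]), cs[c])
    for (v in 0:maxv) {
      m[r, c] <- v
      fill(m, r, c + 1L)
    }
  }
  fill(matrix(0L, nrow(tab), ncol(tab)), 1L, 1L)
  lp <- vapply(tables, log_prob, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  p_obs <- p[which(vapply(tables, function(m) all(m == tab), logical(1)))[1]]
  sum(p[p <= p_obs + 1e-9])
}

# L_ixn reconstruction straight from four odds (test-side arithmetic).
oracle_lixn <- function(ab, a0, b0, oo) log((ab + oo) / (a0 + b0))
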