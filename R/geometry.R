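# Planar computational geometry for hull-based home-range estimation.
# All polygons are two-column matrices (x, y) in metres. Convex polygons are
# stored counter-clockwise without a repeated closing vertex.

#' Convex hull polygon of a point set
#'
#' Returns the convex hull as a counter-clockwise two-column matrix, or `NULL`
#' when the points are degenerate (fewer than three distinct non-collinear
#' points), in which case no polygon exists.
#'
#' @param x,y numeric coordinate vectors of equal length.
#' @return A two-column matrix of hull vertices (counter-clockwise), or `NULL`.
#' @export
convex_poly <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(NULL)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) return(NULL)
  poly <- pts[rev(h), , drop = FALSE]  # chull is clockwise; reverse to CCW
  dimnames(poly) <- list(NULL, c("x", "y"))
  if (poly_area(poly) <= 0) return(NULL)
  poly
}

#' Polygon area (shoelace formula)
#'
#' @param poly two-column vertex matrix (closed implicitly).
#' @return Area in squared input units (non-negative).
#' @export
poly_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nrow(poly), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Boundary-inclusive point-in-convex-polygon test for a CCW polygon.
# Vectorised over points; tolerance scales with polygon size so fixes lying
# exactly on a hull edge (e.g. hull parents) count as enclosed.
points_in_convex <- function(px, py, poly, tol = NULL) {
  n <- nrow(poly)
  if (is.null(tol)) {
    tol <- 1e-9 * max(diff(range(poly[, 1])), diff(range(poly[, 2])), 1)
  }
  inside <- rep(TRUE, length(px))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    cross <- (poly[k2, 1] - poly[k, 1]) * (py - poly[k, 2]) -
             (poly[k2, 2] - poly[k, 2]) * (px - poly[k, 1])
    inside <- inside & (cross >= -tol)
    if (!any(inside)) break
  }
  inside
}

#' Intersection of two convex polygons
#'
#' Sutherland–Hodgman clipping of `p` against convex `q`. Both inputs must be
#' counter-clockwise. Returns the intersection polygon or `NULL` when the
#' interiors do not meet.
#'
#' @param p,q convex polygons (two-column CCW matrices).
#' @return The clipped polygon matrix, or `NULL`.
#' @export
clip_convex <- function(p, q) {
  out <- p
  nq <- nrow(q)
  for (k in seq_len(nq)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    k2 <- if (k == nq) 1L else k + 1L
    ax <- q[k, 1]; ay <- q[k, 2]
    ex <- q[k2, 1] - ax; ey <- q[k2, 2] - ay
    side <- ex * (out[, 2] - ay) - ey * (out[, 1] - ax)  # >= 0 is inside (CCW)
    n <- nrow(out)
    nxt <- c(2:n, 1)
    keep <- vector("list", n)
    for (i in seq_len(n)) {
      j <- nxt[i]
      ci <- side[i]; cj <- side[j]
      seg <- NULL
      if (ci >= 0) seg <- out[i, , drop = FALSE]
      if ((ci >= 0) != (cj >= 0)) {
        t <- ci / (ci - cj)
        ip <- out[i, ] + t * (out[j, ] - out[i, ])
        seg <- rbind(seg, ip)
      }
      keep[[i]] <- seg
    }
    out <- do.call(rbind, keep)
    if (!is.null(out)) out <- out[!duplicated(round(out, 9)), , drop = FALSE]
  }
  if (is.null(out) || nrow(out) < 3 || poly_area(out) <= 0) return(NULL)
  out
}

# Separating-axis test for convex polygon overlap (boundary contact counts).
convex_overlap <- function(p, q) {
  axes_sep <- function(a, b) {
    n <- nrow(a)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      # outward normal of CCW edge
      nx <- a[k2, 2] - a[k, 2]
      ny <- a[k, 1] - a[k2, 1]
      pa <- a[, 1] * nx + a[, 2] * ny
      pb <- b[, 1] * nx + b[, 2] * ny
      if (max(pa) < min(pb) || max(pb) < min(pa)) return(TRUE)
    }
    FALSE
  }
  !(axes_sep(p, q) || axes_sep(q, p))
}

# Minimum distance between two convex polygons (0 if they overlap or touch).
convex_dist <- function(p, q) {
  if (convex_overlap(p, q)) return(0)
  min(points_segments_dist(p, q), points_segments_dist(q, p))
}

# Minimum distance from the vertices of `pts_poly` to the edges of `seg_poly`.
points_segments_dist <- function(pts_poly, seg_poly) {
  n <- nrow(seg_poly)
  j <- c(2:n, 1)
  ax <- seg_poly[, 1]; ay <- seg_poly[, 2]
  bx <- seg_poly[j, 1]; by <- seg_poly[j, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- pmax(dx^2 + dy^2, .Machine$double.eps)
  best <- Inf
  for (i in seq_len(nrow(pts_poly))) {
    t <- ((pts_poly[i, 1] - ax) * dx + (pts_poly[i, 2] - ay) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (ax + t * dx - pts_poly[i, 1])^2 + (ay + t * dy - pts_poly[i, 2])^2
    best <- min(best, d2)
  }
  sqrt(best)
}

#' Regular polygon approximating a circle
#'
#' @param center length-2 numeric (x, y).
#' @param r radius.
#' @param n number of vertices.
#' @return CCW vertex matrix.
#' @export
circle_poly <- function(center, r, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# ---- grid machinery for unions of many convex hulls -------------------------
# A union of local hulls is generally non-convex; areas and outlines are
# computed on a regular grid of cell centres (resolution-documented, see the
# methods vignette) while point membership is always tested exactly against
# the member hulls.

make_grid <- function(xlim, ylim, n = 256, pad = 0.02) {
  w <- max(xlim[2] - xlim[1], 1e-6)
  h <- max(ylim[2] - ylim[1], 1e-6)
  px <- w * pad; py <- h * pad
  xlim <- xlim + c(-px, px); ylim <- ylim + c(-py, py)
  cell <- max(xlim[2] - xlim[1], ylim[2] - ylim[1]) / n
  xs <- seq(xlim[1] + cell / 2, xlim[2], by = cell)
  ys <- seq(ylim[1] + cell / 2, ylim[2], by = cell)
  list(x = xs, y = ys, cell = cell)
}

# Logical matrix [length(x), length(y)] marking cell centres inside any hull.
grid_membership <- function(grid, hulls) {
  m <- matrix(FALSE, length(grid$x), length(grid$y))
  for (h in hulls) {
    ix <- which(grid$x >= min(h[, 1]) - grid$cell & grid$x <= max(h[, 1]) + grid$cell)
    iy <- which(grid$y >= min(h[, 2]) - grid$cell & grid$y <= max(h[, 2]) + grid$cell)
    if (!length(ix) || !length(iy)) next
    sub <- m[ix, iy, drop = FALSE]
    todo <- which(!sub)
    if (!length(todo)) next
    px <- grid$x[ix][(todo - 1) %% length(ix) + 1]
    py <- grid$y[iy][(todo - 1) %/% length(ix) + 1]
    sub[todo] <- points_in_convex(px, py, h)
    m[ix, iy] <- sub
  }
  m
}

grid_area <- function(grid, m) sum(m) * grid$cell^2

# Boundary rings of a gridded region via marching squares; the matrix is
# padded with FALSE so rings always close.
grid_outline <- function(grid, m) {
  z <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  z[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m * 1
  xs <- c(grid$x[1] - grid$cell, grid$x, grid$x[length(grid$x)] + grid$cell)
  ys <- c(grid$y[1] - grid$cell, grid$y, grid$y[length(grid$y)] + grid$cell)
  cl <- grDevices::contourLines(xs, ys, z, levels = 0.5)
  lapply(cl, function(r) cbind(x = r$x, y = r$y))
}

# Minimum distance between two point sets given as two-column matrices.
min_dist_points <- function(a, b, chunk = 2000L) {
  best <- Inf
  for (i in seq(1, nrow(a), by = chunk)) {
    ii <- i:min(i + chunk - 1, nrow(a))
    d2 <- outer(a[ii, 1], b[, 1], "-")^2 + outer(a[ii, 2], b[, 2], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}
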