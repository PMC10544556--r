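# Seeded synthetic movement data with the statistical structure the analysis
# assumes: range-resident central-place movement around a den (a discrete
# mean-reverting walk), collar-like fix schedules, injectable excursions,
# dyad regimes with known spatio-temporal truth, and patchy habitat rasters.
# All randomness flows from one configured seed through a documented
# splitting scheme (derive_seed), so outputs are byte-identical per seed.

#' Simulation configuration
#'
#' Defaults emulate the collar schedule and season of a fox telemetry
#' campaign: 12--16 fixes/day at 1.5--2 h intervals from mid-March over ~3
#' months, and a den-centred range whose 95% radius is about 2 km.
#'
#' @param seed master seed (all sub-generators derive from it).
#' @param n_days track duration in days.
#' @param fix_interval `c(min, max)` seconds between fixes (default 1.5--2 h).
#' @param den den location `c(x, y)` in metres.
#' @param attraction per-step pull towards the den, in (0, 1].
#' @param step_sd isotropic per-step noise sd in metres.
#' @param start UTC start time.
#' @param proj_center nominal `c(lon, lat)` used to back-fill geographic
#'   coordinates for round-tripping through fix tables.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, n_days = 90, fix_interval = c(5400, 7200),
                       den = c(0, 0), attraction = 0.1, step_sd = 350,
                       start = as.POSIXct("2019-03-15", tz = "UTC"),
                       proj_center = c(-94, 58)) {
  if (attraction <= 0 || attraction > 1) {
    stop("attraction must be in (0, 1]")
  }
  stopifnot(n_days > 0, length(fix_interval) == 2,
            fix_interval[1] > 0, fix_interval[2] >= fix_interval[1])
  structure(list(seed = seed, n_days = n_days, fix_interval = fix_interval,
                 den = den, attraction = attraction, step_sd = step_sd,
                 start = start, proj_center = proj_center),
            class = "sim_config")
}

# Deterministic seed splitting; keeps derived seeds in [0, 2^31).
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + as.numeric(k) * 30269) %% 2147483647
}

# Stationary sd (per axis) and 95% range radius of the mean-reverting walk.
ou_stationary_sd <- function(cfg) {
  cfg$step_sd / sqrt(1 - (1 - cfg$attraction)^2)
}

ou_r95 <- function(cfg) {
  # 95% quantile of a Rayleigh distance: sigma * sqrt(2 log 20)
  ou_stationary_sd(cfg) * sqrt(2 * log(20))
}

#' Simulate one range-resident central-place forager
#'
#' Discrete-time mean-reverting walk: position_{t+1} = position_t +
#' attraction * (den - position_t) + isotropic Gaussian noise, started from
#' the stationary distribution so the variogram plateaus from the outset.
#'
#' @param cfg a [sim_config()].
#' @param animal_id,species,season labels for the trajectory.
#' @return A projected `traj` (planar metres plus back-filled lon/lat).
#' @export
simulate_forager <- function(cfg, animal_id = "sim1", species = "AF",
                             season = "2019") {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(derive_seed(cfg$seed, 1))
  mean_dt <- mean(cfg$fix_interval)
  n <- max(3L, floor(cfg$n_days * 86400 / mean_dt))
  dt <- stats::runif(n, cfg$fix_interval[1], cfg$fix_interval[2])
  t <- cfg$start + cumsum(dt)
  phi <- 1 - cfg$attraction
  sd_st <- ou_stationary_sd(cfg)
  ox <- stats::filter(stats::rnorm(n, 0, cfg$step_sd), phi,
                      method = "recursive", init = stats::rnorm(1, 0, sd_st))
  oy <- stats::filter(stats::rnorm(n, 0, cfg$step_sd), phi,
                      method = "recursive", init = stats::rnorm(1, 0, sd_st))
  x <- cfg$den[1] + as.numeric(ox)
  y <- cfg$den[2] + as.numeric(oy)
  ll <- tm_inverse(x, y, cfg$proj_center[1], cfg$proj_center[2])
  tr <- trajectory(animal_id, t, lon = ll[, 1], lat = ll[, 2], x = x, y = y,
                   species = species, season = season)
  tr$projection <- list(lon0 = cfg$proj_center[1], lat0 = cfg$proj_center[2])
  tr$vmax <- compute_vmax(tr)
  tr
}

#' 95% range radius of a track
#'
#' @param traj projected `traj`.
#' @param q quantile (default 0.95).
#' @return Distance quantile (m) of fixes from the track centroid.
#' @export
range_radius <- function(traj, q = 0.95) {
  f <- traj$fixes
  d <- sqrt((f$x - mean(f$x))^2 + (f$y - mean(f$y))^2)
  unname(stats::quantile(d, q))
}

#' Inject excursions into a trajectory
#'
#' Displaces chosen runs of fixes along a random bearing to
#' `multiplier x` the 95% range radius, with a half-sine out-and-back profile
#' scaled to [0.5, 1] of the peak so every fix of the excursion lies far
#' outside the range.
#'
#' @param traj projected `traj`.
#' @param n_excursions number of non-overlapping excursions.
#' @param duration fixes per excursion.
#' @param multiplier peak displacement as a multiple of the 95% range radius
#'   (must exceed 1).
#' @param seed optional seed (defaults to a split of nothing — supply one for
#'   reproducibility).
#' @return List: `traj` (with displaced fixes), `mask` (logical truth mask of
#'   injected fixes).
#' @export
inject_excursions <- function(traj, n_excursions = 1, duration = 6,
                              multiplier = 10, seed = NULL) {
  stopifnot(multiplier > 1, duration >= 1, n_excursions >= 0)
  n <- n_fixes(traj)
  if (n_excursions * (duration + 2) > n) {
    stop("requested excursions longer than the track")
  }
  mask <- logical(n)
  if (n_excursions == 0) return(list(traj = traj, mask = mask))
  if (!is.null(seed)) local_seed(seed)
  r95 <- range_radius(traj)
  block <- floor(n / n_excursions)
  f <- traj$fixes
  for (e in seq_len(n_excursions)) {
    lo <- (e - 1L) * block + 2L
    hi <- e * block - duration - 1L
    start <- if (hi > lo) sample(lo:hi, 1) else lo
    idx <- start:(start + duration - 1L)
    theta <- stats::runif(1, 0, 2 * pi)
    prof <- 0.5 + 0.5 * sin(pi * seq_len(duration) / (duration + 1))
    disp <- multiplier * r95 * prof
    f$x[idx] <- f$x[idx] + cos(theta) * disp
    f$y[idx] <- f$y[idx] + sin(theta) * disp
    mask[idx] <- TRUE
  }
  if (!is.null(traj$projection)) {
    ll <- tm_inverse(f$x, f$y, traj$projection$lon0, traj$projection$lat0)
    f$lon <- ll[, 1]; f$lat <- ll[, 2]
  }
  traj$fixes <- f
  traj$centroid <- c(mean(f$x), mean(f$y))
  list(traj = traj, mask = mask)
}

#' Simulate a dyad of neighbours with a known interaction regime
#'
#' Two dens are placed so the (theoretical) 95% ranges overlap; both animals
#' run on the same collar schedule with small independent timing jitter.
#' Regimes manipulate the fix schedule, not the step dynamics, so the
#' temporal truth is unambiguous:
#' * `independent` — no manipulation;
#' * `cohesive` — whenever A is in the shared area, B's simultaneous fix is
#'   relocated next to A with probability `compliance`;
#' * `exclusive` — whenever both are in the shared area simultaneously, B's
#'   fix is reflected through its own den, out of the shared area.
#'
#' @param cfg a [sim_config()].
#' @param regime `"independent"`, `"cohesive"` or `"exclusive"`.
#' @param compliance probability B follows A under the cohesive regime.
#' @param separation den separation as a multiple of the theoretical 95%
#'   range radius (default 1.5, giving a moderate shared area).
#' @return List: `a`, `b` (projected `traj`), `shared_truth` (the convex lens
#'   where the theoretical ranges intersect), `regime`, `expected_sign` of
#'   L_ixn (+1, -1, or 0).
#' @export
simulate_dyad <- function(cfg, regime = c("independent", "cohesive",
                                          "exclusive"),
                          compliance = 0.9, separation = 1.5) {
  regime <- match.arg(regime)
  stopifnot(inherits(cfg, "sim_config"))
  r95 <- ou_r95(cfg)
  dsep <- separation * r95
  den_a <- cfg$den + c(-dsep / 2, 0)
  den_b <- cfg$den + c(dsep / 2, 0)
  cfg_a <- cfg; cfg_a$den <- den_a; cfg_a$seed <- derive_seed(cfg$seed, 11)
  cfg_b <- cfg; cfg_b$den <- den_b; cfg_b$seed <- derive_seed(cfg$seed, 12)
  a <- simulate_forager(cfg_a, animal_id = "A", species = "AF")
  b <- simulate_forager(cfg_b, animal_id = "B", species = "AF")

  # common schedule with +/- 2 min independent jitter (within the 5-min buffer)
  local_seed(derive_seed(cfg$seed, 13))
  n <- min(n_fixes(a), n_fixes(b))
  a$fixes <- a$fixes[seq_len(n), ]; b$fixes <- b$fixes[seq_len(n), ]
  base_t <- a$fixes$t
  a$fixes$t <- base_t + stats::runif(n, -120, 120)
  b$fixes$t <- base_t + stats::runif(n, -120, 120)

  shared <- clip_convex(circle_poly(den_a, r95), circle_poly(den_b, r95))
  in_a <- points_in_convex(a$fixes$x, a$fixes$y, shared)
  in_b <- points_in_convex(b$fixes$x, b$fixes$y, shared)
  if (regime == "cohesive") {
    follow <- in_a & stats::runif(n) < compliance
    k <- which(follow)
    b$fixes$x[k] <- a$fixes$x[k] + stats::rnorm(length(k), 0, 50)
    b$fixes$y[k] <- a$fixes$y[k] + stats::rnorm(length(k), 0, 50)
  } else if (regime == "exclusive") {
    clash <- which(in_a & in_b)
    b$fixes$x[clash] <- 2 * den_b[1] - b$fixes$x[clash]
    b$fixes$y[clash] <- 2 * den_b[2] - b$fixes$y[clash]
  }
  for (tr in c("a", "b")) {
    obj <- get(tr)
    ll <- tm_inverse(obj$fixes$x, obj$fixes$y, cfg$proj_center[1],
                     cfg$proj_center[2])
    obj$fixes$lon <- ll[, 1]; obj$fixes$lat <- ll[, 2]
    obj$centroid <- c(mean(obj$fixes$x), mean(obj$fixes$y))
    obj$vmax <- compute_vmax(obj)
    assign(tr, obj)
  }
  list(a = a, b = b, shared_truth = shared, regime = regime,
       expected_sign = switch(regime, independent = 0, cohesive = 1,
                              exclusive = -1))
}

#' Generate a patchy categorical habitat raster
#'
#' Seeded nucleation-and-growth mosaic: class nuclei are scattered over the
#' window in numbers proportional to the configured shares and every cell
#' takes the class of its nearest nucleus, yielding contiguous patches whose
#' realized shares track the configuration.
#'
#' @param cfg a [sim_config()] (supplies the seed).
#' @param legend named integer vector of classes; default the seven
#'   tundra-coast classes (barren land, wetland, tundra, shrubland, forest,
#'   intertidal, sea ice).
#' @param shares class area shares (recycled/normalized; default equal).
#' @param extent half-width of the square window in metres (default 8000).
#' @param cellsize cell size in metres (default 100).
#' @param n_nuclei number of patch nuclei (default 250).
#' @return A [habitat_raster()] centred on the origin.
#' @export
generate_habitat_raster <- function(cfg, legend = NULL, shares = NULL,
                                    extent = 8000, cellsize = 100,
                                    n_nuclei = 250) {
  if (is.null(legend)) {
    legend <- c(barren = 1L, wetland = 2L, tundra = 3L, shrubland = 4L,
                forest = 5L, intertidal = 6L, sea_ice = 7L)
  }
  k <- length(legend)
  if (is.null(shares)) shares <- rep(1 / k, k)
  shares <- shares / sum(shares)
  local_seed(derive_seed(cfg$seed, 21))
  n_nuclei <- max(n_nuclei, k)
  # largest-remainder allocation of nuclei to classes
  raw <- shares * n_nuclei
  cnt <- floor(raw)
  rem <- n_nuclei - sum(cnt)
  if (rem > 0) {
    cnt[order(raw - cnt, decreasing = TRUE)[seq_len(rem)]] <-
      cnt[order(raw - cnt, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  cls <- rep(unname(legend), times = cnt)
  sx <- stats::runif(n_nuclei, -extent, extent)
  sy <- stats::runif(n_nuclei, -extent, extent)
  ncell <- floor(2 * extent / cellsize)
  cx <- seq(-extent + cellsize / 2, by = cellsize, length.out = ncell)
  cy <- seq(-extent + cellsize / 2, by = cellsize, length.out = ncell)
  pts <- expand.grid(x = cx, y = cy)
  nearest <- rep(1L, nrow(pts))
  best <- (pts$x - sx[1])^2 + (pts$y - sy[1])^2
  for (i in seq_len(n_nuclei)[-1]) {
    d2 <- (pts$x - sx[i])^2 + (pts$y - sy[i])^2
    upd <- d2 < best
    nearest[upd] <- i
    best[upd] <- d2[upd]
  }
  vals <- matrix(cls[nearest], ncell, ncell)  # [x, y]
  # habitat_raster stores row 1 = north: transpose and flip
  m <- t(vals)[ncell:1, , drop = FALSE]
  habitat_raster(m, cellsize, xll = -extent, yll = -extent,
                 legend = legend)
}

#' Simulate a small multi-animal study
#'
#' Dens on a grid with spacing `spacing` metres, species labels alternating
#' between Arctic and red fox, one seeded trajectory per animal.
#'
#' @param cfg a [sim_config()].
#' @param n_animals number of animals (default 6).
#' @param spacing den spacing in metres (default 2500, close enough that all
#'   grid neighbours fall within the 3.2 km dyad rule).
#' @return Named list of projected `traj` objects with species labels.
#' @export
simulate_study <- function(cfg, n_animals = 6, spacing = 2500) {
  ncol_grid <- ceiling(sqrt(n_animals))
  out <- list()
  for (k in seq_len(n_animals)) {
    row <- (k - 1) %/% ncol_grid
    col <- (k - 1) %% ncol_grid
    cfg_k <- cfg
    cfg_k$den <- cfg$den + c(col * spacing, row * spacing)
    cfg_k$seed <- derive_seed(cfg$seed, 100 + k)
    id <- sprintf("F%02d", k)
    sp <- if (k %% 2 == 0) "RF" else "AF"
    out[[id]] <- simulate_forager(cfg_k, animal_id = id, species = sp)
  }
  out
}
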