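test_that("time-scaled distance reduces correctly and matches hand arithmetic", {
  # s = 0: time ignored
  expect_equal(tsd_distance(3, 4, 7200, s = 0, v_max = 2), 5)
  # dt = 0: planar distance
  expect_equal(tsd_distance(3, 4, 0, s = 0.05, v_max = 2), 5)
  # dx=3, dy=4, dt=3600, s=0.05, v_max=1 -> sqrt(25 + 180^2)
  expect_equal(tsd_distance(3, 4, 3600, s = 0.05, v_max = 1),
               sqrt(25 + 180^2), tolerance = 1e-12)
})

test_that("adaptive neighbour selection respects the cumulative budget", {
  # fixes on a line at 0, 1, 2, 3, 4 m, all simultaneous in TSD terms (s = 0)
  tr <- make_traj(c(0, 1, 2, 3, 4), rep(0, 5))

  # budget sums 1+2+3 = 6 <= 6: three neighbours
  nb <- select_neighbors_adaptive(tr, parent = 1, s = 0, a = 6, v_max = 1)
  expect_setequal(nb, 2:4)

  # huge budget: everyone
  nb <- select_neighbors_adaptive(tr, parent = 1, s = 0, a = 1e9, v_max = 1)
  expect_setequal(nb, 2:5)

  # vanishing budget: the 2-neighbour floor still applies
  nb <- select_neighbors_adaptive(tr, parent = 1, s = 0, a = 1e-9, v_max = 1)
  expect_equal(length(nb), 2)
  expect_setequal(nb, 2:3)

  expect_error(select_neighbors_adaptive(make_traj(0:1, 0:1), 1, 0, 1, 1),
               "at least 3")
})

test_that("hulls on toy geometry equal the brute-force oracle", {
  # unit square, generous budget: every hull is the square
  tr <- make_traj(c(0, 1, 1, 0), c(0, 0, 1, 1))
  fit <- tlocoh(tr, s = 0, a = 100, v_max = 1)
  expect_equal(nrow(fit$metrics), 4)
  expect_equal(fit$metrics$area, rep(1, 4))
  expect_equal(fit$metrics$n_enclosed, rep(4L, 4))

  # random <= 12-point clouds: hull area matches an independent Jarvis-march
  # + triangle-fan oracle exactly
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    x <- runif(n, 0, 1000)
    y <- runif(n, 0, 1000)
    tr <- make_traj(x, y)
    fit <- tlocoh(tr, s = 0, a = 1e9, v_max = 1)
    expect_equal(fit$metrics$area, rep(oracle_hull_area(x, y), n),
                 tolerance = 1e-9)
  }
})

test_that("degenerate point sets are skipped and reported, not hulled", {
  # three co-located den fixes force degenerate neighbour sets at small a
  x <- c(rep(0, 3), 100, 200, 300, 150, 250, 50, 175)
  y <- c(rep(0, 3), 80, 160, 240, 120, 200, 40, 140)
  tr <- make_traj(x, y)
  fit <- tlocoh(tr, s = 0, a = 1e-6, v_max = 1, max_skip_frac = 1)
  expect_gte(nrow(fit$skipped), 3)
  expect_true(all(fit$skipped$reason == "degenerate"))

  # every hull contains its parent fix
  cfg <- sim_config(seed = 41, n_days = 20)
  sim <- simulate_forager(cfg)
  fit2 <- tlocoh(sim)
  f <- fit2$traj$fixes
  ok <- vapply(fit2$hulls, function(h) {
    points_in_convex(f$x[h$parent], f$y[h$parent], h$poly)
  }, logical(1))
  expect_true(all(ok))
})

test_that("visit partitioning by the inter-visit gap drives NSV and MNLV", {
  # four co-located fixes at 0, 2, 14, 16 h with a 12-h gap: two visits of two
  tr <- make_traj(c(0, 0.1, 0, 0.1), c(0, 0, 0.1, 0.1),
                  t = as.POSIXct("2019-03-15", tz = "UTC") +
                      c(0, 2, 14, 16) * 3600)
  fit <- tlocoh(tr, s = 0, a = 100, v_max = 1, ivg = 43200)
  expect_equal(fit$metrics$nsv, rep(2L, 4))
  expect_equal(fit$metrics$mnlv, rep(2, 4))

  # all within one 6-h window: one visit containing everything
  tr1 <- make_traj(c(0, 0.1, 0, 0.1), c(0, 0, 0.1, 0.1),
                   t = as.POSIXct("2019-03-15", tz = "UTC") +
                       c(0, 2, 4, 6) * 3600)
  fit1 <- tlocoh(tr1, s = 0, a = 100, v_max = 1, ivg = 43200)
  expect_equal(fit1$metrics$nsv, rep(1L, 4))
  expect_equal(fit1$metrics$mnlv, rep(4, 4))

  # 24-h spacing: every enclosed fix is its own visit
  tr2 <- make_traj(c(0, 0.1, 0.05), c(0, 0, 0.1),
                   t = as.POSIXct("2019-03-15", tz = "UTC") +
                       c(0, 24, 48) * 3600)
  fit2 <- tlocoh(tr2, s = 0, a = 100, v_max = 1, ivg = 43200)
  expect_equal(fit2$metrics$nsv, rep(3L, 3))
  expect_equal(fit2$metrics$mnlv, rep(1, 3))

  # nsv = 1 implies mnlv = n_enclosed (simulated track, any params)
  cfg <- sim_config(seed = 42, n_days = 20)
  fit3 <- tlocoh(simulate_forager(cfg))
  m <- fit3$metrics
  one <- m$nsv == 1L
  if (any(one)) expect_equal(m$mnlv[one], as.numeric(m$n_enclosed[one]))
})

test_that("isopleths nest, cover and order by use density", {
  cfg <- sim_config(seed = 43, n_days = 30)
  fit <- tlocoh(simulate_forager(cfg))

  iso <- isopleths(fit, levels = c(0.5, 0.95, 1.0))
  i50 <- iso$isopleths[[1]]; i95 <- iso$isopleths[[2]]; i100 <- iso$isopleths[[3]]

  # coverage and nesting: member hulls are prefixes of the same ordering
  expect_gte(i50$frac, 0.5)
  expect_gte(i95$frac, 0.95)
  expect_equal(i100$frac, 1.0)
  expect_true(all(i50$hull_ids %in% i95$hull_ids))
  expect_lte(i50$area, i95$area)
  expect_lte(i95$area, i100$area)

  # spatial nesting: every fix inside the 50% region is inside the 95% one
  f <- fit$traj$fixes
  in50 <- in_isopleth(i50, f$x, f$y)
  in95 <- in_isopleth(i95, f$x, f$y)
  expect_true(all(in95[in50]))

  # density sanity: the core packs more fixes per unit area
  expect_gte(i50$n_fixes / i50$area, i95$n_fixes / i95$area)
})

test_that("density ordering picks the tighter of two clusters first", {
  set.seed(44)
  # cluster A is denser (same n, smaller spread); B sits 5 km away
  ax <- rep(seq(0, 90, by = 10), each = 5) + runif(50, 0, 5)
  ay <- rep(seq(0, 40, by = 10), times = 10) + runif(50, 0, 5)
  bx <- 5000 + rep(seq(0, 180, by = 20), each = 5) + runif(50, 0, 10)
  by <- rep(seq(0, 80, by = 20), times = 10) + runif(50, 0, 10)
  tr <- make_traj(c(ax, bx), c(ay, by))
  fit <- tlocoh(tr, s = 0, a = 300, v_max = 1)
  iso <- isopleths(fit, levels = c(0.5, 1.0), grid_n = 128)
  i50 <- iso$isopleths[[1]]
  # the 50% isopleth covers (essentially) only the dense cluster
  covered <- in_isopleth(i50, c(ax, bx), c(ay, by))
  expect_gte(mean(covered[1:50]), 0.9)
  expect_lte(mean(covered[51:100]), 0.1)
  expect_lt(i50$area, 0.6 * iso$isopleths[[2]]$area)
})

test_that("s = 0 hullsets are invariant to timestamp permutation", {
  cfg <- sim_config(seed = 45, n_days = 15)
  tr <- simulate_forager(cfg)
  fit <- tlocoh(tr, s = 0, a = 2000, v_max = 1)

  set.seed(9)
  f <- tr$fixes
  perm <- sample(nrow(f))
  tr2 <- tr
  tr2$fixes <- data.frame(t = f$t, lon = f$lon[perm], lat = f$lat[perm],
                          x = f$x[perm], y = f$y[perm])
  fit2 <- tlocoh(tr2, s = 0, a = 2000, v_max = 1)

  # same multiset of hull polygons (compare sorted areas and perimeters)
  per <- function(p) sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), ])^2)))
  expect_equal(sort(fit$metrics$area), sort(fit2$metrics$area),
               tolerance = 1e-9)
  expect_equal(sort(vapply(fit$hulls, function(h) per(h$poly), numeric(1))),
               sort(vapply(fit2$hulls, function(h) per(h$poly), numeric(1))),
               tolerance = 1e-9)
})

test_that("suggested s balances the time and space terms", {
  cfg <- sim_config(seed = 46, n_days = 60)
  tr <- simulate_forager(cfg)
  v <- compute_vmax(tr)
  s1 <- suggest_s(tr, period = 43200, v_max = v)
  expect_gte(s1, 0.005)
  expect_lte(s1, 0.2)

  # doubling every time interval (and the period with the schedule) halves s
  tr2 <- tr
  t0 <- tr$fixes$t[1]
  tr2$fixes$t <- t0 + 2 * as.numeric(tr$fixes$t - t0)
  s2 <- suggest_s(tr2, period = 2 * 43200, v_max = v)
  expect_equal(s2, s1 / 2, tolerance = 1e-9)

  # stationary track: spatial term vanishes, s clamps low with a warning
  st <- make_traj(rep(0, 120), rep(0, 120))
  expect_warning(s3 <- suggest_s(st, v_max = 1), "clamping")
  expect_equal(s3, 0.001)
})
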