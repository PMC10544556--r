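test_that("variogram bins mean squared half-displacements by lag", {
  # stationary track: all semivariances zero
  tr <- make_traj(rep(0, 12), rep(0, 12), dt = 7200)
  vg <- empirical_variogram(tr, bin_width = 2, max_lag = 48)
  expect_true(all(vg$semivariance == 0))

  # alternating 100-m hops every 2 h: odd lags -> d = 100 m -> 5000 m^2,
  # even lags -> 0
  tr <- make_traj(rep(c(0, 100), 5), rep(0, 10), dt = 7200)
  vg <- empirical_variogram(tr, bin_width = 2, max_lag = 48)
  odd <- vg$semivariance[vg$lag %in% c(3, 7, 11)]   # bin centres for 2-4 h etc.
  even <- vg$semivariance[vg$lag %in% c(5, 9, 13)]
  expect_equal(odd, rep(5000, length(odd)))
  expect_equal(even, rep(0, length(even)))
  expect_true(all(vg$n_pairs >= 1))

  expect_error(empirical_variogram(make_traj(1:5, 1:5)), "at least 10")
})

test_that("residency verdicts follow the tail/plateau ratio", {
  mk_vg <- function(lag, sv) {
    structure(data.frame(lag = lag, semivariance = sv,
                         n_pairs = rep(10L, length(lag))),
              class = c("variogram", "data.frame"))
  }
  lags <- seq(12, 40 * 24, by = 24)
  # flat: resident
  expect_equal(assess_residency(mk_vg(lags, rep(4e5, length(lags))))$verdict,
               "resident")
  # linear growth (Brownian-like): tail well above plateau
  expect_equal(assess_residency(mk_vg(lags, 1e3 * lags))$verdict,
               "non_resident")
  # no bins in a window -> inconclusive
  expect_error(assess_residency(mk_vg(c(12, 24), c(1, 1))), "inconclusive")

  # simulated resident plateaus; a mid-season den relocation does not
  cfg <- sim_config(seed = 11, n_days = 80)
  tr <- simulate_forager(cfg)
  vg <- empirical_variogram(tr)
  expect_equal(assess_residency(vg, tail_window = c(25, 38) * 24)$verdict,
               "resident")

  # disperser: den relocated 20 km at mid-season
  tr2 <- simulate_forager(sim_config(seed = 12, n_days = 80))
  f <- tr2$fixes
  late <- f$t > f$t[1] + 40 * 86400
  f$x[late] <- f$x[late] + 20000
  disp <- tr2; disp$fixes <- f
  vg2 <- empirical_variogram(disp)
  expect_equal(assess_residency(vg2, tail_window = c(25, 38) * 24)$verdict,
               "non_resident")
})

test_that("Tukey lambda tracks the shape of the sample", {
  set.seed(101)
  v <- rnorm(400, mean = 10, sd = 3)
  lam_norm <- tukey_lambda(v[v > 0])
  expect_gte(as.numeric(lam_norm), 0.7)
  expect_lte(as.numeric(lam_norm), 1.3)

  lam_ln <- tukey_lambda(exp(rnorm(400)))
  expect_gte(as.numeric(lam_ln), -0.3)
  expect_lte(as.numeric(lam_ln), 0.3)

  expect_warning(lam_const <- tukey_lambda(c(5, 5, 5, 5)), "constant")
  expect_equal(as.numeric(lam_const), 1)
  expect_error(tukey_lambda(c(1, 2)), "at least 3")
})

test_that("Hampel upper bound is median + 3 unscaled MADs", {
  expect_equal(hampel_upper_bound(1:9), 11)          # median 5, MAD 2
  expect_equal(hampel_upper_bound(rep(7, 5)), 7)     # MAD 0 -> the constant
  expect_equal(hampel_upper_bound(c(0, 0, 0, 100)), 0)  # degenerate MAD
})

test_that("excursion filter recovers injected loops and partitions the track", {
  cfg <- sim_config(seed = 21, n_days = 60)
  tr <- simulate_forager(cfg)

  # clean track: nothing beyond the bound stays, partition property holds
  ef <- remove_excursions(tr)
  expect_equal(nrow(ef$kept$fixes) + sum(ef$flagged), nrow(tr$fixes))
  expect_lt(mean(ef$flagged), 0.1)

  # one injected 6-fix loop at 10x the range radius is fully recovered
  inj <- inject_excursions(tr, n_excursions = 1, duration = 6,
                           multiplier = 10, seed = 5)
  ef1 <- remove_excursions(inj$traj)
  expect_true(all(ef1$flagged[inj$mask]))
  expect_true(any(vapply(seq_len(nrow(ef1$excursions)), function(i) {
    seg <- ef1$excursions$start_fix[i]:ef1$excursions$end_fix[i]
    all(which(inj$mask) %in% seg)
  }, logical(1))))

  # two excursions of 4 and 6 fixes -> at least those 10 fixes in >= 2 runs
  inj4 <- inject_excursions(tr, n_excursions = 1, duration = 4,
                            multiplier = 8, seed = 6)
  inj46 <- inject_excursions(inj4$traj, n_excursions = 1, duration = 6,
                             multiplier = 8, seed = 7)
  mask <- inj4$mask | inj46$mask
  ef2 <- remove_excursions(inj46$traj)
  expect_true(all(ef2$flagged[mask]))
  expect_gte(nrow(ef2$excursions), 2)

  # raising the multiplier never flags more fixes
  ef_k4 <- remove_excursions(inj$traj, k = 4)
  expect_lte(sum(ef_k4$flagged), sum(ef1$flagged))
  expect_true(all(which(ef_k4$flagged) %in% which(ef1$flagged)))
})

test_that("range-shift detection finds a moved activity centre", {
  # stationary centroid: strong reversion keeps segment centroids together
  cfg <- sim_config(seed = 31, n_days = 30, attraction = 0.5)
  a <- simulate_forager(cfg)
  expect_null(detect_range_shift(a))

  # centroid jump of 15 km at fix 120 of ~400
  b <- simulate_forager(sim_config(seed = 32, n_days = 30, attraction = 0.5))
  n <- nrow(a$fixes)
  f <- a$fixes
  cut <- 120
  f$x[(cut + 1):n] <- b$fixes$x[(cut + 1):n] + 15000
  f$y[(cut + 1):n] <- b$fixes$y[(cut + 1):n]
  jumped <- a; jumped$fixes <- f
  cp <- detect_range_shift(jumped)
  expect_false(is.null(cp))
  expect_lte(abs(cp$index - cut), 10)

  # a jump smaller than the home-range radius is not a shift
  f2 <- a$fixes
  f2$x[(cut + 1):n] <- f2$x[(cut + 1):n] + 400
  small <- a; small$fixes <- f2
  expect_null(detect_range_shift(small))
})
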