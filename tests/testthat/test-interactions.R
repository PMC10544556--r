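test_that("dyads form under the boundary-distance rule", {
  # unit: 1 km squares; overlapping pair, 3.3-km pair, mutually-near triple
  a <- fake_iso(rect_poly(0, 0, 1000, 1000))
  b <- fake_iso(rect_poly(500, 0, 1500, 1000))      # overlaps a
  c <- fake_iso(rect_poly(4800, 0, 5800, 1000))     # 3300 m from b's edge
  dy <- find_dyads(list(A = a, B = b, C = c), threshold = 3200)
  expect_equal(nrow(dy), 1)
  expect_equal(dy$distance_m, 0)
  expect_setequal(c(dy$a, dy$b), c("A", "B"))

  # at 3100 m the b-c pair qualifies too
  dy2 <- find_dyads(list(A = a, B = b, C = c), threshold = 3400)
  expect_equal(nrow(dy2), 2)

  near <- list(A = a, B = b,
               C = fake_iso(rect_poly(2000, 0, 3000, 1000)))
  dy3 <- find_dyads(near, threshold = 3200)
  expect_equal(nrow(dy3), 3)  # all pairs mutually near

  # species labels ride along
  dy4 <- find_dyads(list(A = a, B = b), threshold = 3200,
                    species = c(A = "RF", B = "AF"))
  expect_equal(dy4$species_pair, "AF-RF")
})

test_that("overlap index is the geometric mean of directed fractions", {
  sq <- rect_poly(0, 0, 1000, 1000)
  expect_equal(overlap_index(sq, sq)$index, 1.0)
  expect_equal(overlap_index(sq, rect_poly(5000, 0, 6000, 1000))$index, 0.0)

  # directed fractions 0.25 and 0.31 -> 0.28 at 2 dp
  b <- rect_poly(750, 0, 750 + 250 / 0.31, 1000)
  ov <- overlap_index(sq, b)
  expect_equal(ov$frac_a, 0.25, tolerance = 1e-9)
  expect_equal(ov$frac_b, 0.31, tolerance = 1e-9)
  expect_equal(round(ov$index, 2), 0.28)

  # symmetry and the max-directed-fraction bound
  ov2 <- overlap_index(b, sq)
  expect_equal(ov$index, ov2$index, tolerance = 1e-12)
  expect_lte(ov$index, max(ov$frac_a, ov$frac_b))

  expect_error(overlap_index(sq, rect_poly(0, 0, 0, 0)), "zero-area")

  # grid-based isopleth route agrees with the exact rectangle arithmetic
  ovg <- overlap_index(fake_iso(sq), fake_iso(b), grid_n = 512)
  expect_equal(ovg$index, ov$index, tolerance = 0.02)
})

test_that("simultaneous-fix matching is greedy, one-to-one and buffered", {
  t0 <- as.POSIXct("2019-03-15", tz = "UTC")
  mk <- function(mins, id) trajectory(id, t0 + mins * 60,
                                      x = seq_along(mins), y = 0 * mins)
  # identical schedules: everything pairs
  a <- mk(c(0, 120, 240), "a"); b <- mk(c(0, 120, 240), "b")
  expect_equal(nrow(simultaneous_pairs(a, b)), 3)

  # constant 6-min offset with a 5-min buffer: nothing pairs
  b6 <- mk(c(6, 126, 246), "b")
  expect_equal(nrow(simultaneous_pairs(a, b6)), 0)

  # worked matching example: two pairs, nearest-unmatched wins
  bx <- mk(c(2, 119, 360), "b")
  pr <- simultaneous_pairs(a, bx)
  expect_equal(nrow(pr), 2)
  expect_equal(pr$i, c(1, 2))
  expect_equal(pr$j, c(1, 2))

  # pairs are disjoint and bounded by the smaller schedule
  set.seed(31)
  am <- sort(sample(0:500, 60)); bm <- sort(sample(0:500, 45))
  pa <- simultaneous_pairs(mk(am, "a"), mk(bm, "b"), buffer = 180)
  expect_lte(nrow(pa), 45)
  expect_false(any(duplicated(pa$i)))
  expect_false(any(duplicated(pa$j)))
  expect_true(all(abs(pa$dt) <= 180))
})

test_that("spatial coefficient matches hand arithmetic and the binomial test", {
  # use proportional to area: no response
  r <- minta_spatial_counts(k = 25, m = 75, q = 0.25)
  expect_equal(r$L, 0, tolerance = 1e-12)
  expect_equal(r$response, "random")

  # q = 0.25 but half the fixes inside: L = ln 3, strongly significant
  r2 <- minta_spatial_counts(k = 50, m = 50, q = 0.25)
  expect_equal(r2$L, log(3), tolerance = 1e-12)
  expect_lt(r2$p, 0.05)
  expect_equal(r2$response, "attraction")
  expect_equal(r2$p, binom.test(50, 100, 0.25)$p.value)

  # balanced use of a half-share zone: L = 0, p = 1
  r3 <- minta_spatial_counts(k = 30, m = 30, q = 0.5)
  expect_equal(r3$L, 0)
  expect_equal(r3$p, 1)

  # zero cells carry infinite sentinels
  expect_equal(minta_spatial_counts(k = 0, m = 40, q = 0.3)$L, -Inf)
  expect_equal(minta_spatial_counts(k = 40, m = 0, q = 0.3)$L, Inf)
  expect_error(minta_spatial_counts(0, 0, 0.3), "undefined")
})

test_that("temporal coefficient reproduces odds arithmetic and labels", {
  # observed = expected in every cell: all odds 1, L_ixn = 0
  in_a <- rep(c(TRUE, TRUE, FALSE, FALSE), 25)
  in_b <- rep(c(TRUE, FALSE, TRUE, FALSE), 25)
  r <- minta_temporal(in_a, in_b)
  expect_equal(unname(r$odds), rep(1, 4))
  expect_equal(r$L_ixn, 0)
  expect_equal(r$label, "Random")
  expect_equal(sum(r$observed), r$n)
  expect_equal(sum(r$expected), r$n)

  # counts (40, 10, 10, 40) with pA = pB = 0.5: odds (1.6, .4, .4, 1.6),
  # L_ixn = ln 4
  in_a <- rep(c(TRUE, TRUE, FALSE, FALSE), c(40, 10, 10, 40))
  in_b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40))
  r2 <- minta_temporal(in_a, in_b)
  expect_equal(unname(r2$odds), c(1.6, 0.4, 0.4, 1.6), tolerance = 1e-12)
  expect_equal(r2$L_ixn, log(4), tolerance = 1e-12)
  expect_lt(r2$p, 0.05)
  expect_equal(r2$label, "Simultaneous")

  # degenerate margin: a zero expected cell is an error, not a silent drop
  expect_error(minta_temporal(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               "degenerate margin")

  # rotation p agrees in direction and is a valid probability
  r3 <- minta_temporal(in_a, in_b, p_method = "rotation")
  expect_equal(r3$L_ixn, r2$L_ixn)
  expect_gte(r3$p, 0)
  expect_lte(r3$p, 1)
})

test_that("dyad classification follows sign and significance", {
  sp <- function(resp) list(L = switch(resp, attraction = 1, avoidance = -1,
                                       random = 0.1),
                            p = if (resp == "random") 0.5 else 0.01,
                            response = resp)
  tm <- function(label) list(label = label)

  expect_equal(classify_dyad(sp("attraction"), sp("attraction"),
                             tm("Simultaneous"))$spatial,
               "Symmetric attraction")
  expect_equal(classify_dyad(sp("random"), sp("avoidance"), tm("Random"))$spatial,
               "Singular avoidance")
  expect_equal(classify_dyad(sp("attraction"), sp("avoidance"), tm("Random"))$spatial,
               "Asymmetric")
  expect_equal(classify_dyad(sp("random"), sp("random"), tm("Random"))$spatial,
               "Random")
  expect_equal(classify_dyad(sp("random"), sp("random"),
                             tm("Solitary trend"))$temporal, "Solitary trend")
})

test_that("a full dyad analysis runs end to end on simulated neighbours", {
  cfg <- sim_config(seed = 51, n_days = 45)
  dy <- simulate_dyad(cfg, "cohesive")
  fa <- tlocoh(dy$a); fb <- tlocoh(dy$b)
  ia <- isopleths(fa, levels = 0.95)$isopleths[[1]]
  ib <- isopleths(fb, levels = 0.95)$isopleths[[1]]
  m <- minta(dy$a, dy$b, ia, ib)
  expect_s3_class(m, "minta")
  expect_gt(m$temporal$L_ixn, 0)
  expect_equal(sum(m$temporal$observed), m$n_pairs)
  expect_gt(m$shared$area, 0)
  tab <- minta_table(list("A-B" = m))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$L_ixn, m$temporal$L_ixn)
})
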