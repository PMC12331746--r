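test_that("Gensini severity points and multipliers match the worked examples", {
  expect_equal(gensini_score(list())$total, 0)
  expect_false(gensini_score(list())$severe)

  lm_total <- gensini_score(list(coronary_lesion("LM", 100)))
  expect_equal(lm_total$total, 32 * 5)

  expect_equal(gensini_score(list(coronary_lesion("LAD_prox", 50)))$total,
               2 * 2.5)
  g10 <- gensini_score(list(coronary_lesion("LAD_prox", 75)))
  expect_equal(g10$total, 10)
  expect_false(g10$severe)
  g14 <- gensini_score(list(coronary_lesion("LAD_prox", 75),
                            coronary_lesion("RCA_mid", 75)))
  expect_equal(g14$total, 14)
  expect_false(g14$severe)
  g18 <- gensini_score(list(coronary_lesion("LAD_prox", 75),
                            coronary_lesion("RCA_mid", 90)))
  expect_equal(g18$total, 18)
  expect_true(g18$severe)
})

test_that("stenosis bins are right-closed and scored from the point table", {
  pts <- vapply(c(10, 25, 26, 50, 60, 75, 80, 90, 95, 99, 100),
                function(s) gensini_score(list(coronary_lesion("PDA", s)))$total,
                numeric(1))
  expect_equal(pts, c(1, 1, 2, 2, 4, 4, 8, 8, 16, 16, 32))
})

test_that("collateral adjustment demotes total occlusions to the 90% bin", {
  with_col <- gensini_score(list(coronary_lesion("LAD_prox", 100,
                                                 collaterals = TRUE)))
  expect_equal(with_col$total, 8 * 2.5)
  cfg_off <- gensini_config(collateral_adjustment = FALSE)
  no_adj <- gensini_score(list(coronary_lesion("LAD_prox", 100,
                                               collaterals = TRUE)), cfg_off)
  expect_equal(no_adj$total, 32 * 2.5)
})

test_that("Gensini score is additive, non-negative and monotone in stenosis", {
  set.seed(42)
  for (rep in 1:20) {
    segs <- sample(coronary_segments, 3, replace = TRUE)
    sten <- runif(3, 0, 100)
    les <- Map(coronary_lesion, segs, sten)
    total <- gensini_score(les)$total
    parts <- vapply(les, function(l) gensini_score(list(l))$total, numeric(1))
    expect_equal(total, sum(parts))
    expect_true(all(parts >= 0))
    bumped <- gensini_score(Map(coronary_lesion, segs,
                                pmin(100, sten + 10)))$total
    expect_gte(bumped, total)
  }
  expect_error(gensini_score(list(list(segment = "LAD9", stenosis = 50))),
               "unknown")
})

test_that("significant-CAD rule uses 50% for left main and 70% elsewhere", {
  expect_true(classify_significant(list(coronary_lesion("LM", 50))))
  expect_false(classify_significant(list(coronary_lesion("LM", 49))))
  expect_true(classify_significant(list(coronary_lesion("RCA_prox", 70))))
  expect_false(classify_significant(list(coronary_lesion("RCA_prox", 69))))
  expect_false(classify_significant(list()))
})

test_that("adding a lesion never revokes significance (monotone rule)", {
  set.seed(7)
  for (rep in 1:20) {
    les <- Map(coronary_lesion,
               sample(coronary_segments, 2, replace = TRUE), runif(2, 0, 100))
    base <- classify_significant(les)
    more <- c(les, list(coronary_lesion(sample(coronary_segments, 1),
                                        runif(1, 0, 100))))
    if (base) expect_true(classify_significant(more))
  }
})

test_that("severity rule thresholds at 15 points", {
  expect_false(classify_severe(14.99))
  expect_true(classify_severe(15))
  expect_true(classify_severe(100))
})

test_that("biplane Simpson volume matches closed forms and a Riemann oracle", {
  # cylinder: all disks equal
  expect_equal(simpson_biplane_volume(rep(40, 20), rep(40, 20), 80),
               (pi / 4) * 40^2 * 80 / 1000)
  # zero-diameter disks contribute nothing
  d <- rep(40, 10); d[3] <- 0
  v <- simpson_biplane_volume(d, rep(40, 10), 100)
  expect_equal(v, (pi / 4) * (100 / 10) * sum(d * 40) / 1000)
  # hemiellipsoid sampled at 20 disks vs analytic half-ellipsoid volume
  a <- 25; b <- 15; L <- 60
  z <- (seq_len(20) - 0.5) / 20
  d4 <- 2 * a * sqrt(1 - z^2)
  d2 <- 2 * b * sqrt(1 - z^2)
  v_hat <- simpson_biplane_volume(d4, d2, L)
  v_true <- (2 / 3) * pi * a * b * L / 1000
  expect_lt(abs(v_hat - v_true) / v_true, 0.02)
  # brute-force Riemann oracle at arbitrary n
  set.seed(1)
  for (n in c(1, 5, 17)) {
    d4 <- runif(n, 0, 50); d2 <- runif(n, 0, 50); L <- runif(1, 40, 90)
    oracle <- sum((pi / 4) * d4 * d2 * (L / n)) / 1000
    expect_equal(simpson_biplane_volume(d4, d2, L), oracle)
  }
  expect_error(simpson_biplane_volume(1:3, 1:4, 10), "disk counts")
})

test_that("EF and strain curves are anchored at end-diastole", {
  expect_equal(ef_curve(rep(120, 20)), rep(0, 20))
  expect_equal(max(ef_curve(c(100, 80, 40, 60))), 60)
  v <- c(100, seq(95, 40, length.out = 10), seq(45, 90, length.out = 9))
  expect_equal(ef_curve(v)[1], 0)
  expect_error(ef_curve(c(0, 10)), "positive")

  expect_equal(strain_curve(rep(7, 20)), rep(0, 20))
  expect_equal(min(strain_curve(c(10, 9, 8, 8.5))), -20)
  expect_equal(strain_curve(c(10, 8) * 3), strain_curve(c(10, 8)))
  expect_error(strain_curve(c(-1, 2)), "positive")
})

test_that("work efficiency from the pressure-strain loop behaves at the limits", {
  p <- lv_pressure_curve(20)
  shortening <- c(0, seq(-2, -20, length.out = 10), seq(-18, -1, length.out = 9))
  expect_equal(as.numeric(gwe_from_loop(shortening, p)), 100)
  expect_equal(as.numeric(gwe_from_loop(-shortening, p)), 0)
  # equal shortening and lengthening magnitude at constant pressure -> 50%
  s <- c(0, -5, 0, rep(0, 17))
  expect_equal(as.numeric(gwe_from_loop(s, rep(80, 20), es_index = 3L)), 50)
  # invariant to uniform pressure scaling
  s2 <- c(0, -4, -2, -8, rep(-8, 16))
  expect_equal(as.numeric(gwe_from_loop(s2, p)),
               as.numeric(gwe_from_loop(s2, 3.7 * p)))
  expect_error(gwe_from_loop(rep(0, 20), p), "undefined")
})
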