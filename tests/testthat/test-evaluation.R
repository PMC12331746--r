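test_that("dice matches direct overlap counting and is symmetric", {
  m <- array(0, c(4, 10, 10))
  a <- m; a[1, 1:5, ] <- 1
  expect_equal(dice(a, a), 1)
  b <- m; b[1, 6:10, ] <- 1
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 100, overlap 50
  g <- array(0, c(1, 20, 20))
  cells <- cbind(1, rep(1:20, 10), rep(1:10, each = 20)) # 200 cell coords
  a2 <- g; a2[cells[1:100, ]] <- 1
  b2 <- g; b2[cells[51:150, ]] <- 1
  expect_equal(dice(a2, b2), 2 * 50 / (100 + 100))
  expect_equal(dice(a2, b2), dice(b2, a2))
  expect_equal(dice(m, m), 1) # empty-vs-empty convention
  expect_error(dice(a, array(0, c(2, 2, 2))), "grids differ")
})

test_that("mae matches hand arithmetic", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3) + 4.5, c(1, 2, 3)), 4.5)
  expect_equal(mae(c(1, 3), c(2, 1)), 1.5)
  expect_error(mae(1:3, 1:4), "mismatch")
})

test_that("pearson handles the canonical cases", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson(rep(1, 5), 1:5), "variance")
})

test_that("AUC equals brute-force pair counting, exhaustively for small n", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  brute <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
  }
  set.seed(9)
  for (n in 4:8) {
    for (rep in 1:10) {
      l <- c(0, 1, sample(0:1, n - 2, TRUE))
      s <- sample(1:4, n, TRUE) # heavy ties
      expect_equal(roc_auc(s, l), brute(s, l))
    }
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC score-negation symmetry holds under ties", {
  set.seed(10)
  for (rep in 1:20) {
    l <- c(0, 1, sample(0:1, 8, TRUE))
    s <- sample(seq(0, 2, by = 0.5), 10, TRUE)
    expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  s <- rnorm(60)
  l <- rbinom(60, 1, plogis(s))
  if (length(unique(l)) == 2) {
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, l), ref, tolerance = 1e-12)
  }
})

test_that("classification report matches confusion-cell arithmetic", {
  perfect <- classification_report(c(1, 0, 1), c(1, 0, 1))
  expect_true(all(perfect$value == 1))
  allpos <- classification_report(rep(1, 10), rep(c(0, 1), 5))
  vals <- setNames(allpos$value, allpos$metric)
  expect_equal(vals[["sensitivity"]], 1)
  expect_equal(vals[["specificity"]], 0)
  expect_equal(vals[["accuracy"]], 0.5)
  # TP=3 FP=1 FN=1 TN=5
  pred <- c(rep(1, 4), rep(0, 6))
  truth <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  r <- setNames(classification_report(pred, truth)$value,
                c("accuracy", "precision", "sensitivity", "specificity", "f1"))
  expect_equal(r[["precision"]], 0.75)
  expect_equal(r[["sensitivity"]], 0.75)
  expect_equal(r[["specificity"]], 5 / 6)
  expect_equal(r[["f1"]], 0.75)
  # undefined ratios are NA, not zero
  nopos <- classification_report(rep(0, 4), rep(0, 4))
  expect_true(is.na(nopos$value[nopos$metric == "precision"]))
  expect_true(is.na(nopos$value[nopos$metric == "sensitivity"]))
})

test_that("bootstrap CI is seeded, covers the estimate, and handles degeneracy", {
  expect_equal(as.numeric(bootstrap_ci(function(d) 1, 1:30, 200, seed = 5)),
               c(1, 1))
  set.seed(12)
  x <- rnorm(80)
  ci <- bootstrap_ci(mean, x, n_boot = 1000, seed = 3)
  expect_lte(ci[1], mean(x))
  expect_gte(ci[2], mean(x))
  ci2 <- bootstrap_ci(mean, x, n_boot = 1000, seed = 3)
  expect_identical(as.numeric(ci), as.numeric(ci2))
  # degenerate resamples (single-class AUC draws) are skipped and counted
  d <- data.frame(s = rnorm(6), l = c(1, rep(0, 5)))
  ci3 <- bootstrap_ci(function(dd) roc_auc(dd$s, dd$l), d, 200, seed = 8)
  expect_gte(attr(ci3, "skipped"), 1)
  expect_error(bootstrap_ci(mean, 1:5, 50), "at least 100")
})
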