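test_that("phantom generation is deterministic and respects the disease dial", {
  p0 <- make_phantom(0, 0)
  expect_equal(unname(p0$contractility), c(1, 1, 1))
  p1 <- make_phantom(0, 1)
  expect_equal(min(p1$contractility), 0.3)
  expect_identical(make_phantom(5, 0.4), make_phantom(5, 0.4))
  expect_error(make_phantom(1, 1.2), "disease_level")
  expect_error(make_phantom(-1, 0), "seed")
})

test_that("rendered subjects satisfy the block and mask contracts", {
  rec <- render_subject(make_phantom(2, 0.3),
                        list(coronary_lesion("LAD_prox", 80)),
                        noise_seed = 3, size = 64)
  for (v in c("A4C", "A3C", "A2C")) {
    expect_equal(dim(rec$views[[v]]), c(20, 64, 64))
    expect_true(all(rec$views[[v]] >= 0 & rec$views[[v]] <= 1))
    expect_true(all(unique(as.integer(rec$masks[[v]])) %in% 0:2))
  }
  # cavity strictly inside the annulus: dilating the cavity by one pixel
  # never reaches background
  m <- rec$masks$A4C[11, , ]
  cav <- which(m == 2L, arr.ind = TRUE)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    shifted <- cbind(pmin(pmax(cav[, 1] + d[1], 1), 64),
                     pmin(pmax(cav[, 2] + d[2], 1), 64))
    expect_true(all(m[shifted] %in% c(1L, 2L)))
  }
  expect_equal(rec$strain[1], 0)
  expect_equal(rec$ef[1], 0)
  expect_equal(rec$gls, min(rec$strain))
  expect_equal(rec$lvef, max(rec$ef))
  expect_true(rec$gwe >= 0 && rec$gwe <= 100)
  expect_true(rec$significant)
})

test_that("a motionless phantom produces flat curves", {
  p <- make_phantom(1, 0)
  p$alpha <- 0
  rec <- render_subject(p, list(), 1, render = FALSE)
  expect_equal(rec$strain, rep(0, 20))
  expect_equal(rec$ef, rep(0, 20))
})

test_that("uniform-contractility phantoms peak strain at end-systole", {
  for (seed in c(3, 8, 21)) {
    rec <- render_subject(make_phantom(seed, 0), list(), 1, render = FALSE)
    expect_equal(which.min(rec$strain), 11) # frame index 10, 1-based 11
    expect_lte(rec$gls, 0)
    expect_true(rec$lvef > 0 && rec$lvef < 100)
  }
})

test_that("circular uniform phantom reproduces the closed-form ejection fraction", {
  p <- make_phantom(0, 0)
  p$a0 <- 60; p$b0 <- 60; p$alpha <- 0.2
  rec <- render_subject(p, list(), 1, render = FALSE)
  # isotropic scaling by (1 - alpha): volume scales cubically
  expect_equal(rec$lvef, 100 * (1 - (1 - 0.2)^3), tolerance = 0.01)
})

test_that("increasing disease level never improves function (monotone effect)", {
  levels <- seq(0, 1, by = 0.25)
  metrics <- sapply(levels, function(D) {
    r <- render_subject(make_phantom(3, D), list(), 1, render = FALSE)
    c(abs_gls = abs(r$gls), lvef = r$lvef, gwe = r$gwe)
  })
  for (row in rownames(metrics)) {
    expect_true(all(diff(metrics[row, ]) <= 1e-9), info = row)
  }
})

test_that("identical seeds give bit-identical records", {
  r1 <- render_subject(make_phantom(4, 0.5), list(), 9, size = 32)
  r2 <- render_subject(make_phantom(4, 0.5), list(), 9, size = 32)
  expect_identical(r1, r2)
  c1 <- make_cohort(3, 0.5, rng_seed = 6, size = 32)
  c2 <- make_cohort(3, 0.5, rng_seed = 6, size = 32)
  expect_identical(c1, c2)
})

test_that("cohorts carry three views per subject and the disease gradient", {
  cohort <- make_cohort(50, prevalence = 0.42, rng_seed = 13, render = FALSE)
  expect_equal(sum(vapply(cohort, function(r) length(r$view_labels),
                          integer(1))), 150)
  sig <- vapply(cohort, `[[`, logical(1), "significant")
  expect_equal(sum(sig), round(0.42 * 50))
  gens <- vapply(cohort, `[[`, numeric(1), "gensini")
  expect_gt(mean(gens[sig]), mean(gens[!sig]))
  # functional metrics degrade with disease, as in the clinical comparison
  gls <- vapply(cohort, `[[`, numeric(1), "gls")
  lvef <- vapply(cohort, `[[`, numeric(1), "lvef")
  gwe <- vapply(cohort, `[[`, numeric(1), "gwe")
  expect_lt(mean(abs(gls[sig])), mean(abs(gls[!sig])))
  expect_lt(mean(lvef[sig]), mean(lvef[!sig]))
  expect_lt(mean(gwe[sig]), mean(gwe[!sig]))
  # severe flag is the >= 15 point rule
  sev <- vapply(cohort, `[[`, logical(1), "severe")
  expect_equal(sev, gens >= 15)
})

test_that("cohort writer produces a readable manifest", {
  cohort <- make_cohort(2, 0.5, rng_seed = 3, size = 32)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  back <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(back), 2)
  blob <- readRDS(back$a4c[1])
  expect_equal(dim(blob$video), c(20, 32, 32))
})
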