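test_that("per-task losses hit their closed-form anchors", {
  cfg <- tiny_config(input_size = 32L)
  cohort <- make_cohort(2, prevalence = 0.5, rng_seed = 5, size = 32)
  batch <- iecad:::make_batch(cohort_samples(cohort)[1:2], cfg)
  # a perfect curve prediction has zero MSE
  out_fake <- list(gls = ag_tensor(batch$gls), lvef = ag_tensor(batch$lvef),
                   gwe = ag_tensor(batch$gwe))
  l <- task_losses(out_fake, batch)
  expect_equal(ag_value(l$gls), 0)
  expect_equal(ag_value(l$lvef), 0)
  # uniform CAD logits give ln 2
  out_fake2 <- list(gensini = ag_tensor(batch$gensini),
                    cad_logits = ag_tensor(matrix(0, 2, 2)))
  l2 <- task_losses(out_fake2, batch)
  expect_equal(ag_value(l2$cad), log(2))
  expect_equal(ag_value(l2$gensini), 0)
  # a perfect one-hot segmentation has ~zero Dice loss
  seg_logits <- array(0, c(32, 32, 20, 3, 2))
  for (k in 1:3) {
    sel <- batch$seg == k
    arr <- array(FALSE, dim(seg_logits))
    arr[, , , k, ][sel] <- TRUE
    seg_logits[arr] <- 50
  }
  l3 <- task_losses(list(seg_logits = ag_tensor(seg_logits)), batch)
  expect_lt(ag_value(l3$seg_dice), 1e-6)
  expect_lt(ag_value(l3$seg_ce), 1e-6)
})

test_that("gradient accumulation reproduces the large-batch gradient", {
  # linear model: loss is mean squared error, gradients are exact, so the
  # mean of two half-batch gradients (each scaled by 1/2) must equal the
  # full-batch gradient
  set.seed(6)
  X <- matrix(rnorm(40), 8, 5)
  yt <- rnorm(8)
  W <- ag_tensor(matrix(rnorm(5), 5, 1), requires_grad = TRUE)
  full <- iecad:::ag_mse(iecad:::ag_matmul(ag_tensor(X), W), yt)
  ag_backward(full)
  g_full <- W$grad
  ag_zero_grad(list(W))
  for (half in list(1:4, 5:8)) {
    l <- iecad:::ag_mse(iecad:::ag_matmul(ag_tensor(X[half, ]), W),
                        yt[half])
    ag_backward(iecad:::ag_scale(l, 1 / 2))
  }
  expect_equal(W$grad, g_full, tolerance = 1e-12)
})

test_that("the re-warmed cosine schedule warms up then decays to zero", {
  lrs <- vapply(1:100, cosine_warmup_lr, numeric(1), total_updates = 100,
                lr_max = 2e-4, warmup_frac = 0.05)
  expect_equal(which.max(lrs), 5)
  expect_equal(max(lrs), 2e-4)
  expect_true(all(diff(lrs[1:5]) > 0))
  expect_true(all(diff(lrs[6:100]) < 0))
  expect_lt(lrs[100], 1e-7)
})

test_that("subject split partitions, stratifies and reproduces the study sizes", {
  # composition consistent with the printed prevalence 122/290
  labs <- data.frame(
    significant = rep(c(FALSE, TRUE, TRUE), c(168, 33, 89)),
    severe = rep(c(FALSE, FALSE, TRUE), c(168, 33, 89)))
  sp <- split_cohort(labs, ratio = 0.8, seed = 2)
  expect_length(sp$train_idx, 234)
  expect_length(sp$test_idx, 56)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(290))
  # label balance screen
  for (col in c("significant", "severe")) {
    tab <- table(seq_len(290) %in% sp$test_idx, labs[[col]])
    p <- suppressWarnings(chisq.test(tab)$p.value)
    expect_gt(p, 0.1)
  }
  # constant labels: plain random split with the same allocation rule
  labs2 <- data.frame(significant = rep(TRUE, 40), severe = rep(FALSE, 40))
  sp2 <- split_cohort(labs2, 0.8, seed = 3)
  expect_length(sp2$test_idx, 8)
  expect_error(split_cohort(labs2[1:1, ], 0.5, seed = 1), "too small")
})

test_that("split is at the subject level and deterministic in the seed", {
  cohort <- make_cohort(20, prevalence = 0.4, rng_seed = 9, render = FALSE)
  s1 <- split_cohort(cohort, 0.8, seed = 4)
  s2 <- split_cohort(cohort, 0.8, seed = 4)
  expect_identical(s1$test_idx, s2$test_idx)
  ids_tr <- vapply(s1$train, `[[`, character(1), "id")
  ids_te <- vapply(s1$test, `[[`, character(1), "id")
  expect_length(intersect(ids_tr, ids_te), 0)
})

test_that("a short phase run reduces its loss and is seed-reproducible", {
  cfg <- tiny_config(input_size = 32L, seed = 2L)
  cohort <- make_cohort(6, prevalence = 0.5, rng_seed = 8, size = 32)
  samples <- cohort_samples(cohort)
  tc <- train_config(phase_epochs = c(3, 1, 1), lr = 1e-3, batch_size = 6,
                     grad_accumulation = 1, seed = 2)
  m1 <- iecad_model(cfg)
  st1 <- run_phase(m1, samples, tc, 1)
  expect_lt(st1$epoch_losses[3], st1$epoch_losses[1])
  expect_true(all(is.finite(st1$epoch_losses)))
  m2 <- iecad_model(cfg)
  st2 <- run_phase(m2, samples, tc, 1)
  expect_identical(st1$epoch_losses, st2$epoch_losses)
})

test_that("phase 3 freezes the encoder and phase-1/2 heads exactly", {
  cfg <- tiny_config(input_size = 32L, seed = 3L)
  cohort <- make_cohort(6, prevalence = 0.5, rng_seed = 10, size = 32)
  samples <- cohort_samples(cohort)
  tc <- train_config(phase_epochs = c(1, 1, 2), lr = 1e-3, batch_size = 6,
                     grad_accumulation = 1, seed = 3)
  model <- iecad_model(cfg)
  run_phase(model, samples, tc, 1)
  run_phase(model, samples, tc, 2)
  frozen <- grep("^(stem|stage|lowlevel_proj|aspp|conv_block|lr_gls|lr_lvef|lr_gwe|view_head|seg_|gls_|lvef_|gwe_)",
                 names(model$params), value = TRUE)
  trainable <- grep("^(lr_gensini|gensini_|cad_)", names(model$params),
                    value = TRUE)
  expect_setequal(c(frozen, trainable), names(model$params))
  before <- lapply(model$params[frozen], function(p) p$value)
  head_before <- lapply(model$params[trainable], function(p) p$value)
  st3 <- run_phase(model, samples, tc, 3)
  after <- lapply(model$params[frozen], function(p) p$value)
  expect_identical(before, after) # bit-identical, not merely close
  head_after <- lapply(model$params[trainable], function(p) p$value)
  expect_false(identical(head_before, head_after))
  expect_true(all(is.finite(st3$epoch_losses)))
})
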