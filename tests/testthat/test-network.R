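# Shape conformance at reduced width (the full-width conformance check
# lives in the acceptance suite); functional properties of the network.

test_that("scaled model preserves the frame axis and relative tensor shapes", {
  cfg <- tiny_config(input_size = 32L)
  model <- iecad_model(cfg)
  clip <- array(runif(20 * 32 * 32), c(20, 32, 32))
  out <- ag_no_grad(iecad_forward(model, list(clip, clip)))
  expect_equal(dim(ag_value(out$view_logits)), c(2, 3))
  expect_equal(dim(ag_value(out$seg_logits)), c(32, 32, 20, 3, 2))
  expect_equal(dim(ag_value(out$gls)), c(20, 2))
  expect_equal(dim(ag_value(out$lvef)), c(20, 2))
  expect_length(ag_value(out$gwe), 2)
  expect_length(ag_value(out$gensini), 2)
  expect_equal(dim(ag_value(out$cad_probs)), c(2, 2))
  expect_equal(out$fused_channels, 4L * cfg$aspp_out + cfg$lowlevel)
})

test_that("softmax outputs are normalised within 1e-5", {
  model <- iecad_model(tiny_config(input_size = 32L))
  clip <- array(runif(20 * 32 * 32), c(20, 32, 32))
  out <- ag_no_grad(iecad_forward(model, list(clip)))
  expect_equal(rowSums(ag_value(out$view_probs)), 1, tolerance = 1e-5)
  expect_equal(rowSums(ag_value(out$cad_probs)), 1, tolerance = 1e-5)
  sp <- ag_value(out$seg_probs)
  sums <- apply(sp[seq(1, 32, by = 7), seq(1, 32, by = 7), c(1, 20), , 1,
                   drop = FALSE], c(1, 2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("evaluation-mode forward is deterministic", {
  model <- iecad_model(tiny_config(input_size = 32L))
  clip <- array(runif(20 * 32 * 32), c(20, 32, 32))
  o1 <- predict_block(model, clip)
  o2 <- predict_block(model, clip)
  expect_identical(o1, o2)
})

test_that("wrong input shapes are rejected with a named error", {
  model <- iecad_model(tiny_config(input_size = 32L))
  expect_error(iecad_forward(model, array(0, c(10, 32, 32))), "expected")
  expect_error(iecad_forward(model, array(0, c(20, 64, 64))), "expected")
})

test_that("the low-rank factorisation shrinks the 3x3x3 parameter count", {
  blk <- iecad:::nn_lowrank_block(256L, 4L)
  lr_params <- sum(vapply(iecad:::collect_params(blk$children$lr1),
                          function(p) length(ag_value(p)), numeric(1)))
  dense_params <- 27 * 256 * 256
  expect_lt(lr_params, dense_params)
  expect_equal(lr_params, 27 * 256 * 4 + 4 * 256)
  # shape preservation
  x <- array(rnorm(4 * 4 * 2 * 256), c(4, 4, 2, 256, 1))
  y <- ag_no_grad(blk$forward(ag_tensor(x), TRUE))
  expect_equal(dim(ag_value(y)), dim(x))
  # exported convenience wrapper
  y2 <- low_rank_block(x, rank = 4L, seed = 2L)
  expect_equal(dim(y2), dim(x))
})

test_that("every head's loss sends gradient back to the encoder", {
  cfg <- tiny_config(input_size = 32L)
  model <- iecad_model(cfg)
  cohort <- make_cohort(2, prevalence = 0.5, rng_seed = 4, size = 32)
  batch <- iecad:::make_batch(cohort_samples(cohort)[1:2], cfg)
  stem_w <- model$params[["stem.conv.w"]]
  for (task in list("view", "seg", "metrics", "score")) {
    ag_zero_grad(model$params)
    out <- iecad_forward(model, batch$x, tasks = task, training = TRUE)
    losses <- task_losses(out, batch)
    total <- iecad:::weighted_total(losses, c())
    ag_backward(total)
    expect_false(is.null(stem_w$grad), info = task)
    expect_gt(max(abs(stem_w$grad)), 0, label = paste("stem grad for", task))
  }
})

test_that("the pooled sequence path is frame-permutation equivariant", {
  # permuting a feature tensor's frames permutes the pooled 20-step
  # sequence (and hence the per-step curve outputs) identically
  set.seed(31)
  feat <- array(rnorm(8 * 8 * 20 * 6 * 2), c(8, 8, 20, 6, 2))
  perm <- sample(20)
  pooled <- ag_value(iecad:::ag_gap_hw(ag_tensor(feat)))
  pooled_p <- ag_value(iecad:::ag_gap_hw(
    ag_tensor(feat[, , perm, , , drop = FALSE])))
  expect_equal(pooled_p, pooled[perm, , , drop = FALSE])
  head <- iecad:::nn_seq_dense(6L, 1L)
  curve <- ag_value(head$forward(ag_tensor(pooled)))
  curve_p <- ag_value(head$forward(ag_tensor(pooled_p)))
  expect_equal(curve_p, curve[perm, , , drop = FALSE])
})
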