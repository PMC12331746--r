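# Every autograd op is validated against central finite differences; the
# convolution additionally against a brute-force direct-convolution
# oracle.

test_that("conv3d forward matches a brute-force convolution oracle", {
  set.seed(1)
  x <- array(rnorm(4 * 4 * 3 * 2 * 2), c(4, 4, 3, 2, 2))
  w <- array(rnorm(3 * 3 * 3 * 2 * 3) * 0.3, c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  oracle <- array(0, c(4, 4, 3, 3, 2))
  for (n in 1:2) for (co in 1:3) for (t in 1:3) for (wc in 1:4) for (h in 1:4) {
    acc <- b[co]
    for (ci in 1:2) for (kt in 1:3) for (kw in 1:3) for (kh in 1:3) {
      hh <- h + kh - 2; ww <- wc + kw - 2; tt <- t + kt - 2
      if (hh >= 1 && hh <= 4 && ww >= 1 && ww <= 4 && tt >= 1 && tt <= 3) {
        acc <- acc + x[hh, ww, tt, ci, n] * w[kh, kw, kt, ci, co]
      }
    }
    oracle[h, wc, t, co, n] <- acc
  }
  got <- ag_value(iecad:::ag_conv3d(ag_tensor(x), ag_tensor(w), ag_tensor(b)))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("conv3d gradients match finite differences (plain, strided, dilated)", {
  set.seed(2)
  x <- array(rnorm(4 * 4 * 3 * 2 * 1), c(4, 4, 3, 2, 1))
  w <- array(rnorm(3 * 3 * 3 * 2 * 2) * 0.3, c(3, 3, 3, 2, 2))
  b <- rnorm(2)
  r_same <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2, 1))
  r_strided <- array(rnorm(2 * 2 * 3 * 2), c(2, 2, 3, 2, 1))
  expect_lt(grad_relerr(function(xx) weighted_sum(
    iecad:::ag_conv3d(xx, ag_tensor(w), ag_tensor(b)), r_same), x), 1e-6)
  expect_lt(grad_relerr(function(ww) weighted_sum(
    iecad:::ag_conv3d(ag_tensor(x), ww, ag_tensor(b)), r_same), w), 1e-6)
  expect_lt(grad_relerr(function(xx) weighted_sum(
    iecad:::ag_conv3d(xx, ag_tensor(w), ag_tensor(b), stride = c(2, 2)),
    r_strided), x), 1e-6)
  expect_lt(grad_relerr(function(xx) weighted_sum(
    iecad:::ag_conv3d(xx, ag_tensor(w), ag_tensor(b),
                      dilation = c(1, 2, 2)), r_same), x), 1e-6)
})

test_that("normalisation, pooling and sequence ops backpropagate exactly", {
  set.seed(3)
  x5 <- array(rnorm(4 * 4 * 3 * 2 * 2), c(4, 4, 3, 2, 2))
  bn <- iecad:::nn_batchnorm(2)
  bn$params$gamma$value <- rnorm(2) + 1
  r5 <- array(rnorm(prod(dim(x5))), dim(x5))
  expect_lt(grad_relerr(function(xx) weighted_sum(
    iecad:::ag_batchnorm(xx, bn$params$gamma, bn$params$beta, bn, TRUE),
    r5), x5), 1e-4)
  expect_lt(grad_relerr(function(g) weighted_sum(
    iecad:::ag_batchnorm(ag_tensor(x5), g, bn$params$beta, bn, TRUE), r5),
    bn$params$gamma$value), 1e-5)
  r_pool <- array(rnorm(2 * 2 * 3 * 2 * 2), c(2, 2, 3, 2, 2))
  expect_lt(grad_relerr(function(xx) weighted_sum(
    iecad:::ag_avgpool_hw(xx, 2), r_pool), x5), 1e-6)
  r_up <- array(rnorm(8 * 8 * 3 * 2 * 2), c(8, 8, 3, 2, 2))
  expect_lt(grad_relerr(function(xx) weighted_sum(
    iecad:::ag_upsample_hw(xx, 2), r_up), x5), 1e-6)
  r_gap <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  expect_lt(grad_relerr(function(xx) weighted_sum(
    iecad:::ag_gap_hw(xx), r_gap), x5), 1e-6)
  xs <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  Wd <- matrix(rnorm(8), 4, 2); bd <- rnorm(2)
  rs <- array(rnorm(5 * 2 * 3), c(5, 2, 3))
  expect_lt(grad_relerr(function(xx) weighted_sum(
    iecad:::ag_seq_dense(xx, ag_tensor(Wd), ag_tensor(bd)), rs), xs), 1e-6)
  r_soft <- array(rnorm(prod(dim(xs))), dim(xs))
  expect_lt(grad_relerr(function(xx) weighted_sum(
    iecad:::ag_softmax(xx, 2L), r_soft), xs), 1e-6)
})

test_that("attention and recurrent layers backpropagate exactly", {
  set.seed(4)
  xs <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  rA <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  expect_lt(grad_relerr(function(q) weighted_sum(
    iecad:::ag_mha_core(q, ag_tensor(xs), ag_tensor(0.5 * xs), 2L), rA),
    xs), 1e-4)
  att <- iecad:::nn_temporal_attention(4L, 2L)
  expect_lt(grad_relerr(function(xx) weighted_sum(att$forward(xx), rA), xs),
            1e-4)
  lst <- iecad:::nn_bilstm(4L, 3L)
  rl <- array(rnorm(5 * 6 * 3), c(5, 6, 3))
  expect_lt(grad_relerr(function(xx) weighted_sum(lst$forward(xx), rl), xs),
            1e-4)
  # weight gradient of the recurrent layer
  pp <- iecad:::collect_params(lst)
  pW <- pp[["fwd.Wx"]]
  ag_zero_grad(pp)
  ag_backward(weighted_sum(lst$forward(ag_tensor(xs)), rl))
  ga <- pW$grad
  gn <- numeric_grad(function(v) {
    dim(v) <- dim(pW$value)
    old <- pW$value; pW$value <- v
    r <- ag_value(ag_no_grad(weighted_sum(lst$forward(ag_tensor(xs)), rl)))
    pW$value <- old
    r
  }, pW$value)
  expect_lt(max(abs(ga - gn)) / max(abs(gn)), 1e-4)
})

test_that("loss functions reach their closed-form values and gradients", {
  lg <- matrix(rnorm(18), 6, 3)
  tg <- c(1, 2, 3, 1, 2, 3)
  expect_lt(grad_relerr(function(xx) iecad:::ag_ce_logits(xx, tg), lg), 1e-6)
  expect_lt(grad_relerr(function(xx) iecad:::ag_mse(xx, 0.3 * lg), lg), 1e-6)
  onehot <- diag(3)[tg, ]
  expect_lt(grad_relerr(function(xx) iecad:::ag_dice_loss(
    iecad:::ag_softmax(xx, 2L), onehot), lg), 1e-6)
  # uniform two-class prediction has cross-entropy ln 2
  expect_equal(ag_value(iecad:::ag_ce_logits(matrix(0, 4, 2), c(1, 2, 1, 2))),
               log(2))
  # a perfect one-hot prediction has (near) zero Dice loss
  sharp <- diag(3)[tg, ]
  expect_lt(ag_value(iecad:::ag_dice_loss(sharp, onehot)), 1e-6)
  expect_equal(ag_value(iecad:::ag_mse(ag_tensor(lg), lg)), 0)
})

test_that("gradients accumulate across backward passes and reset on demand", {
  w <- ag_tensor(c(1, 2), requires_grad = TRUE)
  loss1 <- iecad:::ag_sum(iecad:::ag_mul(w, c(3, 4)))
  ag_backward(loss1)
  g1 <- w$grad
  ag_backward(iecad:::ag_sum(iecad:::ag_mul(w, c(3, 4))))
  expect_equal(w$grad, 2 * g1)
  ag_zero_grad(list(w))
  expect_null(w$grad)
})
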