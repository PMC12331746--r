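# Shared fixtures: a tiny network configuration and a finite-difference
# gradient checker used across the op tests.

tiny_config <- function(input_size = 32L, seed = 1L) {
  iecad_config(input_size = input_size, width_scale = 1 / 8,
               blocks = c(1L, 1L, 1L, 1L), lowlevel_channels = 12L,
               aspp_rates = c(1L, 2L), seed = seed)
}

numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# relative error between analytic and numeric gradient of a scalar field
grad_relerr <- function(f_ag, x0) {
  xt <- ag_tensor(x0, requires_grad = TRUE)
  ag_backward(f_ag(xt))
  ga <- xt$grad
  gn <- numeric_grad(function(v) {
    d <- dim(x0)
    if (!is.null(d)) dim(v) <- d
    ag_value(f_ag(ag_tensor(v)))
  }, x0)
  max(abs(ga - gn)) / max(1e-8, max(abs(gn)))
}

weighted_sum <- function(y, r) iecad:::ag_sum(iecad:::ag_mul(y, ag_tensor(r)))
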