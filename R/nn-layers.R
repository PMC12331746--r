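# Layer constructors. A layer is an environment of class "nn_layer" with
# $params (named list of leaf tensors), $children (sub-layers) and
# $forward(x, training). Parameter initialisation draws from the session
# RNG, so models are reproducible given a seed.

new_layer <- function(forward = NULL, params = list(), children = list()) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$children <- children
  e$forward <- forward
  class(e) <- "nn_layer"
  e
}

nn_param <- function(dim, sd) {
  ag_tensor(array(stats::rnorm(prod(dim), sd = sd), dim = dim),
            requires_grad = TRUE)
}

#' @keywords internal
collect_params <- function(layer, prefix = "") {
  out <- list()
  if (inherits(layer, "nn_layer")) {
    for (nm in names(layer$params)) {
      out[[paste0(prefix, nm)]] <- layer$params[[nm]]
    }
    for (nm in names(layer$children)) {
      out <- c(out, collect_params(layer$children[[nm]],
                                   paste0(prefix, nm, ".")))
    }
  } else if (is.list(layer)) {
    for (nm in names(layer)) {
      out <- c(out, collect_params(layer[[nm]], paste0(prefix, nm, ".")))
    }
  }
  out
}

# kernel is (kt, kh, kw); weights stored (kh, kw, kt, cin, cout)
nn_conv3d <- function(cin, cout, kernel = c(3L, 3L, 3L), stride = c(1L, 1L),
                      dilation = c(1L, 1L, 1L), bias = TRUE) {
  force(stride); force(dilation) # evaluate now, not at first forward
  fan_in <- cin * prod(kernel)
  w <- nn_param(c(kernel[2], kernel[3], kernel[1], cin, cout),
                sd = sqrt(2 / fan_in))
  params <- list(w = w)
  if (bias) params$b <- ag_tensor(numeric(cout), requires_grad = TRUE)
  l <- new_layer(params = params)
  l$forward <- function(x, training = TRUE) {
    ag_conv3d(x, l$params$w, l$params$b, stride = stride,
              dilation = dilation)
  }
  l
}

nn_batchnorm <- function(c, momentum = 0.1, eps = 1e-5) {
  l <- new_layer(params = list(
    gamma = ag_tensor(rep(1, c), requires_grad = TRUE),
    beta = ag_tensor(numeric(c), requires_grad = TRUE)
  ))
  l$running_mean <- numeric(c)
  l$running_var <- rep(1, c)
  l$momentum <- momentum
  l$eps <- eps
  l$forward <- function(x, training = TRUE) {
    ag_batchnorm(x, l$params$gamma, l$params$beta, l, training)
  }
  l
}

# conv -> BN -> activation (the standard block unit)
nn_conv_bn <- function(cin, cout, kernel = c(3L, 3L, 3L), stride = c(1L, 1L),
                       dilation = c(1L, 1L, 1L), act = "relu") {
  force(act)
  conv <- nn_conv3d(cin, cout, kernel, stride, dilation, bias = FALSE)
  bn <- nn_batchnorm(cout)
  l <- new_layer(children = list(conv = conv, bn = bn))
  l$forward <- function(x, training = TRUE) {
    y <- bn$forward(conv$forward(x, training), training)
    if (identical(act, "relu")) y <- ag_relu(y)
    y
  }
  l
}

# Low-rank convolution: the kernel is factorised through an r-channel
# bottleneck (full kernel to r channels, then pointwise r -> cout).
nn_lowrank_conv3d <- function(cin, cout, kernel, r) {
  down <- nn_conv3d(cin, r, kernel, bias = FALSE)
  up <- nn_conv3d(r, cout, c(1L, 1L, 1L), bias = FALSE)
  l <- new_layer(children = list(down = down, up = up))
  l$forward <- function(x, training = TRUE) {
    up$forward(down$forward(x, training), training)
  }
  l
}

# Low-rank expert block: low-rank 3x3x3 stage then low-rank 1x1x1 stage,
# each with batch norm + rectification.
nn_lowrank_block <- function(c, r) {
  lr1 <- nn_lowrank_conv3d(c, c, c(3L, 3L, 3L), r)
  bn1 <- nn_batchnorm(c)
  lr2 <- nn_lowrank_conv3d(c, c, c(1L, 1L, 1L), r)
  bn2 <- nn_batchnorm(c)
  l <- new_layer(children = list(lr1 = lr1, bn1 = bn1, lr2 = lr2, bn2 = bn2))
  l$forward <- function(x, training = TRUE) {
    y <- ag_relu(bn1$forward(lr1$forward(x, training), training))
    ag_relu(bn2$forward(lr2$forward(y, training), training))
  }
  l
}

# Residual bottleneck (1x1x1 reduce, 3x3x3, 1x1x1 expand), spatial stride
# on the 3x3x3 stage, optional dilation for the final (stride-free) stage.
nn_bottleneck <- function(cin, cout, mid, stride = 1L, dilation = 1L) {
  c1 <- nn_conv_bn(cin, mid, c(1L, 1L, 1L))
  c2 <- nn_conv_bn(mid, mid, c(3L, 3L, 3L), stride = c(stride, stride),
                   dilation = c(1L, dilation, dilation))
  c3conv <- nn_conv3d(mid, cout, c(1L, 1L, 1L), bias = FALSE)
  c3bn <- nn_batchnorm(cout)
  children <- list(c1 = c1, c2 = c2, c3conv = c3conv, c3bn = c3bn)
  proj <- NULL
  if (cin != cout || stride != 1L) {
    proj <- nn_conv_bn(cin, cout, c(1L, 1L, 1L), stride = c(stride, stride),
                       act = "none")
    children$proj <- proj
  }
  l <- new_layer(children = children)
  l$forward <- function(x, training = TRUE) {
    y <- c1$forward(x, training)
    y <- c2$forward(y, training)
    y <- c3bn$forward(c3conv$forward(y, training), training)
    skip <- if (is.null(proj)) x else proj$forward(x, training)
    ag_relu(ag_add(y, skip))
  }
  l
}

# Dense output layers may carry a fixed affine output map
# (y = scale * dense(x) + base): regression heads predict in
# standardised units and are mapped to the target's physiologic range,
# so rate-limited optimisers need only O(1) parameter motion.
nn_dense <- function(cin, cout, out_scale = 1, out_base = 0) {
  force(out_scale); force(out_base)
  l <- new_layer(params = list(
    W = nn_param(c(cin, cout), sd = sqrt(1 / cin)),
    b = ag_tensor(numeric(cout), requires_grad = TRUE)
  ))
  l$forward <- function(x, training = TRUE) {
    y <- ag_dense(x, l$params$W, l$params$b)
    if (out_scale != 1 || out_base != 0) {
      y <- ag_add(ag_scale(y, out_scale), out_base)
    }
    y
  }
  l
}

nn_seq_dense <- function(cin, cout, out_scale = 1, out_base = 0) {
  force(out_scale); force(out_base)
  l <- new_layer(params = list(
    W = nn_param(c(cin, cout), sd = sqrt(1 / cin)),
    b = ag_tensor(numeric(cout), requires_grad = TRUE)
  ))
  l$forward <- function(x, training = TRUE) {
    y <- ag_seq_dense(x, l$params$W, l$params$b)
    if (out_scale != 1 || out_base != 0) {
      y <- ag_add(ag_scale(y, out_scale), out_base)
    }
    y
  }
  l
}

# Bidirectional LSTM over (T, C, N); output (T, 2*hidden, N).
nn_bilstm <- function(cin, hidden) {
  make_dir <- function() {
    b <- numeric(4 * hidden)
    b[(hidden + 1):(2 * hidden)] <- 1 # forget-gate bias
    list(
      Wx = nn_param(c(cin, 4 * hidden), sd = sqrt(1 / cin)),
      Wh = nn_param(c(hidden, 4 * hidden), sd = sqrt(1 / hidden)),
      b = ag_tensor(b, requires_grad = TRUE)
    )
  }
  pf <- make_dir(); pb <- make_dir()
  l <- new_layer(params = list(
    fwd.Wx = pf$Wx, fwd.Wh = pf$Wh, fwd.b = pf$b,
    bwd.Wx = pb$Wx, bwd.Wh = pb$Wh, bwd.b = pb$b
  ))
  run_dir <- function(x, order, Wx, Wh, b) {
    d <- dim(ag_value(x))
    N <- d[3]
    h <- ag_tensor(matrix(0, N, hidden))
    cc <- ag_tensor(matrix(0, N, hidden))
    outs <- vector("list", d[1])
    for (t in order) {
      xt <- ag_time_slice(x, t)
      z <- ag_add(ag_dense(xt, Wx, b), ag_matmul(h, Wh))
      i_g <- ag_sigmoid(ag_slice(z, 2L, seq_len(hidden)))
      f_g <- ag_sigmoid(ag_slice(z, 2L, hidden + seq_len(hidden)))
      g_g <- ag_tanh(ag_slice(z, 2L, 2L * hidden + seq_len(hidden)))
      o_g <- ag_sigmoid(ag_slice(z, 2L, 3L * hidden + seq_len(hidden)))
      cc <- ag_add(ag_mul(f_g, cc), ag_mul(i_g, g_g))
      h <- ag_mul(o_g, ag_tanh(cc))
      outs[[t]] <- h
    }
    ag_stack_time(outs)
  }
  l$forward <- function(x, training = TRUE) {
    T <- dim(ag_value(x))[1]
    hf <- run_dir(x, seq_len(T), l$params$fwd.Wx, l$params$fwd.Wh,
                  l$params$fwd.b)
    hb <- run_dir(x, rev(seq_len(T)), l$params$bwd.Wx, l$params$bwd.Wh,
                  l$params$bwd.b)
    ag_concat(list(hf, hb), axis = 2L)
  }
  l
}

# Temporal multi-head self-attention block with residual connection.
nn_temporal_attention <- function(dim, nhead) {
  force(nhead)
  wq <- nn_seq_dense(dim, dim); wk <- nn_seq_dense(dim, dim)
  wv <- nn_seq_dense(dim, dim); wo <- nn_seq_dense(dim, dim)
  l <- new_layer(children = list(wq = wq, wk = wk, wv = wv, wo = wo))
  l$forward <- function(x, training = TRUE) {
    att <- ag_mha_core(wq$forward(x), wk$forward(x), wv$forward(x), nhead)
    ag_add(x, wo$forward(att))
  }
  l
}

# ---- optimizer -------------------------------------------------------------

#' Adam optimizer state
#'
#' @param params Named list of leaf `ag_tensor` parameters.
#' @param lr Learning rate.
#' @param weight_decay L2 penalty coefficient added to gradients.
#' @param beta1,beta2,eps Adam moment coefficients.
#' @return An optimizer environment; step with [adam_step()].
#' @export
adam_optimizer <- function(params, lr = 2e-4, weight_decay = 1e-5,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$weight_decay <- weight_decay
  opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(params, function(p) ag_value(p) * 0)
  opt$v <- lapply(params, function(p) ag_value(p) * 0)
  opt
}

#' Take one Adam step over parameters with accumulated gradients
#'
#' @param opt Optimizer from [adam_optimizer()].
#' @param lr Learning rate for this step (overrides the stored rate, for
#'   schedules).
#' @export
adam_step <- function(opt, lr = opt$lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (nm in names(opt$params)) {
    p <- opt$params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    if (opt$weight_decay > 0) g <- g + opt$weight_decay * p$value
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  invisible(opt)
}

nn_batchnorm1d <- function(c, momentum = 0.1, eps = 1e-5) {
  l <- new_layer(params = list(
    gamma = ag_tensor(rep(1, c), requires_grad = TRUE),
    beta = ag_tensor(numeric(c), requires_grad = TRUE)
  ))
  l$running_mean <- numeric(c)
  l$running_var <- rep(1, c)
  l$momentum <- momentum
  l$eps <- eps
  l$forward <- function(x, training = TRUE) {
    ag_batchnorm_mat(x, l$params$gamma, l$params$beta, l, training)
  }
  l
}
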