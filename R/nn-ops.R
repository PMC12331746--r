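# Structured autograd ops for video tensors (H, W, T, C, N) and sequence
# tensors (T, C, N).

same_pad <- function(k, d) as.integer(d * (k - 1) %/% 2)

# 3D convolution. stride is spatial (h, w); temporal stride is always 1 so
# the 20-frame axis survives every stage. pad/dilation are (t, h, w).
ag_conv3d <- function(x, w, b = NULL, stride = c(1L, 1L),
                      dilation = c(1L, 1L, 1L), pad = NULL) {
  xv <- ag_value(x); wv <- ag_value(w)
  wd <- dim(wv) # (kh, kw, kt, Cin, Cout)
  if (is.null(pad)) {
    pad <- c(same_pad(wd[3], dilation[1]),
             same_pad(wd[1], dilation[2]),
             same_pad(wd[2], dilation[3]))
  }
  xd <- dim(xv)
  if (length(xd) != 5L) stop("conv3d input must be 5-D (H,W,T,C,N), got ",
                             paste(xd, collapse = "x"))
  if (xd[4] != wd[4]) stop("conv3d: input has ", xd[4],
                           " channels, kernel expects ", wd[4])
  bv <- if (is.null(b)) numeric(0) else ag_value(b)
  y <- conv3d_fw_cpp(xv, as.integer(xd), wv, as.integer(wd), bv,
                     as.integer(stride[1]), as.integer(stride[2]),
                     as.integer(pad[2]), as.integer(pad[3]),
                     as.integer(pad[1]),
                     as.integer(dilation[2]), as.integer(dilation[3]),
                     as.integer(dilation[1]))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(y, parents, function(g) {
    need_gx <- is_ag(x) && x$requires_grad
    need_gw <- is_ag(w) && w$requires_grad
    bwres <- conv3d_bw_cpp(xv, as.integer(xd), wv, as.integer(wd), g,
                           as.integer(stride[1]), as.integer(stride[2]),
                           as.integer(pad[2]), as.integer(pad[3]),
                           as.integer(pad[1]),
                           as.integer(dilation[2]), as.integer(dilation[3]),
                           as.integer(dilation[1]),
                           need_gx, need_gw)
    gb <- NULL
    if (!is.null(b)) {
      gd <- dim(g)
      gb <- rowSums(colSums(array(g, c(prod(gd[1:3]), gd[4], gd[5]))))
    }
    gx <- if (need_gx) bwres$gx else NULL
    gw <- if (need_gw) bwres$gw else NULL
    if (is.null(b)) list(gx, gw) else list(gx, gw, gb)
  })
}

# per-channel helpers for (H, W, T, C, N)
ch_broadcast <- function(v, d) array(rep(v, each = prod(d[1:3])), dim = d)
ch_sum <- function(a, d) rowSums(colSums(array(a, c(prod(d[1:3]), d[4], d[5]))))

# Batch normalization over (H, W, T, N) per channel, with running
# statistics kept on `layer` (an environment with $running_mean,
# $running_var, $momentum, $eps).
ag_batchnorm <- function(x, gamma, beta, layer, training) {
  xv <- ag_value(x)
  d <- dim(xv)
  n_red <- prod(d[c(1, 2, 3, 5)])
  eps <- layer$eps
  if (training) {
    mu <- ch_sum(xv, d) / n_red
    va <- ch_sum(xv^2, d) / n_red - mu^2
    va <- pmax(va, 0)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * va
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
  }
  sd_ <- sqrt(va + eps)
  gv <- ag_value(gamma); bv <- ag_value(beta)
  scale <- gv / sd_
  y <- xv * ch_broadcast(scale, d) + ch_broadcast(bv - mu * scale, d)
  ag_node(y, list(x, gamma, beta), function(g) {
    xhat <- xv * ch_broadcast(1 / sd_, d) - ch_broadcast(mu / sd_, d)
    gbeta <- ch_sum(g, d)
    ggamma <- ch_sum(g * xhat, d)
    if (training) {
      gx <- ch_broadcast(scale, d) *
        (g - ch_broadcast(gbeta / n_red, d) -
           xhat * ch_broadcast(ggamma / n_red, d))
    } else {
      gx <- g * ch_broadcast(scale, d)
    }
    list(gx, ggamma, gbeta)
  })
}

# Non-overlapping k x k spatial average pooling.
ag_avgpool_hw <- function(x, k) {
  xv <- ag_value(x)
  d <- dim(xv)
  H <- d[1]; W <- d[2]
  if (H %% k != 0L || W %% k != 0L) stop("pooling size must divide H and W")
  H2 <- H %/% k; W2 <- W %/% k
  y1 <- colSums(array(xv, c(k, H2, W, d[3], d[4], d[5])), dims = 1L)
  y2 <- aperm(array(y1, c(H2, k, W2, d[3], d[4], d[5])), c(2, 1, 3, 4, 5, 6))
  y <- colSums(y2, dims = 1L) / (k * k)
  ag_node(y, list(x), function(g) {
    list(g[rep(seq_len(H2), each = k), rep(seq_len(W2), each = k), , , ,
           drop = FALSE] / (k * k))
  })
}

# Nearest-neighbour spatial upsampling by integer factor k.
ag_upsample_hw <- function(x, k) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- xv[rep(seq_len(d[1]), each = k), rep(seq_len(d[2]), each = k), , , ,
          drop = FALSE]
  ag_node(y, list(x), function(g) {
    gd <- dim(g)
    H2 <- d[1]; W2 <- d[2]
    s1 <- colSums(array(g, c(k, H2, gd[2], gd[3], gd[4], gd[5])), dims = 1L)
    s2 <- aperm(array(s1, c(H2, k, W2, gd[3], gd[4], gd[5])),
                c(2, 1, 3, 4, 5, 6))
    list(colSums(s2, dims = 1L))
  })
}

# Global average pool over H, W -> sequence (T, C, N).
ag_gap_hw <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  s <- d[1] * d[2]
  y <- colSums(array(xv, c(s, d[3], d[4], d[5])), dims = 1L) / s
  ag_node(y, list(x), function(g) {
    list(array(rep(g, each = s), dim = d) / s)
  })
}

# Global average pool over H, W, T -> (C, N).
ag_gap_hwt <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  s <- prod(d[1:3])
  y <- colSums(array(xv, c(s, d[4], d[5])), dims = 1L) / s
  ag_node(y, list(x), function(g) {
    list(array(rep(g, each = s), dim = d) / s)
  })
}

# Mean over time for a sequence (T, C, N) -> (C, N).
ag_mean_time <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- colSums(xv, dims = 1L) / d[1]
  ag_node(y, list(x), function(g) {
    list(array(rep(g, each = d[1]), dim = d) / d[1])
  })
}

# Per-step dense layer on a sequence: (T, C, N) x (C, O) -> (T, O, N).
ag_seq_dense <- function(x, W, b = NULL) {
  xv <- ag_value(x); Wv <- ag_value(W)
  d <- dim(xv)
  xm <- matrix(aperm(xv, c(1, 3, 2)), ncol = d[2]) # (T*N, C)
  y <- xm %*% Wv
  if (!is.null(b)) y <- sweep(y, 2L, ag_value(b), `+`)
  O <- ncol(Wv)
  yarr <- aperm(array(y, c(d[1], d[3], O)), c(1, 3, 2))
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_node(yarr, parents, function(g) {
    gm <- matrix(aperm(g, c(1, 3, 2)), ncol = O)
    gx <- aperm(array(gm %*% t(Wv), c(d[1], d[3], d[2])), c(1, 3, 2))
    gW <- crossprod(xm, gm)
    if (is.null(b)) list(gx, gW) else list(gx, gW, colSums(gm))
  })
}

# Extract time step t of a sequence (T, C, N) as an (N, C) matrix.
ag_time_slice <- function(x, t) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- t(array(xv[t, , ], dim = d[2:3]))
  ag_node(y, list(x), function(g) {
    out <- array(0, dim = d)
    out[t, , ] <- t(g)
    list(out)
  })
}

# Stack a list of (N, C) matrices into a sequence (T, C, N).
ag_stack_time <- function(steps) {
  vals <- lapply(steps, ag_value)
  N <- nrow(vals[[1]]); C <- ncol(vals[[1]]); T <- length(vals)
  out <- array(0, dim = c(T, C, N))
  for (t in seq_len(T)) out[t, , ] <- t(vals[[t]])
  ag_node(out, steps, function(g) {
    lapply(seq_len(T), function(t) t(array(g[t, , ], dim = c(C, N))))
  })
}

# Scaled dot-product multi-head self-attention core on (T, D, N)
# sequences; D must be divisible by nhead.
ag_mha_core <- function(q, k, v, nhead) {
  qv <- ag_value(q); kv <- ag_value(k); vv <- ag_value(v)
  d <- dim(qv)
  D <- d[2]; N <- d[3]
  if (D %% nhead != 0L) stop("attention width not divisible by head count")
  dk <- D %/% nhead
  out <- array(0, dim = d)
  probs <- vector("list", N * nhead)
  for (n in seq_len(N)) {
    for (h in seq_len(nhead)) {
      idx <- (h - 1L) * dk + seq_len(dk)
      Q <- array(qv[, idx, n], dim = c(d[1], dk))
      K <- array(kv[, idx, n], dim = c(d[1], dk))
      V <- array(vv[, idx, n], dim = c(d[1], dk))
      S <- tcrossprod(Q, K) / sqrt(dk)
      S <- S - apply(S, 1L, max)
      P <- exp(S)
      P <- P / rowSums(P)
      out[, idx, n] <- P %*% V
      probs[[(n - 1L) * nhead + h]] <- P
    }
  }
  ag_node(out, list(q, k, v), function(g) {
    gq <- array(0, dim = d); gk <- array(0, dim = d); gv_ <- array(0, dim = d)
    for (n in seq_len(N)) {
      for (h in seq_len(nhead)) {
        idx <- (h - 1L) * dk + seq_len(dk)
        P <- probs[[(n - 1L) * nhead + h]]
        Q <- array(qv[, idx, n], dim = c(d[1], dk))
        K <- array(kv[, idx, n], dim = c(d[1], dk))
        V <- array(vv[, idx, n], dim = c(d[1], dk))
        gO <- array(g[, idx, n], dim = c(d[1], dk))
        gP <- tcrossprod(gO, V)
        gv_[, idx, n] <- crossprod(P, gO)
        gS <- P * (gP - rowSums(gP * P))
        gq[, idx, n] <- gS %*% K / sqrt(dk)
        gk[, idx, n] <- crossprod(gS, Q) / sqrt(dk)
      }
    }
    list(gq, gk, gv_)
  })
}

# Batch normalisation for (N, C) feature matrices (per-column statistics,
# running stats on `layer` as in the 5-D variant).
ag_batchnorm_mat <- function(x, gamma, beta, layer, training) {
  xv <- ag_value(x)
  n <- nrow(xv)
  eps <- layer$eps
  if (training && n > 1L) {
    mu <- colMeans(xv)
    va <- colMeans(xv^2) - mu^2
    va <- pmax(va, 0)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * va
    use_batch <- TRUE
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
    use_batch <- FALSE
  }
  sd_ <- sqrt(va + eps)
  gv <- ag_value(gamma); bv <- ag_value(beta)
  scale <- gv / sd_
  y <- sweep(sweep(xv, 2L, scale, `*`), 2L, bv - mu * scale, `+`)
  ag_node(y, list(x, gamma, beta), function(g) {
    xhat <- sweep(sweep(xv, 2L, mu, `-`), 2L, sd_, `/`)
    gbeta <- colSums(g)
    ggamma <- colSums(g * xhat)
    if (use_batch) {
      gx <- sweep(g - matrix(gbeta / n, n, length(gbeta), byrow = TRUE) -
                    xhat * matrix(ggamma / n, n, length(ggamma),
                                  byrow = TRUE),
                  2L, scale, `*`)
    } else {
      gx <- sweep(g, 2L, scale, `*`)
    }
    list(gx, ggamma, gbeta)
  })
}
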