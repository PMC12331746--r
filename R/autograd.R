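# Reverse-mode automatic differentiation on dense R arrays.
#
# Tensors are environments holding a numeric array ($value), an accumulated
# gradient ($grad), and -- for graph nodes -- their parents and a backward
# closure. Video feature tensors use dim (H, W, T, C, N); sequence tensors
# use dim (T, C, N); matrices are (N, F). Gradients are exact (double
# precision) and every op is checked against finite differences in the
# test suite.

ag_state <- new.env(parent = emptyenv())
ag_state$grad_enabled <- TRUE

#' Evaluate an expression without recording the autograd graph
#'
#' @param expr Expression to evaluate.
#' @return The expression's value.
#' @export
ag_no_grad <- function(expr) {
  old <- ag_state$grad_enabled
  ag_state$grad_enabled <- FALSE
  on.exit(ag_state$grad_enabled <- old)
  expr
}

#' Create an autograd tensor
#'
#' @param value Numeric array, matrix or vector.
#' @param requires_grad Track gradients for this leaf.
#' @param name Optional label (used in parameter lists).
#' @return An `ag_tensor`.
#' @export
ag_tensor <- function(value, requires_grad = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  e$parents <- NULL
  e$bw <- NULL
  e$name <- name
  class(e) <- "ag_tensor"
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")

#' Plain value of a tensor (or pass through a plain array)
#' @param x `ag_tensor` or array.
#' @return Numeric array.
#' @export
ag_value <- function(x) if (is_ag(x)) x$value else x

needs_graph <- function(parents) {
  ag_state$grad_enabled &&
    any(vapply(parents, function(p) is_ag(p) && p$requires_grad, logical(1)))
}

# Build an op node. `parents` is a list of ag_tensors (plain inputs are
# treated as constants); `bw` maps the output gradient to a list of parent
# gradients (NULL entries for constants).
ag_node <- function(value, parents, bw) {
  if (!needs_graph(parents)) {
    return(ag_tensor(value))
  }
  out <- ag_tensor(value, requires_grad = TRUE)
  out$parents <- Filter(is_ag, parents)
  keep <- vapply(parents, is_ag, logical(1))
  out$bw <- function(g) bw(g)[keep]
  out
}

#' Backpropagate from a scalar loss
#'
#' Accumulates gradients into every reachable leaf with
#' `requires_grad = TRUE`. Interior-node gradients are released as soon as
#' they have been consumed.
#'
#' @param loss Scalar `ag_tensor`.
#' @param grad Seed gradient (default 1).
#' @export
ag_backward <- function(loss, grad = 1) {
  stopifnot(is_ag(loss))
  if (!loss$requires_grad) stop("loss does not require grad")
  # iterative topological sort (post-order DFS)
  topo <- vector("list", 1024L)
  n_topo <- 0L
  visited <- new.env(parent = emptyenv(), hash = TRUE)
  stack <- list(list(node = loss, expanded = FALSE))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- format(node)
    if (top$expanded) {
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- node
    } else if (is.null(visited[[key]])) {
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, expanded = TRUE)
      for (p in node$parents) {
        if (p$requires_grad && is.null(visited[[format(p)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
        }
      }
    }
  }
  loss$grad <- if (length(grad) == 1L && length(loss$value) == 1L) grad else grad
  for (i in seq(n_topo, 1L)) {
    node <- topo[[i]]
    if (is.null(node$bw)) next
    g <- node$grad
    if (is.null(g)) next
    grads <- node$bw(g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      gj <- grads[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      if (!p$requires_grad) next
      p$grad <- if (is.null(p$grad)) gj else p$grad + gj
    }
    node$grad <- NULL # free interior gradient
  }
  invisible(loss)
}

#' Reset gradients on a list of parameters
#' @param params List of `ag_tensor` leaves.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- elementwise ops -------------------------------------------------------

ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(av + bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L && length(bv) > 1L) sum(g) else g
    gb <- if (length(bv) == 1L && length(av) > 1L) sum(g) else g
    list(ga, gb)
  })
}

ag_sub <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(av - bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L && length(bv) > 1L) sum(g) else g
    gb <- if (length(bv) == 1L && length(av) > 1L) sum(-g) else -g
    list(ga, gb)
  })
}

ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(av * bv, list(a, b), function(g) {
    ga <- g * bv; gb <- g * av
    if (length(av) == 1L && length(bv) > 1L) ga <- sum(ga)
    if (length(bv) == 1L && length(av) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ag_scale <- function(a, k) {
  av <- ag_value(a)
  ag_node(av * k, list(a), function(g) list(g * k))
}

ag_relu <- function(a) {
  av <- ag_value(a)
  m <- av > 0
  ag_node(av * m, list(a), function(g) list(g * m))
}

ag_gelu <- function(a) {
  av <- ag_value(a)
  k <- sqrt(2 / pi)
  inner <- k * (av + 0.044715 * av^3)
  th <- tanh(inner)
  y <- 0.5 * av * (1 + th)
  ag_node(y, list(a), function(g) {
    dinner <- k * (1 + 3 * 0.044715 * av^2)
    dy <- 0.5 * (1 + th) + 0.5 * av * (1 - th^2) * dinner
    list(g * dy)
  })
}

ag_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-ag_value(a)))
  ag_node(y, list(a), function(g) list(g * y * (1 - y)))
}

ag_tanh <- function(a) {
  y <- tanh(ag_value(a))
  ag_node(y, list(a), function(g) list(g * (1 - y^2)))
}

ag_sum <- function(a) {
  av <- ag_value(a)
  d <- dim(av)
  ag_node(sum(av), list(a), function(g) {
    out <- array(g, dim = if (is.null(d)) length(av) else d)
    list(out)
  })
}

ag_mean <- function(a) {
  av <- ag_value(a)
  n <- length(av)
  d <- dim(av)
  ag_node(mean(av), list(a), function(g) {
    list(array(g / n, dim = if (is.null(d)) n else d))
  })
}

ag_reshape <- function(a, dims) {
  av <- ag_value(a)
  old <- dim(av)
  v <- av
  dim(v) <- dims
  ag_node(v, list(a), function(g) {
    dim(g) <- old
    list(g)
  })
}

ag_aperm <- function(a, perm) {
  av <- ag_value(a)
  ag_node(aperm(av, perm), list(a), function(g) list(aperm(g, order(perm))))
}

# Concatenate along `axis` (all inputs same rank / other dims equal).
ag_concat <- function(tensors, axis) {
  vals <- lapply(tensors, ag_value)
  dims <- lapply(vals, dim)
  sizes <- vapply(dims, function(d) d[axis], numeric(1))
  outdim <- dims[[1]]
  outdim[axis] <- sum(sizes)
  out <- array(0, dim = outdim)
  rank <- length(outdim)
  idx <- lapply(outdim, seq_len)
  off <- 0L
  for (i in seq_along(vals)) {
    sel <- idx
    sel[[axis]] <- off + seq_len(sizes[i])
    out <- do.call(`[<-`, c(list(out), sel, list(value = vals[[i]])))
    off <- off + sizes[i]
  }
  ag_node(out, tensors, function(g) {
    grads <- vector("list", length(vals))
    off <- 0L
    for (i in seq_along(vals)) {
      sel <- idx
      sel[[axis]] <- off + seq_len(sizes[i])
      grads[[i]] <- do.call(`[`, c(list(g), sel, list(drop = FALSE)))
      off <- off + sizes[i]
    }
    grads
  })
}

# Contiguous slice along one axis.
ag_slice <- function(a, axis, idx) {
  av <- ag_value(a)
  d <- dim(av)
  sel <- lapply(d, seq_len)
  sel[[axis]] <- idx
  v <- do.call(`[`, c(list(av), sel, list(drop = FALSE)))
  ag_node(v, list(a), function(g) {
    out <- array(0, dim = d)
    out <- do.call(`[<-`, c(list(out), sel, list(value = g)))
    list(out)
  })
}

ag_matmul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

# x: (N, in) matrix; W: (in, out); b: length out (or NULL)
ag_dense <- function(x, W, b = NULL) {
  xv <- ag_value(x); Wv <- ag_value(W)
  y <- xv %*% Wv
  if (!is.null(b)) y <- sweep(y, 2L, ag_value(b), `+`)
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_node(y, parents, function(g) {
    gx <- g %*% t(Wv)
    gW <- crossprod(xv, g)
    if (is.null(b)) list(gx, gW) else list(gx, gW, colSums(g))
  })
}

row_max <- function(m) {
  r <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) r <- pmax(r, m[, j])
  r
}

# Softmax over the given axis (moved-to-last internally).
ag_softmax <- function(a, axis) {
  av <- ag_value(a)
  d <- dim(av)
  rank <- length(d)
  perm <- c(setdiff(seq_len(rank), axis), axis)
  xm <- matrix(aperm(av, perm), ncol = d[axis])
  xm <- xm - row_max(xm)
  e <- exp(xm)
  p <- e / rowSums(e)
  parr <- array(p, dim = d[perm])
  y <- aperm(parr, order(perm))
  ag_node(y, list(a), function(g) {
    gm <- matrix(aperm(g, perm), ncol = d[axis])
    gi <- p * (gm - rowSums(gm * p))
    list(aperm(array(gi, dim = d[perm]), order(perm)))
  })
}

# ---- losses ----------------------------------------------------------------

# Mean cross-entropy from logits. x: (M, K); target: integer vector in 1..K.
ag_ce_logits <- function(x, target) {
  xv <- ag_value(x)
  m <- nrow(xv)
  xs <- xv - row_max(xv)
  lse <- log(rowSums(exp(xs)))
  picked <- xs[cbind(seq_len(m), target)]
  loss <- mean(lse - picked)
  p <- exp(xs - lse)
  ag_node(loss, list(x), function(g) {
    gx <- p
    gx[cbind(seq_len(m), target)] <- gx[cbind(seq_len(m), target)] - 1
    list(g * gx / m)
  })
}

# Mean squared error against a constant target.
ag_mse <- function(pred, target) {
  pv <- ag_value(pred)
  tv <- ag_value(target)
  diffv <- pv - tv
  n <- length(diffv)
  ag_node(mean(diffv^2), list(pred), function(g) list(g * 2 * diffv / n))
}

# Soft Dice loss on probabilities. probs: (M, K); onehot: (M, K) constant.
ag_dice_loss <- function(probs, onehot, eps = 1e-6) {
  pv <- ag_value(probs)
  qv <- ag_value(onehot)
  K <- ncol(pv)
  num <- 2 * colSums(pv * qv)
  den <- colSums(pv^2) + colSums(qv^2) + eps
  dice <- num / den
  loss <- 1 - mean(dice)
  ag_node(loss, list(probs), function(g) {
    # d dice_c / dp = (2 q den_c - num_c 2 p) / den_c^2
    gp <- -(sweep(2 * qv, 2L, den, `/`) -
              sweep(2 * pv, 2L, num / den^2, `*`)) / K
    list(g * gp)
  })
}
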