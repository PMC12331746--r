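#' Model configuration
#'
#' Channel widths follow the published architecture at `width_scale = 1`:
#' a 3D residual-bottleneck encoder (stages of 3/4/6/3 blocks, spatial
#' output stride 16, temporal stride 1 throughout), an atrous spatial
#' pyramid projecting to 256 deep-semantic channels, a 48-channel low-level
#' tap, rank-4 low-rank expert blocks per regression task, a
#' 1,072-channel fusion (4 x 256 + 48) feeding the score and CAD heads,
#' bidirectional recurrent curve decoders (256 hidden units per direction)
#' and 8-head temporal self-attention at width 512. `width_scale` shrinks
#' every channel width proportionally for reduced-size experiments;
#' `input_size` shrinks the spatial grid.
#'
#' @param input_size Spatial frame size (pixels; default 256).
#' @param n_frames Frames per cycle block (default 20).
#' @param width_scale Multiplier on all channel widths (1, 1/2, 1/4, 1/8).
#' @param blocks Residual blocks per encoder stage.
#' @param rank Bottleneck rank of the low-rank expert convolutions.
#' @param attn_heads Temporal attention heads.
#' @param aspp_rates Spatial dilation rates of the atrous pyramid.
#' @param lowlevel_channels Channels of the low-level tap; default scales
#'   the published 48.
#' @param seed Seed for parameter initialisation.
#' @return A config list for [iecad_model()].
#' @export
iecad_config <- function(input_size = 256L, n_frames = 20L, width_scale = 1,
                         blocks = c(3L, 4L, 6L, 3L), rank = 4L,
                         attn_heads = 8L, aspp_rates = c(1L, 6L, 12L, 18L),
                         lowlevel_channels = NULL, seed = 1L) {
  sc <- function(x) max(2L, as.integer(round(x * width_scale)))
  attn_dim <- sc(512)
  if (attn_dim %% attn_heads != 0L) {
    stop("attention width ", attn_dim, " not divisible by ", attn_heads,
         " heads; adjust width_scale or attn_heads")
  }
  if (input_size %% 16L != 0L) stop("input_size must be a multiple of 16")
  ll <- if (is.null(lowlevel_channels)) sc(48) else as.integer(lowlevel_channels)
  cfg <- list(
    input_size = as.integer(input_size),
    n_frames = as.integer(n_frames),
    width_scale = width_scale,
    stem = sc(64),
    stage_out = c(sc(256), sc(512), sc(1024), sc(2048)),
    stage_mid = c(sc(64), sc(128), sc(256), sc(512)),
    blocks = as.integer(blocks),
    aspp_out = sc(256),
    aspp_rates = as.integer(aspp_rates),
    lowlevel = ll,
    lstm_hidden = sc(256),
    attn_dim = attn_dim,
    attn_heads = as.integer(attn_heads),
    head_hidden = sc(256),
    rank = as.integer(rank),
    seed = as.integer(seed)
  )
  cfg$fusion <- 4L * cfg$aspp_out + cfg$lowlevel
  cfg
}

# Broadcast a (T, C, N) sequence across an H x W grid.
ag_broadcast_hw <- function(x, H, W) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- array(rep(xv, each = H * W), dim = c(H, W, d[1], d[2], d[3]))
  ag_node(y, list(x), function(g) {
    list(colSums(array(g, c(H * W, d[1], d[2], d[3])), dims = 1L))
  })
}

#' Build the multi-task video network
#'
#' Shared 3D encoder (stem + 4 bottleneck stages + atrous pyramid), a
#' low-level feature tap, four low-rank expert blocks, and six decoders:
#' view classification, 3-class segmentation, GLS and LVEF curve
#' regression, GWE regression, and the fused Gensini-score / CAD heads
#' with temporal self-attention.
#'
#' @param config From [iecad_config()].
#' @return An `iecad_model` environment with `$layers`, `$params` and
#'   `$config`.
#' @export
iecad_model <- function(config = iecad_config()) {
  set.seed(config$seed)
  L <- list()
  L$stem <- nn_conv_bn(1L, config$stem, c(3L, 7L, 7L), stride = c(2L, 2L))
  make_stage <- function(cin, cout, mid, n, stride, dilation = 1L) {
    blocks <- vector("list", n)
    for (i in seq_len(n)) {
      blocks[[i]] <- nn_bottleneck(if (i == 1L) cin else cout, cout, mid,
                                   stride = if (i == 1L) stride else 1L,
                                   dilation = dilation)
    }
    names(blocks) <- paste0("b", seq_len(n))
    blocks
  }
  L$stage1 <- make_stage(config$stem, config$stage_out[1], config$stage_mid[1],
                         config$blocks[1], 1L)
  L$stage2 <- make_stage(config$stage_out[1], config$stage_out[2],
                         config$stage_mid[2], config$blocks[2], 2L)
  L$stage3 <- make_stage(config$stage_out[2], config$stage_out[3],
                         config$stage_mid[3], config$blocks[3], 2L)
  L$stage4 <- make_stage(config$stage_out[3], config$stage_out[4],
                         config$stage_mid[4], config$blocks[4], 1L,
                         dilation = 2L)
  L$lowlevel_proj <- nn_conv_bn(config$stage_out[1], config$lowlevel,
                                c(1L, 1L, 1L))
  a <- config$aspp_out
  L$aspp0 <- nn_conv_bn(config$stage_out[4], a, c(1L, 1L, 1L))
  for (i in seq_along(config$aspp_rates)[-1]) {
    r <- config$aspp_rates[i]
    L[[paste0("aspp", i - 1L)]] <- nn_conv_bn(config$stage_out[4], a,
                                              c(3L, 3L, 3L),
                                              dilation = c(1L, r, r))
  }
  L$aspp_pool_fc <- nn_seq_dense(config$stage_out[4], a)
  L$aspp_proj <- nn_conv_bn((length(config$aspp_rates) + 1L) * a, a,
                            c(1L, 1L, 1L))
  L$conv_block1 <- nn_conv_bn(a, a, c(3L, 3L, 3L))
  L$conv_block2 <- nn_conv_bn(a, a, c(1L, 1L, 1L))
  for (task in c("gls", "lvef", "gwe", "gensini")) {
    L[[paste0("lr_", task)]] <- nn_lowrank_block(a, config$rank)
  }
  # classification logits carry a fixed gain for the same reason the
  # regression heads carry an affine map: with a rate-bounded optimiser
  # the logit magnitude needed to separate classes must be reachable
  # within the scheduled update count
  L$view_head <- nn_dense(config$lowlevel, 3L, out_scale = 60)
  L$seg_conv <- nn_conv_bn(a + config$lowlevel, a, c(3L, 3L, 3L))
  L$seg_out <- nn_conv3d(a, 3L, c(1L, 1L, 1L))
  h <- config$lstm_hidden
  # regression heads predict standardised values mapped onto the
  # targets' physiologic ranges by a fixed affine (centre, spread)
  L$gls_lstm <- nn_bilstm(a, h)
  L$gls_fc <- nn_seq_dense(2L * h, 1L, out_scale = 10, out_base = -8)
  L$lvef_lstm <- nn_bilstm(a, h)
  L$lvef_fc <- nn_seq_dense(2L * h, 1L, out_scale = 20, out_base = 15)
  L$gwe_fc <- nn_dense(a, 1L, out_scale = 5, out_base = 95)
  ad <- config$attn_dim
  L$gensini_conv <- nn_conv_bn(config$fusion, ad, c(3L, 3L, 3L))
  L$gensini_attn <- nn_temporal_attention(ad, config$attn_heads)
  L$gensini_fc1 <- nn_dense(ad, config$head_hidden)
  L$gensini_fc2 <- nn_dense(config$head_hidden, 1L, out_scale = 25,
                            out_base = 20)
  L$cad_conv <- nn_conv_bn(config$fusion, ad, c(3L, 3L, 3L))
  L$cad_attn <- nn_temporal_attention(ad, config$attn_heads)
  L$cad_fc1 <- nn_dense(ad, config$head_hidden)
  L$cad_fc2 <- nn_dense(config$head_hidden, 2L, out_scale = 10)

  m <- new.env(parent = emptyenv())
  m$config <- config
  m$layers <- L
  m$params <- collect_params(L)
  class(m) <- "iecad_model"
  m
}

#' @export
print.iecad_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(ag_value(p)), numeric(1)))
  cat(sprintf("<iecad_model> input %dx%dx%d, %s parameters\n",
              x$config$n_frames, x$config$input_size, x$config$input_size,
              format(np, big.mark = ",")))
  invisible(x)
}

# Convert a list of (T, H, W) clips into the network input (H, W, T, 1, N).
blocks_to_input <- function(blocks, config) {
  if (!is.list(blocks)) blocks <- list(blocks)
  s <- config$input_size
  for (b in blocks) {
    d <- dim(b)
    if (length(d) != 3L || d[1] != config$n_frames || d[2] != s || d[3] != s) {
      stop("expected clips of ", config$n_frames, "x", s, "x", s, ", got ",
           paste(d, collapse = "x"))
    }
  }
  x <- array(0, dim = c(s, s, config$n_frames, 1L, length(blocks)))
  for (n in seq_along(blocks)) {
    x[, , , 1L, n] <- aperm(blocks[[n]], c(2, 3, 1))
  }
  x
}

# Release dead activation memory eagerly. Only worthwhile for large
# spatial grids, where single activations reach hundreds of megabytes.
maybe_trim <- function(model) {
  if (model$config$input_size >= 128L) {
    gc(FALSE)
    mem_trim_cpp()
  }
  invisible(NULL)
}

run_stage <- function(stage, x, training, model = NULL) {
  for (b in stage) {
    x <- b$forward(x, training)
    if (!is.null(model)) maybe_trim(model)
  }
  x
}

#' Encode a batch into the shared feature bundle
#'
#' @param model An [iecad_model()].
#' @param x Input tensor (H, W, T, 1, N) as array or `ag_tensor`.
#' @param training Batch-statistics mode for normalisation layers.
#' @return List of feature tensors: `lowlevel_pre` (1/4 grid),
#'   `lowlevel_ds` (1/16 grid), `deep` (atrous-pyramid output) and
#'   `backbone` (conv-block output), each preserving all frames.
#' @export
iecad_encode <- function(model, x, training = FALSE) {
  L <- model$layers
  if (!is_ag(x)) x <- ag_tensor(x)
  y <- L$stem$forward(x, training)
  y <- ag_avgpool_hw(y, 2L)
  maybe_trim(model)
  s1 <- run_stage(L$stage1, y, training, model)
  lowlevel_pre <- L$lowlevel_proj$forward(s1, training)
  y <- run_stage(L$stage2, s1, training, model)
  y <- run_stage(L$stage3, y, training, model)
  y <- run_stage(L$stage4, y, training, model)
  d <- dim(ag_value(y))
  branches <- list(L$aspp0$forward(y, training))
  for (i in seq_along(model$config$aspp_rates)[-1]) {
    branches[[i]] <- L[[paste0("aspp", i - 1L)]]$forward(y, training)
  }
  pooled <- ag_relu(L$aspp_pool_fc$forward(ag_gap_hw(y)))
  branches[[length(branches) + 1L]] <- ag_broadcast_hw(pooled, d[1], d[2])
  deep <- L$aspp_proj$forward(ag_concat(branches, 4L), training)
  backbone <- L$conv_block2$forward(L$conv_block1$forward(deep, training),
                                    training)
  list(
    lowlevel_pre = lowlevel_pre,
    lowlevel_ds = ag_avgpool_hw(lowlevel_pre, 4L),
    deep = deep,
    backbone = backbone
  )
}

mat_t <- function(x) ag_aperm(x, c(2L, 1L))

decode_view <- function(model, bundle, training) {
  feat <- mat_t(ag_gap_hwt(bundle$lowlevel_ds))
  model$layers$view_head$forward(feat, training)
}

decode_seg <- function(model, bundle, training) {
  L <- model$layers
  up <- ag_upsample_hw(bundle$backbone, 4L)
  y <- L$seg_conv$forward(ag_concat(list(up, bundle$lowlevel_pre), 4L),
                          training)
  maybe_trim(model)
  out <- ag_upsample_hw(L$seg_out$forward(y, training), 4L)
  maybe_trim(model)
  out
}

decode_curve <- function(model, bundle, sparse, lstm, fc, training) {
  feat <- ag_gap_hw(ag_add(bundle$backbone, sparse))
  seq <- lstm$forward(feat, training)
  out <- fc$forward(seq, training) # (T, 1, N)
  d <- dim(ag_value(out))
  ag_reshape(out, c(d[1], d[3]))
}

decode_scalar_head <- function(model, fused, conv, attn, fc1, fc2, act,
                               training) {
  y <- conv$forward(fused, training)
  seq <- attn$forward(ag_gap_hw(y), training)
  feat <- mat_t(ag_mean_time(seq))
  z <- fc1$forward(feat, training)
  z <- if (identical(act, "gelu")) ag_gelu(z) else ag_relu(z)
  fc2$forward(z, training)
}

#' Full multi-task forward pass
#'
#' @param model An [iecad_model()].
#' @param x Input (H, W, T, 1, N) array/tensor, or a list of (T, H, W)
#'   clips, or a single clip.
#' @param tasks Subset of `c("view", "seg", "metrics", "score")`.
#' @param training Normalisation mode.
#' @param bundle Optional precomputed feature bundle (see
#'   [iecad_encode()]), e.g. frozen features during phase-3 training.
#' @return Named list of output tensors: `view_logits`/`view_probs` (N x 3),
#'   `seg_logits`/`seg_probs` (H, W, T, 3, N), `gls` and `lvef` curves
#'   (T x N), `gwe`, `gensini` (N), `cad_logits`/`cad_probs` (N x 2).
#' @export
iecad_forward <- function(model, x,
                          tasks = c("view", "seg", "metrics", "score"),
                          training = FALSE, bundle = NULL) {
  L <- model$layers
  if (is.null(bundle)) {
    if (!is_ag(x) && (is.list(x) || length(dim(x)) == 3L)) {
      x <- blocks_to_input(x, model$config)
    }
    bundle <- iecad_encode(model, x, training)
  }
  out <- list()
  if ("view" %in% tasks) {
    out$view_logits <- decode_view(model, bundle, training)
    out$view_probs <- ag_softmax(out$view_logits, 2L)
  }
  if ("seg" %in% tasks) {
    out$seg_logits <- decode_seg(model, bundle, training)
    # probabilities are recomputed inside the losses during training
    if (!training) out$seg_probs <- ag_softmax(out$seg_logits, 4L)
  }
  need_sparse <- any(c("metrics", "score") %in% tasks)
  if (need_sparse) {
    if (is.null(bundle$sparse_gls)) {
      bundle$sparse_gls <- L$lr_gls$forward(bundle$deep, training)
      bundle$sparse_lvef <- L$lr_lvef$forward(bundle$deep, training)
      bundle$sparse_gwe <- L$lr_gwe$forward(bundle$deep, training)
    }
  }
  if ("metrics" %in% tasks) {
    out$gls <- decode_curve(model, bundle, bundle$sparse_gls,
                            L$gls_lstm, L$gls_fc, training)
    out$lvef <- decode_curve(model, bundle, bundle$sparse_lvef,
                             L$lvef_lstm, L$lvef_fc, training)
    gwe_feat <- mat_t(ag_gap_hwt(ag_add(bundle$backbone, bundle$sparse_gwe)))
    gwe <- L$gwe_fc$forward(gwe_feat, training)
    out$gwe <- ag_reshape(gwe, nrow(ag_value(gwe)))
  }
  if ("score" %in% tasks) {
    sparse_gensini <- L$lr_gensini$forward(bundle$deep, training)
    fused <- ag_concat(list(
      ag_add(bundle$backbone, sparse_gensini),
      bundle$sparse_gls, bundle$sparse_lvef, bundle$sparse_gwe,
      bundle$lowlevel_ds
    ), 4L)
    out$fused_channels <- dim(ag_value(fused))[4]
    gensini <- decode_scalar_head(model, fused, L$gensini_conv,
                                  L$gensini_attn, L$gensini_fc1,
                                  L$gensini_fc2, "gelu", training)
    out$gensini <- ag_reshape(gensini, nrow(ag_value(gensini)))
    out$cad_logits <- decode_scalar_head(model, fused, L$cad_conv,
                                         L$cad_attn, L$cad_fc1, L$cad_fc2,
                                         "relu", training)
    out$cad_probs <- ag_softmax(out$cad_logits, 2L)
  }
  out
}

#' Low-rank expert block applied to a feature tensor
#'
#' Exposes one rank-`r` expert convolution block directly: the 3x3x3 stage
#' factorised through `r` channels, then a 1x1x1 low-rank stage, each with
#' normalisation and rectification. Output shape equals input shape.
#'
#' @param features (H, W, T, C, N) array or tensor with C channels.
#' @param rank Bottleneck rank.
#' @param seed Parameter seed.
#' @return Same-shape array.
#' @export
low_rank_block <- function(features, rank = 4L, seed = 1L) {
  v <- ag_value(features)
  d <- dim(v)
  set.seed(seed)
  blk <- nn_lowrank_block(d[4], rank)
  ag_value(ag_no_grad(blk$forward(ag_tensor(v), training = TRUE)))
}

#' Count trainable parameters
#' @param model,layer An [iecad_model()] or a single layer.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  ps <- if (inherits(model, "iecad_model")) model$params else
    collect_params(model)
  sum(vapply(ps, function(p) length(ag_value(p)), numeric(1)))
}

#' Evaluate the network on one video block
#'
#' Runs the full forward pass in evaluation mode (running normalisation
#' statistics, no gradient graph) and returns plain numeric outputs.
#'
#' @param model An [iecad_model()].
#' @param block A (T, H, W) video block.
#' @return A `network_output` list: `view_probs` (3), `seg_probs`
#'   (H, W, T, 3), `gls`/`lvef` curves, `gwe`, `gensini`, `cad_probs` (2).
#' @export
predict_block <- function(model, block) {
  out <- ag_no_grad(iecad_forward(model, list(block), training = FALSE))
  structure(list(
    view_probs = as.numeric(ag_value(out$view_probs)),
    seg_probs = array(ag_value(out$seg_probs),
                      dim = dim(ag_value(out$seg_probs))[1:4]),
    gls = as.numeric(ag_value(out$gls)),
    lvef = as.numeric(ag_value(out$lvef)),
    gwe = as.numeric(ag_value(out$gwe)),
    gensini = as.numeric(ag_value(out$gensini)),
    cad_probs = as.numeric(ag_value(out$cad_probs))
  ), class = "network_output")
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, all parameter values and the
#' normalisation layers' running statistics, so a reloaded model
#' reproduces evaluation-mode outputs bit for bit.
#'
#' @param model An [iecad_model()].
#' @param path File path (RDS).
#' @export
save_iecad <- function(model, path) {
  bn_stats <- list()
  walk_bn <- function(layer, prefix) {
    if (inherits(layer, "nn_layer")) {
      if (!is.null(layer$running_mean)) {
        bn_stats[[prefix]] <<- list(mean = layer$running_mean,
                                    var = layer$running_var)
      }
      for (nm in names(layer$children)) {
        walk_bn(layer$children[[nm]], paste0(prefix, nm, "."))
      }
    } else if (is.list(layer)) {
      for (nm in names(layer)) walk_bn(layer[[nm]], paste0(prefix, nm, "."))
    }
  }
  walk_bn(model$layers, "")
  saveRDS(list(config = model$config,
               params = lapply(model$params, ag_value),
               bn = bn_stats), path)
  invisible(path)
}

#' @rdname save_iecad
#' @param path File path of a saved checkpoint.
#' @return The restored `iecad_model`.
#' @export
load_iecad <- function(path) {
  ck <- readRDS(path)
  model <- iecad_model(ck$config)
  for (nm in names(ck$params)) model$params[[nm]]$value <- ck$params[[nm]]
  restore_bn <- function(layer, prefix) {
    if (inherits(layer, "nn_layer")) {
      if (!is.null(layer$running_mean) && !is.null(ck$bn[[prefix]])) {
        layer$running_mean <- ck$bn[[prefix]]$mean
        layer$running_var <- ck$bn[[prefix]]$var
      }
      for (nm in names(layer$children)) {
        restore_bn(layer$children[[nm]], paste0(prefix, nm, "."))
      }
    } else if (is.list(layer)) {
      for (nm in names(layer)) restore_bn(layer[[nm]], paste0(prefix, nm, "."))
    }
  }
  restore_bn(model$layers, "")
  model
}
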