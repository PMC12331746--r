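# Losses and the three-phase training schedule: (1) view classification +
# segmentation, (2) GLS/LVEF/GWE regression, (3) Gensini-score + CAD
# classification with the shared backbone and the phase-1/2 heads frozen.
# Adam with weight decay, cosine-annealed learning rate re-warmed at the
# start of every phase, and parameter updates after every
# `grad_accumulation` batches.

#' Training configuration
#'
#' Defaults follow the published schedule: 30/30/90 epochs, initial
#' learning rate 2e-4, weight decay 1e-5, batch size 16 with an update
#' after every 3 gradient accumulations, cosine annealing re-warmed at
#' each phase.
#'
#' @param phase_epochs Epochs for the three phases.
#' @param lr Initial learning rate.
#' @param weight_decay L2 coefficient.
#' @param batch_size Clips per batch.
#' @param grad_accumulation Batches per optimizer update.
#' @param seed RNG seed for batching and initial state.
#' @param loss_weights Named per-task weights (all 1 by default).
#' @param joint_phase2 Also optimise the phase-1 losses during phase 2.
#' @param feature_noise Relative standard deviation of Gaussian noise
#'   added to the cached frozen features during phase 3 (feature-space
#'   augmentation; the frozen encoder precludes input-space
#'   augmentation). 0 disables.
#' @param warmup_frac Fraction of each phase's updates spent on linear
#'   warmup before the cosine decay.
#' @return A `train_config` list.
#' @export
train_config <- function(phase_epochs = c(30L, 30L, 90L), lr = 2e-4,
                         weight_decay = 1e-5, batch_size = 16L,
                         grad_accumulation = 3L, seed = 1L,
                         loss_weights = c(view = 1, seg = 1, gls = 1,
                                          lvef = 1, gwe = 1, gensini = 1,
                                          cad = 1),
                         joint_phase2 = FALSE, feature_noise = 0,
                         warmup_frac = 0.05) {
  stopifnot(all(phase_epochs >= 1L), lr > 0, grad_accumulation >= 1L,
            batch_size >= 1L)
  structure(list(
    phase_epochs = as.integer(phase_epochs), lr = lr,
    weight_decay = weight_decay, batch_size = as.integer(batch_size),
    grad_accumulation = as.integer(grad_accumulation),
    seed = as.integer(seed), loss_weights = loss_weights,
    joint_phase2 = joint_phase2, feature_noise = feature_noise,
    warmup_frac = warmup_frac
  ), class = "train_config")
}

#' Cosine-annealed learning rate with per-phase re-warming
#'
#' @param update 1-based update index within the phase.
#' @param total_updates Updates in the phase.
#' @param lr_max Peak learning rate.
#' @param warmup_frac Warmup fraction.
#' @return Learning rate for this update.
#' @export
cosine_warmup_lr <- function(update, total_updates, lr_max,
                             warmup_frac = 0.05) {
  n_w <- max(1L, floor(warmup_frac * total_updates))
  if (update <= n_w) return(lr_max * update / n_w)
  prog <- (update - n_w) / max(1L, total_updates - n_w)
  0.5 * lr_max * (1 + cos(pi * min(1, prog)))
}

# ---- samples & batches -----------------------------------------------------

#' Flatten a cohort into per-clip training samples
#'
#' One sample per (subject, view): the clip, its view index, the mask
#' block, and the subject's target curves and scalars.
#'
#' @param cohort List of `subject_record` with rendered clips.
#' @return List of samples.
#' @export
cohort_samples <- function(cohort) {
  out <- list()
  for (rec in cohort) {
    if (is.null(rec$views[[1]])) stop("cohort must be rendered for training")
    for (v in seq_along(rec$view_labels)) {
      nm <- rec$view_labels[v]
      out[[length(out) + 1L]] <- list(
        subject = rec$id, clip = rec$views[[nm]], mask = rec$masks[[nm]],
        view = v, strain = rec$strain, ef = rec$ef,
        gwe = if (is.na(rec$gwe)) 100 else rec$gwe,
        gensini = rec$gensini, cad = as.integer(rec$significant) + 1L
      )
    }
  }
  out
}

make_batch <- function(samples, config_model) {
  n <- length(samples)
  s <- config_model$input_size
  tf <- config_model$n_frames
  x <- array(0, dim = c(s, s, tf, 1L, n))
  seg <- array(1L, dim = c(s, s, tf, n))
  view <- integer(n); cad <- integer(n)
  gls <- matrix(0, tf, n); lvef <- matrix(0, tf, n)
  gwe <- numeric(n); gensini <- numeric(n)
  for (i in seq_len(n)) {
    sm <- samples[[i]]
    x[, , , 1L, i] <- aperm(sm$clip, c(2, 3, 1))
    seg[, , , i] <- aperm(sm$mask, c(2, 3, 1)) + 1L
    view[i] <- sm$view; cad[i] <- sm$cad
    gls[, i] <- sm$strain; lvef[, i] <- sm$ef
    gwe[i] <- sm$gwe; gensini[i] <- sm$gensini
  }
  list(x = x, seg = seg, view = view, cad = cad, gls = gls, lvef = lvef,
       gwe = gwe, gensini = gensini)
}

seg_to_matrix <- function(t5) {
  d <- dim(ag_value(t5))
  ag_reshape(ag_aperm(t5, c(1L, 2L, 3L, 5L, 4L)),
             c(prod(d[c(1, 2, 3, 5)]), d[4]))
}

#' Per-task losses for one batch
#'
#' View loss: 3-class cross-entropy. Segmentation: cross-entropy plus
#' soft Dice loss on the softmax probabilities. GLS/LVEF curves and
#' GWE/Gensini scalars: mean squared error. CAD: 2-class cross-entropy.
#'
#' @param out Output list from [iecad_forward()].
#' @param batch Target batch from the internal batch builder (fields
#'   `view`, `seg`, `gls`, `lvef`, `gwe`, `gensini`, `cad`).
#' @return Named list of scalar loss tensors (only the tasks present in
#'   `out`).
#' @export
task_losses <- function(out, batch) {
  losses <- list()
  if (!is.null(out$view_logits)) {
    losses$view <- ag_ce_logits(out$view_logits, batch$view)
  }
  if (!is.null(out$seg_logits)) {
    lab <- as.integer(batch$seg)
    logit_m <- seg_to_matrix(out$seg_logits)
    losses$seg_ce <- ag_ce_logits(logit_m, lab)
    onehot <- matrix(0, length(lab), 3L)
    onehot[cbind(seq_along(lab), lab)] <- 1
    losses$seg_dice <- ag_dice_loss(ag_softmax(logit_m, 2L), onehot)
  }
  if (!is.null(out$gls)) {
    losses$gls <- ag_mse(out$gls, batch$gls)
    losses$lvef <- ag_mse(out$lvef, batch$lvef)
    losses$gwe <- ag_mse(out$gwe, batch$gwe)
  }
  if (!is.null(out$gensini)) {
    losses$gensini <- ag_mse(out$gensini, batch$gensini)
    losses$cad <- ag_ce_logits(out$cad_logits, batch$cad)
  }
  losses
}

weighted_total <- function(losses, weights) {
  total <- NULL
  for (nm in names(losses)) {
    key <- if (nm %in% c("seg_ce", "seg_dice")) "seg" else nm
    w <- if (key %in% names(weights)) weights[[key]] else 1
    term <- ag_scale(losses[[nm]], w)
    total <- if (is.null(total)) term else ag_add(total, term)
  }
  total
}

phase_tasks <- function(phase, config) {
  switch(phase,
         c("view", "seg"),
         if (isTRUE(config$joint_phase2)) c("view", "seg", "metrics")
         else "metrics",
         "score")
}

# Cache frozen features for phase 3 (encoder + phase-1/2 low-rank experts
# run once in evaluation mode; their parameters and statistics stay
# fixed).
cache_frozen_features <- function(model, samples, batch_size) {
  L <- model$layers
  caches <- vector("list", length(samples))
  i <- 1L
  while (i <= length(samples)) {
    take <- seq(i, min(i + batch_size - 1L, length(samples)))
    b <- make_batch(samples[take], model$config)
    bun <- ag_no_grad({
      bu <- iecad_encode(model, b$x, training = FALSE)
      bu$sparse_gls <- L$lr_gls$forward(bu$deep, FALSE)
      bu$sparse_lvef <- L$lr_lvef$forward(bu$deep, FALSE)
      bu$sparse_gwe <- L$lr_gwe$forward(bu$deep, FALSE)
      bu
    })
    for (k in seq_along(take)) {
      caches[[take[k]]] <- lapply(
        bun[c("deep", "backbone", "sparse_gls", "sparse_lvef", "sparse_gwe",
              "lowlevel_ds")],
        function(t5) {
          v <- ag_value(t5)
          d <- dim(v)
          array(v[, , , , k], dim = c(d[1:4], 1L))
        })
    }
    i <- i + batch_size
  }
  caches
}

bind_cached <- function(caches, idx, noise_sd = 0) {
  nms <- names(caches[[1]])
  out <- list()
  for (nm in nms) {
    parts <- lapply(caches[idx], `[[`, nm)
    d <- dim(parts[[1]])
    arr <- array(0, dim = c(d[1:4], length(parts)))
    for (k in seq_along(parts)) arr[, , , , k] <- parts[[k]]
    if (noise_sd > 0) {
      arr <- arr + stats::rnorm(length(arr), sd = noise_sd * stats::sd(arr))
    }
    out[[nm]] <- ag_tensor(arr)
  }
  out
}

#' Run one training phase
#'
#' Phase 1 optimises the view and segmentation losses; phase 2 the
#' GLS/LVEF/GWE regression losses; phase 3 the Gensini and CAD losses
#' with the encoder and all phase-1/2 heads frozen (their features are
#' computed once in evaluation mode and reused). The learning rate is
#' re-warmed and cosine-annealed within the phase; parameters update
#' after every `grad_accumulation` batches.
#'
#' @param model An [iecad_model()].
#' @param samples Training samples from [cohort_samples()].
#' @param config A [train_config()].
#' @param phase 1, 2 or 3.
#' @return A `phase_state`: per-epoch mean losses, per-task traces,
#'   update count and the learning-rate trace.
#' @export
run_phase <- function(model, samples, config, phase) {
  stopifnot(phase %in% 1:3, length(samples) > 0L)
  tasks <- phase_tasks(phase, config)
  epochs <- config$phase_epochs[phase]
  bs <- config$batch_size
  n <- length(samples)
  batches_per_epoch <- ceiling(n / bs)
  total_updates <- max(1L, ceiling(epochs * batches_per_epoch /
                                     config$grad_accumulation))
  opt <- adam_optimizer(model$params, lr = config$lr,
                        weight_decay = config$weight_decay)
  caches <- NULL
  if (phase == 3L) {
    caches <- cache_frozen_features(model, samples, bs)
  }
  set.seed(config$seed + 7919L * phase)
  epoch_losses <- numeric(epochs)
  task_hist <- list()
  lr_hist <- numeric(0)
  update <- 0L
  accum <- 0L
  refresh_stats <- function() {
    # forward-only pass refreshing normalisation running statistics
    # under the current parameters
    for (b0 in seq(1L, n, by = bs)) {
      idx <- seq(b0, min(b0 + bs - 1L, n))
      batch <- make_batch(samples[idx], model$config)
      if (phase == 3L) {
        bundle <- bind_cached(caches, idx)
        ag_no_grad(iecad_forward(model, NULL, tasks = tasks,
                                 training = TRUE, bundle = bundle))
      } else {
        ag_no_grad(iecad_forward(model, batch$x, tasks = tasks,
                                 training = TRUE))
      }
    }
  }
  for (ep in seq_len(epochs)) {
    # the final epoch trains against frozen (running) normalisation
    # statistics -- refreshed beforehand -- so the heads converge on the
    # exact feature distribution evaluation mode will produce
    final_ep <- ep == epochs && epochs > 1L
    if (final_ep) refresh_stats()
    ord <- sample.int(n)
    ep_loss <- 0
    ep_terms <- NULL
    for (b0 in seq(1L, n, by = bs)) {
      idx <- ord[seq(b0, min(b0 + bs - 1L, n))]
      batch <- make_batch(samples[idx], model$config)
      if (phase == 3L) {
        bundle <- bind_cached(caches, idx, config$feature_noise)
        out <- iecad_forward(model, NULL, tasks = tasks,
                             training = !final_ep, bundle = bundle)
      } else {
        out <- iecad_forward(model, batch$x, tasks = tasks,
                             training = !final_ep)
      }
      losses <- task_losses(out, batch)
      total <- weighted_total(losses, config$loss_weights)
      tv <- ag_value(total)
      if (!is.finite(tv)) {
        stop("non-finite loss in phase ", phase, " epoch ", ep, " (",
             paste(sprintf("%s=%.3g", names(losses),
                           vapply(losses, ag_value, numeric(1))),
                   collapse = ", "), ")")
      }
      ag_backward(ag_scale(total, 1 / config$grad_accumulation))
      accum <- accum + 1L
      if (accum == config$grad_accumulation) {
        update <- update + 1L
        lr_u <- cosine_warmup_lr(update, total_updates, config$lr,
                                 config$warmup_frac)
        lr_hist <- c(lr_hist, lr_u)
        adam_step(opt, lr = lr_u)
        ag_zero_grad(model$params)
        accum <- 0L
      }
      ep_loss <- ep_loss + tv
      term_vals <- vapply(losses, ag_value, numeric(1))
      ep_terms <- if (is.null(ep_terms)) term_vals else ep_terms + term_vals
    }
    if (accum > 0L) { # flush a trailing partial accumulation
      update <- update + 1L
      lr_u <- cosine_warmup_lr(update, total_updates, config$lr,
                               config$warmup_frac)
      lr_hist <- c(lr_hist, lr_u)
      adam_step(opt, lr = lr_u)
      ag_zero_grad(model$params)
      accum <- 0L
    }
    epoch_losses[ep] <- ep_loss / batches_per_epoch
    task_hist[[ep]] <- ep_terms / batches_per_epoch
  }
  if (epochs == 1L) refresh_stats()
  structure(list(
    phase = phase, tasks = tasks, epoch_losses = epoch_losses,
    task_history = do.call(rbind, task_hist), n_updates = update,
    lr_history = lr_hist
  ), class = "phase_state")
}

#' Stratified subject-level train/test split
#'
#' Splits subjects (never individual views) with stratification on the
#' (significant, severe) label pair: each stratum contributes
#' `floor(n_k * (1 - ratio))` subjects to the test set. The resulting
#' label distributions are screened with a chi-squared test (p > 0.1
#' required for both labels) and the split is redrawn up to
#' `max_attempts` times otherwise.
#'
#' @param records List of `subject_record` (or a data frame with logical
#'   columns `significant` and `severe`).
#' @param ratio Training fraction (default 0.8).
#' @param seed RNG seed.
#' @param max_attempts Redraw bound for the balance screen.
#' @return List with `train_idx`, `test_idx` and (for record input)
#'   `train`, `test`.
#' @export
split_cohort <- function(records, ratio = 0.8, seed = 1L,
                         max_attempts = 100L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  if (is.data.frame(records)) {
    labs <- records
    recs <- NULL
  } else {
    labs <- data.frame(
      significant = vapply(records, `[[`, logical(1), "significant"),
      severe = vapply(records, `[[`, logical(1), "severe"))
    recs <- records
  }
  n <- nrow(labs)
  strata <- interaction(labs$significant, labs$severe, drop = TRUE)
  if (n < 2L * nlevels(strata)) stop("cohort too small to stratify")
  balance_ok <- function(test_idx) {
    tr <- setdiff(seq_len(n), test_idx)
    for (col in c("significant", "severe")) {
      tab <- table(factor(c(rep("train", length(tr)),
                            rep("test", length(test_idx))),
                          levels = c("train", "test")),
                   c(labs[[col]][tr], labs[[col]][test_idx]))
      if (any(dim(tab) < 2L)) next # label constant: trivially matched
      p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      if (!is.na(p) && p <= 0.1) return(FALSE)
    }
    TRUE
  }
  test_idx <- run_seeded(seed, {
    for (attempt in seq_len(max_attempts)) {
      ti <- integer(0)
      for (lev in levels(strata)) {
        members <- which(strata == lev)
        k <- floor(length(members) * (1 - ratio) + 1e-9)
        if (k > 0L) ti <- c(ti, sample(members, k))
      }
      if (balance_ok(ti)) break
    }
    sort(ti)
  })
  out <- list(train_idx = setdiff(seq_len(n), test_idx),
              test_idx = test_idx)
  if (!is.null(recs)) {
    out$train <- recs[out$train_idx]
    out$test <- recs[out$test_idx]
  }
  out
}

#' Evaluate a model on a cohort of subjects
#'
#' Runs each subject's three views through the network in evaluation
#' mode, aggregates with the max-over-views rule, and returns per-subject
#' truth and predictions plus per-view view-classification calls.
#'
#' @param model An [iecad_model()].
#' @param records List of rendered `subject_record`.
#' @param severe_cutoff Severity cutoff (points).
#' @return Data frame with one row per subject.
#' @export
evaluate_cohort <- function(model, records, severe_cutoff = 15) {
  rows <- lapply(records, function(rec) {
    out <- ag_no_grad(iecad_forward(
      model, lapply(rec$view_labels, function(v) rec$views[[v]]),
      tasks = c("view", "metrics", "score"), training = FALSE))
    vp <- ag_value(out$view_probs)
    gens <- as.numeric(ag_value(out$gensini))
    cadp <- ag_value(out$cad_probs)
    agg <- aggregate_views(gens, cadp[, 2] >= cadp[, 1], severe_cutoff)
    data.frame(
      id = rec$id,
      view_correct = sum(max.col(vp) == seq_len(3)),
      pred_gensini = agg$gensini,
      pred_significant = agg$significant,
      pred_severe = agg$severe,
      score_significant = max(cadp[, 2]),
      true_gensini = rec$gensini,
      true_significant = rec$significant,
      true_severe = rec$severe,
      true_gls = rec$gls, true_lvef = rec$lvef,
      pred_gls = min(colMeans(t(ag_value(out$gls)))),
      pred_lvef = max(colMeans(t(ag_value(out$lvef))))
    )
  })
  do.call(rbind, rows)
}

#' Train the full three-phase schedule
#'
#' @param model An [iecad_model()].
#' @param cohort Rendered cohort from [make_cohort()].
#' @param config A [train_config()].
#' @param split Optional precomputed [split_cohort()] result.
#' @return List with the trained `model`, `phases` (three `phase_state`),
#'   the `split`, and the `test_report` from [evaluate_cohort()].
#' @export
train_iecad <- function(model, cohort, config = train_config(),
                        split = NULL) {
  if (is.null(split)) split <- split_cohort(cohort, 0.8, seed = config$seed)
  train_samples <- cohort_samples(split$train)
  phases <- vector("list", 3L)
  for (ph in 1:3) {
    phases[[ph]] <- run_phase(model, train_samples, config, ph)
  }
  report <- evaluate_cohort(model, split$test)
  list(model = model, phases = phases, split = split,
       test_report = report)
}
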