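# Evaluation metrics: Dice, MAE, Pearson correlation, ROC/AUC,
# confusion-matrix rates, and subject-level percentile-bootstrap
# confidence intervals.

#' Dice overlap coefficient
#'
#' 2|A n B| / (|A| + |B|) between two binary masks on the same grid; the
#' overlap of two empty masks is defined as 1.
#'
#' @param pred,truth Logical/0-1 arrays of identical dimensions.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("mask grids differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"))
  }
  a <- as.logical(pred); b <- as.logical(truth)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Mean absolute error
#' @param pred,truth Numeric vectors of equal length.
#' @return Mean of |pred - truth|.
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) == 0L) stop("empty input")
  mean(abs(pred - truth))
}

#' Pearson correlation coefficient
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Product-moment correlation.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  stats::cor(x, y)
}

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half (Mann-Whitney U normalisation).
#'
#' @param scores Continuous scores.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix classification report
#'
#' Accuracy, precision, sensitivity, specificity and F1 from binary
#' predictions. Ratios with a zero denominator are reported as `NA`
#' (undefined), not 0.
#'
#' @param pred,truth Binary vectors of equal length.
#' @return Data frame with columns `metric` and `value`.
#' @export
classification_report <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  p <- as.logical(pred); t_ <- as.logical(truth)
  tp <- sum(p & t_); fp <- sum(p & !t_); fn <- sum(!p & t_); tn <- sum(!p & !t_)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  prec <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  data.frame(
    metric = c("accuracy", "precision", "sensitivity", "specificity", "f1"),
    value = c(ratio(tp + tn, length(p)), prec, sens, spec, f1)
  )
}

#' Subject-level percentile bootstrap confidence interval
#'
#' Resamples subjects with replacement, recomputes the metric, and takes
#' the 2.5 / 97.5 percentiles. Resamples on which the metric is undefined
#' (e.g. a single-class draw for AUC) are skipped and counted.
#'
#' @param metric_fn Function taking the resampled data object.
#' @param data A data frame (resampled by row) or list/vector (by element).
#' @param n_boot Number of bootstrap draws (>= 100).
#' @param seed RNG seed.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)` with attribute `skipped`.
#' @export
bootstrap_ci <- function(metric_fn, data, n_boot = 1000L, seed = 1L,
                         level = 0.95) {
  if (n_boot < 100L) stop("n_boot must be at least 100")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  vals <- run_seeded(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      sub <- if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
      tryCatch(metric_fn(sub), error = function(e) NA_real_)
    }, numeric(1))
  })
  skipped <- sum(is.na(vals))
  if (skipped == n_boot) stop("metric undefined on every resample")
  a <- (1 - level) / 2
  ci <- stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  structure(ci, skipped = skipped)
}

#' Metric report row
#'
#' @param name Metric name.
#' @param value Point estimate.
#' @param ci Optional `c(low, high)`.
#' @param n Number of observations.
#' @return One-row data frame (`metric`, `value`, `ci_low`, `ci_high`, `n`).
#' @export
metric_report <- function(name, value, ci = NULL, n = NA_integer_) {
  data.frame(metric = name, value = value,
             ci_low = if (is.null(ci)) NA_real_ else ci[1],
             ci_high = if (is.null(ci)) NA_real_ else ci[2],
             n = n)
}
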