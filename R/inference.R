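# Study-level inference: each apical view is evaluated independently and
# the per-view outputs are aggregated -- the final Gensini score is the
# maximum over views and the study is significant if any view says so,
# maximising sensitivity to view-dependent wall-motion cues.

#' Predict a study from its three apical views
#'
#' @param model An [iecad_model()].
#' @param views Named list with elements `A4C`, `A3C`, `A2C`, each a
#'   (T, H, W) video block. All three must be present.
#' @param severe_cutoff Gensini points at which CAD is graded severe.
#' @return A `study_prediction`: `per_view` (list of `network_output`),
#'   `gensini` (max over views), `significant` (OR over views), `severe`
#'   (final score >= cutoff), per-assignment continuous `scores`, and
#'   `assignments`.
#' @export
predict_study <- function(model, views, severe_cutoff = 15) {
  required <- c("A4C", "A3C", "A2C")
  missing <- setdiff(required, names(views))
  if (length(missing) > 0L) {
    stop("missing view(s): ", paste(missing, collapse = ", "))
  }
  per_view <- lapply(views[required], function(v) predict_block(model, v))
  scores_gensini <- vapply(per_view, function(o) o$gensini, numeric(1))
  sig_prob <- vapply(per_view, function(o) o$cad_probs[2], numeric(1))
  sig_flags <- vapply(per_view, function(o) o$cad_probs[2] >= o$cad_probs[1],
                      logical(1))
  final_gensini <- max(scores_gensini)
  final_significant <- any(sig_flags)
  final_severe <- final_gensini >= severe_cutoff
  p_sig <- max(sig_prob)
  # severity score mapped onto a probability-like scale (0.5 at the cutoff)
  p_sev <- final_gensini / (final_gensini + severe_cutoff)
  structure(list(
    per_view = per_view,
    gensini = final_gensini,
    significant = final_significant,
    severe = final_severe,
    scores = c(assignment1 = p_sig, assignment2 = final_gensini,
               assignment3 = max(p_sig, p_sev),
               assignment4 = min(p_sig, p_sev)),
    assignments = cad_label(final_significant, final_severe)
  ), class = "study_prediction")
}

#' Composite CAD assignments from a study prediction
#'
#' @param pred A `study_prediction` (or anything with `significant` and
#'   `severe` flags).
#' @return A [cad_label()].
#' @export
assignments <- function(pred) {
  cad_label(pred$significant, pred$severe)
}

#' Aggregate already-computed per-view outputs
#'
#' The pure aggregation rule, separated from the network forward pass:
#' max over views for the score, OR over views for significance.
#'
#' @param gensini_scores Numeric per-view Gensini predictions.
#' @param significant_flags Logical per-view significance calls.
#' @param severe_cutoff Severity cutoff in points.
#' @return List with `gensini`, `significant`, `severe`, `assignments`.
#' @export
aggregate_views <- function(gensini_scores, significant_flags,
                            severe_cutoff = 15) {
  if (length(gensini_scores) < 1L) stop("no views")
  g <- max(gensini_scores)
  s <- any(significant_flags)
  list(gensini = g, significant = s, severe = g >= severe_cutoff,
       assignments = cad_label(s, g >= severe_cutoff))
}
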