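#' @useDynLib iecad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Coronary segment identifiers
#'
#' The coronary tree segments recognised by the Gensini scorer, grouped by
#' the territory they perfuse (left anterior descending, left circumflex,
#' right coronary artery; the left main contributes to both left
#' territories).
#'
#' @format Character vector of segment ids.
#' @export
coronary_segments <- c(
  "LM",
  "LAD_prox", "LAD_mid", "LAD_dist", "D1", "D2",
  "LCx_prox", "OM", "LCx_dist", "PLB",
  "RCA_prox", "RCA_mid", "RCA_dist", "PDA"
)

#' Default Gensini configuration
#'
#' Severity points per stenosis bin (right-closed bins at 25/50/75/90/99%
#' plus total occlusion) and location multipliers for each coronary
#' segment, following the classic Gensini system. Both tables can be
#' overridden; the collateral adjustment (a total or near-total occlusion
#' with collateral flow is demoted to the 90% bin) can be disabled.
#'
#' @param severe_cutoff Gensini score at and above which CAD is graded
#'   severe (points; default 15).
#' @param collateral_adjustment If `TRUE` (default), a lesion with
#'   stenosis >= `collateral_floor` and the collateral flag set is scored
#'   in the 90% bin.
#' @param collateral_floor Stenosis percentage from which a lesion counts
#'   as near-total for the collateral adjustment (default 99).
#' @return A list with elements `breaks`, `points`, `multipliers`,
#'   `severe_cutoff`, `collateral_adjustment`, `collateral_floor`.
#' @export
gensini_config <- function(severe_cutoff = 15,
                           collateral_adjustment = TRUE,
                           collateral_floor = 99) {
  multipliers <- c(
    LM = 5,
    LAD_prox = 2.5, LCx_prox = 2.5,
    LAD_mid = 1.5,
    LAD_dist = 1, D1 = 1, OM = 1, LCx_dist = 1,
    RCA_prox = 1, RCA_mid = 1, RCA_dist = 1, PDA = 1,
    D2 = 0.5, PLB = 0.5
  )
  list(
    breaks = c(25, 50, 75, 90, 99, 100), # right-closed upper edges
    points = c(1, 2, 4, 8, 16, 32),
    multipliers = multipliers,
    severe_cutoff = severe_cutoff,
    collateral_adjustment = collateral_adjustment,
    collateral_floor = collateral_floor
  )
}

#' Construct a coronary lesion
#'
#' @param segment Segment id, one of [coronary_segments].
#' @param stenosis Percent luminal narrowing in \[0, 100\].
#' @param collaterals Logical; collateral flow present (meaningful for
#'   total or near-total occlusions only).
#' @return A `coronary_lesion` object.
#' @export
coronary_lesion <- function(segment, stenosis, collaterals = FALSE) {
  if (!is.character(segment) || length(segment) != 1L ||
      !(segment %in% coronary_segments)) {
    stop("unknown coronary segment id: ", paste(segment, collapse = ", "))
  }
  if (!is.numeric(stenosis) || length(stenosis) != 1L ||
      is.na(stenosis) || stenosis < 0 || stenosis > 100) {
    stop("stenosis must be a single value in [0, 100]")
  }
  structure(
    list(segment = segment, stenosis = as.numeric(stenosis),
         collaterals = isTRUE(collaterals)),
    class = "coronary_lesion"
  )
}

severity_points <- function(stenosis, config) {
  if (stenosis <= 0) return(0)
  bin <- findInterval(stenosis, config$breaks, left.open = TRUE) + 1L
  bin <- min(bin, length(config$points))
  config$points[bin]
}

#' Modified Gensini score
#'
#' Each lesion contributes severity points (by stenosis bin) times the
#' segment location multiplier; contributions are summed over lesions.
#' Near-total or total occlusions with collateral flow are demoted to the
#' 90% bin when the collateral adjustment is enabled.
#'
#' @param lesions List of [coronary_lesion] objects (possibly empty).
#' @param config Scoring tables from [gensini_config()].
#' @return A `gensini_result`: list with `total`, per-lesion
#'   `contributions`, and the `severe` flag (total >= cutoff).
#' @examples
#' gensini_score(list(coronary_lesion("LM", 100)))$total  # 160
#' @export
gensini_score <- function(lesions = list(), config = gensini_config()) {
  lesions <- as_lesion_list(lesions)
  contributions <- vapply(lesions, function(l) {
    sten <- l$stenosis
    if (config$collateral_adjustment && l$collaterals &&
        sten >= config$collateral_floor) {
      sten <- 90
    }
    mult <- config$multipliers[[l$segment]]
    severity_points(sten, config) * mult
  }, numeric(1))
  total <- sum(contributions)
  structure(
    list(total = total, contributions = contributions,
         severe = total >= config$severe_cutoff),
    class = "gensini_result"
  )
}

#' @export
print.gensini_result <- function(x, ...) {
  cat(sprintf("Gensini score: %g points (%s)\n", x$total,
              if (x$severe) "severe CAD" else "not severe"))
  invisible(x)
}

as_lesion_list <- function(lesions) {
  if (inherits(lesions, "coronary_lesion")) lesions <- list(lesions)
  if (!is.list(lesions)) stop("lesions must be a list of coronary_lesion")
  lapply(lesions, function(l) {
    if (!inherits(l, "coronary_lesion")) {
      l <- coronary_lesion(l$segment, l$stenosis, isTRUE(l$collaterals))
    }
    l
  })
}

#' Significant CAD rule
#'
#' A study is significant CAD when any left-main lesion reaches 50%
#' stenosis or any non-left-main lesion reaches 70%.
#'
#' @inheritParams gensini_score
#' @param lm_threshold Left-main stenosis threshold (%; default 50).
#' @param other_threshold Non-left-main threshold (%; default 70).
#' @return Logical.
#' @export
classify_significant <- function(lesions = list(), lm_threshold = 50,
                                 other_threshold = 70) {
  lesions <- as_lesion_list(lesions)
  any(vapply(lesions, function(l) {
    if (l$segment == "LM") l$stenosis >= lm_threshold
    else l$stenosis >= other_threshold
  }, logical(1)))
}

#' Severe CAD rule
#'
#' @param score Gensini score in points.
#' @param cutoff Severity cutoff (points; default 15).
#' @return Logical; `TRUE` when `score >= cutoff`.
#' @export
classify_severe <- function(score, cutoff = 15) {
  stopifnot(is.numeric(score))
  score >= cutoff
}

#' CAD label with composite assignments
#'
#' Assignment 1 detects significant CAD, assignment 2 severe CAD,
#' assignment 3 cases that are significant or severe but not both
#' (exclusive or), and assignment 4 cases that are both.
#'
#' @param significant,severe Logical flags.
#' @return A `cad_label` list with `significant`, `severe`,
#'   `assignment1`..`assignment4`.
#' @export
cad_label <- function(significant, severe) {
  significant <- isTRUE(significant)
  severe <- isTRUE(severe)
  structure(
    list(
      significant = significant, severe = severe,
      assignment1 = significant,
      assignment2 = severe,
      assignment3 = xor(significant, severe),
      assignment4 = significant && severe
    ),
    class = "cad_label"
  )
}

#' Biplane Simpson (method of disks) left-ventricular volume
#'
#' The cavity is cut into `n` elliptical disks perpendicular to the long
#' axis; each disk's orthogonal diameters come from the two apical views:
#' V = (pi/4) (L/n) sum_i a_i b_i.
#'
#' @param a4c_diameters,a2c_diameters Per-disk cavity diameters from the
#'   two orthogonal apical views (mm), apex to base, equal lengths.
#' @param long_axis Long-axis length L (mm).
#' @return Volume in mL.
#' @examples
#' simpson_biplane_volume(rep(40, 20), rep(40, 20), 80) # cylinder
#' @export
simpson_biplane_volume <- function(a4c_diameters, a2c_diameters, long_axis) {
  if (length(a4c_diameters) != length(a2c_diameters)) {
    stop("disk counts differ between views: ", length(a4c_diameters),
         " vs ", length(a2c_diameters))
  }
  n <- length(a4c_diameters)
  if (n < 1L) stop("need at least one disk")
  if (any(a4c_diameters < 0) || any(a2c_diameters < 0)) {
    stop("diameters must be non-negative")
  }
  if (!is.numeric(long_axis) || long_axis < 0) stop("invalid long axis")
  v_mm3 <- (pi / 4) * (long_axis / n) * sum(a4c_diameters * a2c_diameters)
  v_mm3 / 1000
}

#' Ejection-fraction curve
#'
#' Per-frame ejected fraction relative to the first (end-diastolic) frame:
#' EF_t = 100 (V_0 - V_t) / V_0. The scalar LVEF is the curve maximum.
#'
#' @param volumes Per-frame cavity volumes, first entry end-diastole.
#' @return Numeric vector of EF values (%), same length.
#' @export
ef_curve <- function(volumes) {
  if (!is.numeric(volumes) || length(volumes) < 1L) stop("empty volumes")
  if (!(volumes[1] > 0)) stop("end-diastolic volume must be positive")
  100 * (volumes[1] - volumes) / volumes[1]
}

#' Longitudinal strain curve
#'
#' Per-frame Lagrangian strain of the myocardial midline contour relative
#' to end-diastole: strain_t = 100 (L_t - L_0) / L_0. Shortening gives
#' negative strain; GLS is the curve minimum.
#'
#' @param midline_lengths Per-frame midline contour lengths, first entry
#'   end-diastole.
#' @return Numeric vector of strain values (%), same length.
#' @export
strain_curve <- function(midline_lengths) {
  if (!is.numeric(midline_lengths) || length(midline_lengths) < 1L) {
    stop("empty lengths")
  }
  if (!(midline_lengths[1] > 0)) stop("end-diastolic length must be positive")
  100 * (midline_lengths - midline_lengths[1]) / midline_lengths[1]
}

#' Global work efficiency from a pressure-strain loop
#'
#' Over the systolic steps (frames 1..`es_index`), shortening under
#' pressure is constructive work and lengthening under pressure is wasted
#' work: CW = sum P max(-d strain, 0), WW = sum P max(d strain, 0), and
#' GWE = 100 CW / (CW + WW). The pressure of a step is the mean of its
#' endpoint pressures.
#'
#' @param strain Strain curve (%), one value per frame.
#' @param pressure Ventricular pressure curve (mmHg), same length,
#'   non-negative.
#' @param es_index End-systolic frame (1-based index into the curves;
#'   default 11, i.e. the 11th frame under the 0 = ED, 10 = ES phase
#'   convention).
#' @return GWE in percent, with attributes `cw` and `ww` (mmHg.%).
#' @export
gwe_from_loop <- function(strain, pressure, es_index = 11L) {
  if (length(strain) != length(pressure)) stop("curve lengths differ")
  if (any(pressure < 0)) stop("pressures must be non-negative")
  es_index <- as.integer(es_index)
  if (es_index < 2L || es_index > length(strain)) stop("invalid es_index")
  d <- diff(strain[seq_len(es_index)])
  p <- (pressure[seq_len(es_index - 1L)] + pressure[2:es_index]) / 2
  cw <- sum(p * pmax(-d, 0))
  ww <- sum(p * pmax(d, 0))
  if (cw + ww == 0) stop("undefined GWE: no work performed (CW + WW = 0)")
  structure(100 * cw / (cw + ww), cw = cw, ww = ww)
}

#' Global work efficiency over myocardial segments
#'
#' Aggregates segmental pressure-strain loops: GWE = 100 sum(CW_s) /
#' sum(CW_s + WW_s) over segments s, so regionally delayed or paradoxical
#' motion lowers the global efficiency even when the global strain curve
#' shortens monotonically.
#'
#' @param strain_matrix Segments x frames matrix of segmental strain (%).
#' @param pressure Pressure curve (mmHg), length = number of frames.
#' @inheritParams gwe_from_loop
#' @return GWE in percent.
#' @export
gwe_segments <- function(strain_matrix, pressure, es_index = 11L) {
  strain_matrix <- as.matrix(strain_matrix)
  cw <- 0
  ww <- 0
  for (s in seq_len(nrow(strain_matrix))) {
    g <- gwe_from_loop(strain_matrix[s, ], pressure, es_index)
    cw <- cw + attr(g, "cw")
    ww <- ww + attr(g, "ww")
  }
  100 * cw / (cw + ww)
}

#' Default synthetic left-ventricular pressure waveform
#'
#' A smooth systolic pressure rise-and-fall over the 20-frame cycle,
#' peaking near end-systole; used when computing work efficiency for
#' phantom subjects.
#'
#' @param n_frames Number of frames (default 20).
#' @param peak Peak systolic pressure (mmHg; default 120).
#' @param diastolic Baseline diastolic pressure (mmHg; default 10).
#' @return Numeric pressure curve (mmHg).
#' @export
lv_pressure_curve <- function(n_frames = 20L, peak = 120, diastolic = 10) {
  t <- seq_len(n_frames) - 1L
  phase <- sin(pi * t / n_frames)^2
  diastolic + (peak - diastolic) * phase
}
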