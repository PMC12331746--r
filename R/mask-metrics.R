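# Recover functional metrics from segmentation masks: per-frame cavity
# disk diameters and long axis from the ventricle class, midline length
# from the myocardium annulus, then volumes via biplane Simpson and the
# standard EF / strain curves.

frame_cavity_geometry <- function(mask_frame, n_disks = 20L) {
  idx <- which(mask_frame == 2L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  ctr <- colMeans(idx)
  cen <- sweep(idx, 2L, ctr)
  ev <- eigen(stats::cov(cen), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  if (axis[1] < 0) axis <- -axis # orient apex -> base consistently
  proj <- cen %*% axis
  long_axis <- diff(range(proj))
  edges <- seq(min(proj), max(proj), length.out = n_disks + 1L)
  thickness <- diff(edges)[1]
  bin <- pmin(pmax(findInterval(proj, edges, rightmost.closed = TRUE), 1L),
              n_disks)
  counts <- tabulate(bin, nbins = n_disks)
  diameters <- counts / thickness # slice area / slice thickness
  list(diameters = diameters, long_axis = long_axis, centroid = ctr)
}

frame_midline_length <- function(mask_frame, centroid, n_bins = 72L) {
  idx <- which(mask_frame == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  cen <- sweep(idx, 2L, centroid)
  ang <- atan2(cen[, 2], cen[, 1])
  rad <- sqrt(rowSums(cen^2))
  bin <- pmin(floor((ang + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  r_mid <- rep(NA_real_, n_bins)
  agg <- tapply(rad, bin, mean)
  r_mid[as.integer(names(agg))] <- agg
  if (sum(is.na(r_mid)) > n_bins / 5) return(NULL)
  if (anyNA(r_mid)) { # fill sparse bins from angular neighbours
    filled <- stats::approx(which(!is.na(r_mid)), r_mid[!is.na(r_mid)],
                            xout = seq_len(n_bins), rule = 2)$y
    r_mid <- filled
  }
  th <- (seq_len(n_bins) - 0.5) / n_bins * 2 * pi - pi
  polygon_perimeter(r_mid * cos(th), r_mid * sin(th))
}

#' Functional metrics from an A4C + A2C mask pair
#'
#' Extracts per-frame cavity disk diameters and the long axis from the
#' ventricle class (label 2), midline contour length from the myocardium
#' annulus (label 1), then computes volumes by biplane Simpson and the
#' EF / strain curves.
#'
#' @param mask_a4c,mask_a2c (T, H, W) mask blocks with labels
#'   \{0, 1, 2\}.
#' @param n_disks Simpson disk count (default 20).
#' @return List with `volumes`, `ef`, `strain`, `lvef`, `gls`,
#'   `midline`.
#' @export
metrics_from_masks <- function(mask_a4c, mask_a2c, n_disks = 20L) {
  d <- dim(mask_a4c)
  if (!identical(d, dim(mask_a2c))) stop("mask grids differ between views")
  n_frames <- d[1]
  volumes <- numeric(n_frames)
  midline <- numeric(n_frames)
  for (t in seq_len(n_frames)) {
    g4 <- frame_cavity_geometry(mask_a4c[t, , ], n_disks)
    g2 <- frame_cavity_geometry(mask_a2c[t, , ], n_disks)
    if (is.null(g4) || is.null(g2)) {
      stop("empty ventricle region in frame ", t)
    }
    L <- (g4$long_axis + g2$long_axis) / 2
    volumes[t] <- simpson_biplane_volume(g4$diameters, g2$diameters, L)
    m4 <- frame_midline_length(mask_a4c[t, , ], g4$centroid)
    m2 <- frame_midline_length(mask_a2c[t, , ], g2$centroid)
    if (is.null(m4) || is.null(m2)) {
      stop("empty myocardium region in frame ", t)
    }
    midline[t] <- (m4 + m2) / 2
  }
  ef <- ef_curve(volumes)
  strain <- strain_curve(midline)
  list(volumes = volumes, ef = ef, strain = strain,
       lvef = max(ef), gls = min(strain), midline = midline)
}
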