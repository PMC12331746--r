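# Synthetic beating-heart phantom: an annular left ventricle (myocardium
# around an elliptical cavity) contracting through a 20-frame cardiac
# cycle, rendered in three apical views with ultrasound-like speckle and
# sector geometry. All ground-truth labels (strain / EF curves, GLS, LVEF,
# GWE, Gensini, CAD flags) are computed analytically from the generating
# geometry, never from the rendered pixels.

run_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Cycle phase: 0 at end-diastole (frame 0), 1 at end-systole (frame 10),
# periodic with period 20 so regional activation delays wrap.
phase_fn <- function(t) sin(pi * t / 20)^2

territory_names <- c("LAD", "LCx", "RCA")

# Smooth angular membership of the three coronary territories
# (von-Mises-like bumps, normalised to sum to 1 at every angle).
territory_weights <- function(theta, kappa = 2) {
  centers <- c(LAD = 0, LCx = 2 * pi / 3, RCA = -2 * pi / 3)
  w <- sapply(centers, function(mu) exp(kappa * cos(theta - mu)))
  w / rowSums(w)
}

default_view_rotations <- c(A4C = 0, A3C = 40, A2C = -20)

#' Create a beating-heart phantom
#'
#' Draws phantom anatomy (cavity semi-axes, wall thickness, ejection
#' amplitude, view rotations) from documented uniform ranges and scales
#' the contractility of one coronary territory down with `disease_level`
#' (0 = healthy, 1 = the documented floor of 0.3).
#'
#' @param rng_seed Non-negative integer seed; identical seeds give
#'   identical phantoms.
#' @param disease_level Fraction in \[0, 1\].
#' @return A `heart_phantom` list: `a0`, `b0` (cavity semi-axes at ED,
#'   pixels in the 256-pixel frame), `h0` (wall thickness at ED),
#'   `alpha` (ejection amplitude), `contractility` (named LAD/LCx/RCA),
#'   `center`, `view_rotations` (degrees), `delay_max` (frames),
#'   `thickening`.
#' @export
make_phantom <- function(rng_seed, disease_level = 0) {
  if (!is.numeric(rng_seed) || rng_seed < 0) stop("seed must be non-negative")
  if (!is.numeric(disease_level) || is.na(disease_level) ||
      disease_level < 0 || disease_level > 1) {
    stop("disease_level must be in [0, 1]")
  }
  run_seeded(as.integer(rng_seed), {
    a0 <- runif(1, 70, 90)
    b0 <- runif(1, 42, 56)
    h0 <- runif(1, 12, 18)
    alpha <- runif(1, 0.22, 0.32)
    center <- c(row = 136 + runif(1, -4, 4), col = 128 + runif(1, -4, 4))
    rot <- default_view_rotations + runif(3, -5, 5)
    u <- runif(3)
    contract <- rep(1, 3)
    names(contract) <- territory_names
    floor_c <- 0.3
    primary <- which.max(u)
    spread <- 0.35 * u / max(u) # secondary territories partially involved
    spread[primary] <- 1
    contract <- pmax(floor_c, 1 - disease_level * (1 - floor_c) * spread)
    structure(list(
      a0 = a0, b0 = b0, h0 = h0, alpha = alpha,
      contractility = contract,
      center = center, view_rotations = rot,
      delay_max = 4, thickening = 1.4, bulge = 0.35,
      disease_level = disease_level, seed = as.integer(rng_seed)
    ), class = "heart_phantom")
  })
}

validate_phantom <- function(p) {
  stopifnot(inherits(p, "heart_phantom"),
            p$a0 > p$h0, p$h0 > 0, p$b0 > p$h0,
            p$alpha >= 0, p$alpha < 1,
            all(p$contractility >= 0), all(p$contractility <= 1))
  invisible(p)
}

# Cavity / outer / midline radii at angles `theta` (radians from the apex
# direction) and frame t. Regional contraction is scaled by the territory
# contractility; diseased territories activate late (delay proportional
# to 1 - contractility) and bulge passively outward while the healthy
# wall squeezes (systolic stretch of ischaemic segments). Wall
# thickening scales with the ejection amplitude so a motionless phantom
# (alpha = 0) is truly motionless.
phantom_radii <- function(phantom, theta, t) {
  w <- territory_weights(theta)
  cc <- as.numeric(w %*% phantom$contractility)
  delay <- phantom$delay_max * (1 - cc)
  phi <- phase_fn(t - delay)
  phi_glob <- phase_fn(t)
  r0 <- phantom$a0 * phantom$b0 /
    sqrt((phantom$b0 * cos(theta))^2 + (phantom$a0 * sin(theta))^2)
  bulge <- if (is.null(phantom$bulge)) 0 else phantom$bulge
  r_cav <- r0 * (1 - phantom$alpha * (phi * cc - bulge * (1 - cc) * phi_glob))
  h <- phantom$h0 * (1 + phantom$thickening * phantom$alpha * phi * cc)
  list(cav = r_cav, out = r_cav + h, mid = r_cav + h / 2)
}

polygon_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# Disk-summation volume of the cavity about the long (apex-base) axis.
disk_volume <- function(x, y, nbins = 80) {
  yr <- range(y)
  edges <- seq(yr[1], yr[2], length.out = nbins + 1L)
  dy <- diff(edges)[1]
  bin <- pmin(pmax(findInterval(y, edges, rightmost.closed = TRUE), 1L), nbins)
  wmax <- tapply(x, bin, max)
  wmin <- tapply(x, bin, min)
  widths <- numeric(nbins)
  widths[as.integer(names(wmax))] <- wmax - wmin
  sum((pi / 4) * widths^2 * dy)
}

# Grid-free ground truth for one phantom: midline lengths, segmental arc
# lengths, cavity volumes per frame.
phantom_geometry <- function(phantom, n_frames = 20L, ntheta = 1440L,
                             n_segments = 18L) {
  theta <- seq(-pi, pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  seg_id <- rep(seq_len(n_segments), each = ntheta / n_segments)
  midline <- numeric(n_frames)
  volumes <- numeric(n_frames)
  seg_len <- matrix(0, n_segments, n_frames)
  for (t in seq_len(n_frames) - 1L) {
    rr <- phantom_radii(phantom, theta, t)
    xm <- rr$mid * sin(theta); ym <- -rr$mid * cos(theta)
    midline[t + 1L] <- polygon_perimeter(xm, ym)
    step <- sqrt(diff(c(xm, xm[1]))^2 + diff(c(ym, ym[1]))^2)
    seg_len[, t + 1L] <- tapply(step, seg_id, sum)
    xc <- rr$cav * sin(theta); yc <- -rr$cav * cos(theta)
    volumes[t + 1L] <- disk_volume(xc, yc)
  }
  list(midline = midline, volumes = volumes, seg_len = seg_len)
}

#' Sector polygon of the synthetic ultrasound field of view
#'
#' @param size Frame size in pixels.
#' @param half_angle Sector half-opening angle (degrees).
#' @return A k x 2 matrix of (row, col) vertices.
#' @export
sector_polygon <- function(size = 256L, half_angle = 38) {
  apex <- c(2, size / 2)
  radius <- 0.96 * size
  ang <- seq(-half_angle, half_angle, length.out = 33L) * pi / 180
  rbind(apex,
        cbind(apex[1] + radius * cos(ang), apex[2] + radius * sin(ang)))
}

sector_mask_pixels <- function(size, half_angle = 38) {
  apex <- c(2, size / 2)
  radius <- 0.96 * size
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  dr <- rows - apex[1]; dc <- cols - apex[2]
  ang <- atan2(dc, dr)
  (abs(ang) <= half_angle * pi / 180) & (sqrt(dr^2 + dc^2) <= radius) &
    (dr >= 0)
}

# Per-view visibility weighting of the myocardium (views favour the
# territories they image best).
view_visibility <- function(theta, view) {
  mu <- switch(view, A4C = pi / 2, A3C = -pi / 3, A2C = pi)
  0.8 + 0.2 * cos(theta - mu)
}

render_view_frames <- function(phantom, view, size, noise_seed,
                               n_frames = 20L) {
  scale <- size / 256
  rot <- phantom$view_rotations[[view]] * pi / 180
  cy <- phantom$center[["row"]] * scale
  cx <- phantom$center[["col"]] * scale
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  # rotate pixel offsets back into the heart frame
  xr <- cos(-rot) * dx - sin(-rot) * dy
  yr <- sin(-rot) * dx + cos(-rot) * dy
  theta <- atan2(xr, -yr) # 0 points toward the apex (up)
  rho <- sqrt(dx^2 + dy^2) / scale
  vis <- view_visibility(theta, view)
  sector <- sector_mask_pixels(size)
  video <- array(0, dim = c(n_frames, size, size))
  masks <- array(0L, dim = c(n_frames, size, size))
  th_vec <- as.numeric(theta)
  noise <- run_seeded(noise_seed, {
    half <- size %/% 2
    u <- array(runif(n_frames * half * half), c(half, half, n_frames))
    r <- sqrt(2 / pi) * sqrt(-2 * log(pmax(u, 1e-12)))
    big <- EBImage::resize(EBImage::Image(r), w = size, h = size)
    array(EBImage::imageData(big), c(size, size, n_frames))
  })
  for (t in seq_len(n_frames) - 1L) {
    rr <- phantom_radii(phantom, th_vec, t)
    cav <- rho <= matrix(rr$cav, size, size)
    myo <- !cav & (rho <= matrix(rr$out, size, size))
    m <- matrix(0L, size, size)
    m[myo] <- 1L
    m[cav] <- 2L
    masks[t + 1L, , ] <- m
    img <- matrix(0.03, size, size)
    img[cav] <- 0.06
    img[myo] <- (0.8 * vis)[myo]
    img <- img * noise[, , t + 1L]
    img[!sector] <- 0
    video[t + 1L, , ] <- pmin(pmax(img, 0), 1)
  }
  list(video = video, mask = masks)
}

#' Render a synthetic subject from a phantom
#'
#' Produces three apical-view cycle clips (20 x `size` x `size`,
#' intensities in \[0, 1\]) with pixel-exact 3-class masks (0 background,
#' 1 left myocardium, 2 left ventricle), plus analytically computed
#' strain / EF curves, GLS, LVEF, GWE, and Gensini-based CAD labels.
#'
#' @param phantom From [make_phantom()].
#' @param lesions List of [coronary_lesion]; scored for the Gensini /
#'   CAD labels.
#' @param noise_seed Seed for the speckle noise.
#' @param size Rendered frame size (default 256).
#' @param render If `FALSE`, skip rasterisation (labels and curves only).
#' @return A `subject_record`.
#' @export
render_subject <- function(phantom, lesions = list(), noise_seed = 0L,
                           size = 256L, render = TRUE) {
  validate_phantom(phantom)
  lesions <- as_lesion_list(lesions)
  geom <- phantom_geometry(phantom)
  strain <- strain_curve(geom$midline)
  ef <- ef_curve(geom$volumes)
  seg_strain <- 100 * sweep(geom$seg_len, 1L, geom$seg_len[, 1L], `/`) - 100
  pressure <- lv_pressure_curve(length(strain))
  gwe <- if (max(abs(seg_strain)) < 1e-9) NA_real_ else
    gwe_segments(seg_strain, pressure, es_index = 11L)
  gres <- gensini_score(lesions)
  significant <- classify_significant(lesions)
  views <- names(default_view_rotations)
  clips <- masks <- stats::setNames(vector("list", 3L), views)
  if (render) {
    for (i in seq_along(views)) {
      rv <- render_view_frames(phantom, views[i], size,
                               noise_seed + 101L * i)
      clips[[i]] <- rv$video
      masks[[i]] <- rv$mask
    }
  }
  structure(list(
    id = sprintf("S%06d", phantom$seed),
    views = clips, masks = masks, view_labels = views,
    strain = strain, ef = ef,
    gls = min(strain), lvef = max(ef), gwe = gwe,
    lesions = lesions, gensini = gres$total,
    significant = significant, severe = gres$severe,
    phantom = phantom
  ), class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf(
    "<subject_record %s> GLS %.1f%%, LVEF %.1f%%, GWE %s, Gensini %.1f (%s%s)\n",
    x$id, x$gls, x$lvef,
    if (is.na(x$gwe)) "NA" else sprintf("%.1f%%", x$gwe),
    x$gensini,
    if (x$significant) "significant" else "non-significant",
    if (x$severe) ", severe" else ""
  ))
  invisible(x)
}

segment_territories <- function(segment) {
  switch(segment,
         LM = c("LAD", "LCx"),
         LAD_prox = , LAD_mid = , LAD_dist = , D1 = , D2 = "LAD",
         LCx_prox = , OM = , LCx_dist = "LCx",
         RCA_prox = , RCA_mid = , RCA_dist = , PDA = , PLB = "RCA",
         stop("unknown segment ", segment))
}

#' Territory contractility implied by a lesion set
#'
#' Each coronary territory's contractility falls with its share of the
#' Gensini burden, with every lesion's contribution weighted by a
#' flow-limitation factor (logistic in stenosis, centred near the 70%
#' hemodynamic-significance threshold) so that flow-limiting lesions
#' depress wall motion much more than moderate narrowings of equal
#' Gensini bin. The reduction saturates toward the floor of 0.3;
#' left-main lesions split their contribution between the LAD and LCx
#' territories.
#'
#' @inheritParams gensini_score
#' @param floor_c Minimum contractility.
#' @return Named numeric vector (LAD, LCx, RCA) in \[`floor_c`, 1\].
#' @export
territory_contractility <- function(lesions, config = gensini_config(),
                                    floor_c = 0.3) {
  g <- c(LAD = 0, LCx = 0, RCA = 0)
  lesions <- as_lesion_list(lesions)
  res <- gensini_score(lesions, config)
  for (i in seq_along(lesions)) {
    flow <- 1 / (1 + exp(-(lesions[[i]]$stenosis - 68) / 6))
    ters <- segment_territories(lesions[[i]]$segment)
    for (ter in ters) {
      g[ter] <- g[ter] + flow * res$contributions[i] / length(ters)
    }
  }
  pmax(floor_c, 1 - 0.85 * g / (g + 8))
}

draw_lesions <- function(significant) {
  non_lm <- setdiff(coronary_segments, "LM")
  lesions <- list()
  if (significant) {
    n <- sample(1:3, 1)
    segs <- sample(non_lm, n)
    sten <- runif(n, 40, 100)
    sten[1] <- runif(1, 70, 100) # index lesion meets the 70% rule
    for (i in seq_len(n)) {
      lesions[[i]] <- coronary_lesion(segs[i], round(sten[i]),
                                      collaterals = sten[i] >= 99 &&
                                        runif(1) < 0.5)
    }
  } else {
    n <- sample(0:2, 1, prob = c(0.35, 0.4, 0.25))
    if (n > 0) {
      segs <- sample(non_lm, n)
      sten <- round(runif(n, 10, 65))
      for (i in seq_len(n)) lesions[[i]] <- coronary_lesion(segs[i], sten[i])
    }
  }
  lesions
}

#' Generate a synthetic cohort
#'
#' `n_subjects` synthetic subjects, three apical-view clips each;
#' approximately `prevalence` of them carry significant coronary lesions.
#' Lesions lower the contractility of the territory they perfuse in
#' proportion to their Gensini contribution (saturating), so diseased
#' subjects have systematically lower |GLS|, LVEF and GWE.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param prevalence Fraction with significant CAD (default 0.421, the
#'   printed cohort prevalence of 122/290).
#' @param rng_seed Integer seed.
#' @param size Rendered frame size.
#' @param render If `FALSE`, skip rasterisation (fast labels-only cohort).
#' @return List of `subject_record`.
#' @export
make_cohort <- function(n_subjects, prevalence = 0.421, rng_seed = 1L,
                        size = 256L, render = TRUE) {
  if (n_subjects < 1L) stop("need at least one subject")
  plan <- run_seeded(rng_seed, {
    n_sig <- round(prevalence * n_subjects)
    sig <- logical(n_subjects)
    sig[sample.int(n_subjects, n_sig)] <- TRUE
    lapply(seq_len(n_subjects), function(i) {
      list(sig = sig[i], lesions = draw_lesions(sig[i]),
           seed = rng_seed * 10000L + i)
    })
  })
  lapply(plan, function(p) {
    phantom <- make_phantom(p$seed, disease_level = 0)
    phantom$contractility <- territory_contractility(p$lesions)
    rec <- render_subject(phantom, p$lesions, noise_seed = p$seed + 7L,
                          size = size, render = render)
    rec$id <- sprintf("S%06d", p$seed %% 1000000L)
    rec
  })
}

#' Write a cohort to disk
#'
#' Clips and masks are written as RDS tensors plus per-frame PNG stacks
#' for the first frame of each view (for quick inspection); labels go to
#' one CSV row per subject and a cohort manifest CSV.
#'
#' @param cohort List of `subject_record`.
#' @param dir Output directory.
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(rec) {
    paths <- character(0)
    if (!is.null(rec$views[[1]])) {
      for (v in rec$view_labels) {
        p <- file.path(dir, paste0(rec$id, "_", v, ".rds"))
        saveRDS(list(video = rec$views[[v]], mask = rec$masks[[v]],
                     strain = rec$strain, ef = rec$ef), p)
        png_path <- file.path(dir, paste0(rec$id, "_", v, "_f1.png"))
        png::writePNG(rec$views[[v]][1, , ], png_path)
        paths <- c(paths, p)
      }
    }
    data.frame(
      id = rec$id,
      a4c = if (length(paths)) paths[1] else NA,
      a3c = if (length(paths)) paths[2] else NA,
      a2c = if (length(paths)) paths[3] else NA,
      gls = rec$gls, lvef = rec$lvef, gwe = rec$gwe,
      gensini = rec$gensini,
      significant = rec$significant, severe = rec$severe
    )
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(manifest)
}
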