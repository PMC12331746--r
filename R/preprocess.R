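# Preprocessing: convert a raw variable-length cardiac-cycle video into
# the fixed 20 x 256 x 256 block the network consumes. Ten frames sample
# the half-open phase interval [ED, ES) uniformly and ten sample
# [ES, next ED), so end-systole is not duplicated; spatial resizing is
# isotropic with zero-padding to square.

#' Construct a raw cardiac-cycle video
#'
#' @param frames (T, H, W) array, T >= 2 frames of one cardiac cycle.
#' @param ed,es 1-based frame indices of end-diastole and end-systole,
#'   with `ed < es`.
#' @param next_ed 1-based index of the next end-diastole; defaults to
#'   `T + 1` (the cycle wraps right after the last frame).
#' @param sector Optional sector polygon (k x 2 matrix of row, col).
#' @return A `raw_cycle` object.
#' @export
raw_cycle <- function(frames, ed, es, next_ed = NULL, sector = NULL) {
  d <- dim(frames)
  if (length(d) != 3L || d[1] < 2L) stop("frames must be a (T>=2, H, W) array")
  if (is.null(next_ed)) next_ed <- d[1] + 1L
  ed <- as.integer(ed); es <- as.integer(es); next_ed <- as.integer(next_ed)
  if (ed < 1L || es <= ed) stop("need 1 <= ED < ES (got ED=", ed,
                                ", ES=", es, ")")
  if (next_ed <= es || next_ed > d[1] + 1L) {
    stop("next ED must lie in (ES, T+1]")
  }
  structure(list(frames = frames, ed = ed, es = es, next_ed = next_ed,
                 sector = sector), class = "raw_cycle")
}

#' Source-frame indices for the 20-frame phase grid
#'
#' Ten uniform samples over the half-open systolic interval \[ED, ES) and
#' ten over \[ES, next ED); selection depends only on the indices, never
#' on pixel content.
#'
#' @param n_total Total frames T.
#' @param ed,es,next_ed 1-based indices as in [raw_cycle()].
#' @param n_half Samples per half-cycle (default 10).
#' @return Integer vector of 2 * `n_half` source indices.
#' @export
resample_indices <- function(n_total, ed, es, next_ed = n_total + 1L,
                             n_half = 10L) {
  if (es <= ed) stop("ES must follow ED")
  sys <- ed + floor((es - ed) * (seq_len(n_half) - 1L) / n_half)
  dia <- es + floor((next_ed - es) * (seq_len(n_half) - 1L) / n_half)
  idx <- as.integer(c(sys, dia))
  if (any(idx < 1L | idx > n_total)) stop("resample index out of range")
  idx
}

resize_pad <- function(frame, size, nearest = FALSE) {
  d <- dim(frame)
  if (d[1] == size && d[2] == size) return(frame)
  sc <- size / max(d)
  nh <- max(1L, round(d[1] * sc)); nw <- max(1L, round(d[2] * sc))
  if (nearest) {
    ri <- pmin(d[1], pmax(1L, floor((seq_len(nh) - 0.5) * d[1] / nh) + 1L))
    ci <- pmin(d[2], pmax(1L, floor((seq_len(nw) - 0.5) * d[2] / nw) + 1L))
    small <- frame[ri, ci, drop = FALSE]
  } else {
    small <- EBImage::imageData(
      EBImage::resize(EBImage::Image(frame), w = nh, h = nw))
  }
  out <- matrix(0, size, size)
  r0 <- (size - nh) %/% 2L
  c0 <- (size - nw) %/% 2L
  out[r0 + seq_len(nh), c0 + seq_len(nw)] <- small
  out
}

#' Resample a raw cycle into a 20 x 256 x 256 video block
#'
#' @param raw A [raw_cycle()].
#' @param size Output spatial size (default 256).
#' @param n_half Frames per half-cycle (default 10).
#' @param view Optional view label (`"A4C"`, `"A3C"`, `"A2C"`).
#' @return A `video_block`: (2 * n_half, size, size) array with
#'   intensities in \[0, 1\] and attributes `view` and `indices`.
#' @export
resample_cycle <- function(raw, size = 256L, n_half = 10L, view = NULL) {
  stopifnot(inherits(raw, "raw_cycle"))
  idx <- resample_indices(dim(raw$frames)[1], raw$ed, raw$es, raw$next_ed,
                          n_half)
  frames <- raw$frames
  mx <- max(frames)
  if (mx > 1) frames <- frames / if (mx > 100) 255 else mx
  frames[frames < 0] <- 0
  out <- array(0, dim = c(length(idx), size, size))
  for (i in seq_along(idx)) {
    out[i, , ] <- resize_pad(frames[idx[i], , ], size)
  }
  structure(out, view = view, indices = idx, class = "video_block")
}

#' Resample an annotated mask stack on the identical frame grid
#'
#' Uses the same source-frame selection as [resample_cycle()] (the paired
#' grid invariant) and nearest-neighbour spatial resizing so the label
#' set is preserved.
#'
#' @param raw_masks (T, H, W) integer array of labels aligned with the
#'   raw frames.
#' @param raw The matching [raw_cycle()].
#' @inheritParams resample_cycle
#' @return A `mask_block` (2 * n_half, size, size) integer array.
#' @export
resample_masks <- function(raw_masks, raw, size = 256L, n_half = 10L) {
  stopifnot(inherits(raw, "raw_cycle"))
  if (!identical(dim(raw_masks)[1], dim(raw$frames)[1])) {
    stop("mask stack has ", dim(raw_masks)[1], " frames but the cycle has ",
         dim(raw$frames)[1])
  }
  idx <- resample_indices(dim(raw$frames)[1], raw$ed, raw$es, raw$next_ed,
                          n_half)
  out <- array(0L, dim = c(length(idx), size, size))
  for (i in seq_along(idx)) {
    out[i, , ] <- resize_pad(raw_masks[idx[i], , ], size, nearest = TRUE)
  }
  structure(out, indices = idx, class = "mask_block")
}

polygon_area <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Zero out pixels outside a sector polygon
#'
#' @param block A (T, H, W) video block.
#' @param sector k x 2 matrix of polygon vertices as (row, col), k >= 3.
#' @return The masked block (pixels outside the polygon set to 0).
#' @export
apply_sector_mask <- function(block, sector) {
  sector <- as.matrix(sector)
  if (nrow(sector) < 3L) stop("sector polygon needs at least 3 vertices")
  if (polygon_area(sector) <= 0) stop("sector polygon has empty interior")
  d <- dim(block)
  pts <- cbind(rep(seq_len(d[2]), times = d[3]),
               rep(seq_len(d[3]), each = d[2]))
  bnd <- rbind(sector, sector[1L, ])
  inside <- mgcv::in.out(bnd, pts)
  keep <- matrix(inside, d[2], d[3])
  out <- block
  for (t in seq_len(d[1])) out[t, , ] <- out[t, , ] * keep
  out
}

#' DICOM ingestion stub
#'
#' The preprocessing contract starts at [raw_cycle()]; multi-frame
#' ultrasound DICOM ingestion is an interface stub in this package.
#'
#' @param path Path to a DICOM file.
#' @export
read_dicom_cycle <- function(path) {
  stop("DICOM ingestion is not implemented; convert to an array and use ",
       "raw_cycle()")
}
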