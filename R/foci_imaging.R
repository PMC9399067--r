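# ---------------------------------------------------------------------------
# DNA-damage foci pipeline: maximum projection of z-stacks, nucleus
# segmentation on the nuclear stain, per-nucleus adaptive thresholding of
# the damage marker (mean + k SD inside the nucleus), focus counting, and
# time-course summaries.
# ---------------------------------------------------------------------------

#' Two-channel image stack
#'
#' Container for a registered two-channel z-stack: a nuclear stain (e.g.
#' DAPI) and a DNA-damage marker (e.g. 53BP1), stored as 3-D arrays
#' (x, y, z) with a common pixel size.
#'
#' @param nuclear,damage 3-D numeric arrays (or 2-D matrices, promoted to
#'   a single z-plane) of identical dimensions.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(nuclear, damage, pixel_size_um) {
  promote <- function(x) if (length(dim(x)) == 2L)
    array(x, c(dim(x), 1L)) else x
  nuclear <- promote(nuclear); damage <- promote(damage)
  if (!identical(dim(nuclear), dim(damage)))
    stop_domain("channels must have identical dimensions")
  if (length(dim(nuclear)) != 3L)
    stop_domain("channels must be 2-D or 3-D arrays")
  if (any(!is.finite(nuclear)) || any(!is.finite(damage)))
    stop_domain("intensities must be finite")
  check_number(pixel_size_um, "pixel_size_um", lower = 0,
               allow_zero = FALSE)
  structure(list(nuclear = nuclear, damage = damage,
                 pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' Maximum-intensity projection of an image stack
#'
#' Per-pixel maximum across z-planes, per channel.
#'
#' @param stack An `image_stack`.
#' @return List with 2-D matrices `nuclear` and `damage`.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  proj <- function(a) {
    nz <- dim(a)[3L]
    Reduce(pmax, lapply(seq_len(nz), function(k) a[, , k]))
  }
  list(nuclear = proj(stack$nuclear), damage = proj(stack$damage),
       pixel_size_um = stack$pixel_size_um)
}

#' Segment nuclei in a nuclear-stain image
#'
#' Global (Otsu) thresholding of the normalized nuclear channel, hole
#' filling, minimum-area filtering, and optional splitting of touching
#' nuclei by watershed on the distance transform.
#'
#' @param nuclear_image 2-D numeric matrix (e.g. the maximum projection of
#'   the DAPI channel).
#' @param min_area_px Minimum nucleus area in pixels (default 500).
#' @param split_touching Split touching nuclei by watershed (default TRUE).
#' @param watershed_tolerance Minimum height of an object in the distance
#'   map to remain a separate nucleus (pixels; default 2).
#' @return Object of class `nucleus_rois`: list with `labels` (integer
#'   label matrix, 0 = background) and `stats` (`data.frame` with `roi`,
#'   `area_px`, centroid coordinates). Empty (with a warning) when no
#'   nucleus is found.
#' @export
segment_nuclei <- function(nuclear_image, min_area_px = 500,
                           split_touching = TRUE,
                           watershed_tolerance = 2) {
  stopifnot(is.matrix(nuclear_image))
  empty <- structure(list(labels = matrix(0L, nrow(nuclear_image),
                                          ncol(nuclear_image)),
                          stats = data.frame(roi = integer(),
                                             area_px = numeric(),
                                             cx = numeric(),
                                             cy = numeric())),
                     class = "nucleus_rois")
  rng <- range(nuclear_image)
  if (diff(rng) == 0) {
    warning("constant nuclear image: no nuclei found")
    return(empty)
  }
  x <- (nuclear_image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(x))
  mask <- EBImage::fillHull(EBImage::Image(x > thr))
  if (split_touching) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) {
    warning("no nuclei found")
    return(empty)
  }
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  if (!length(keep)) {
    warning("no nuclei above the minimum area")
    return(empty)
  }
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  idx <- which(out > 0, arr.ind = TRUE)
  v <- out[out > 0]
  stats <- data.frame(
    roi = seq_along(keep),
    area_px = as.numeric(tabulate(v, nbins = length(keep))),
    cx = as.numeric(tapply(idx[, 1], v, mean)),
    cy = as.numeric(tapply(idx[, 2], v, mean)))
  structure(list(labels = out, stats = stats), class = "nucleus_rois")
}

#' Count damage foci per nucleus
#'
#' For each segmented nucleus, the mean and standard deviation of the raw
#' damage-marker signal inside the mask set an adaptive threshold
#' `mean + k SD`; the threshold is applied to a lightly Gaussian-smoothed
#' copy of the channel (suppressing single-pixel noise excursions), and
#' connected components of supra-threshold pixels inside the mask with
#' area at least `min_focus_area_px` are counted as foci. Touching foci
#' are split by watershed on the supra-threshold intensity relief (the
#' split tolerance is a fixed fraction of the relief height). Because the
#' statistics, the smoothing and the relief are affine-equivariant, the
#' count is invariant under affine rescaling of the damage channel.
#'
#' @param rois A `nucleus_rois` from [segment_nuclei()].
#' @param damage_image 2-D matrix, registered with the segmentation.
#' @param k SD multiplier of the adaptive threshold (default 1).
#' @param min_focus_area_px Minimum focus area in pixels (default 4).
#' @param smooth_sigma Gaussian pre-smoothing of the damage channel in
#'   pixels (default 1; 0 disables). Suppresses single-pixel noise
#'   excursions while leaving diffraction-sized foci intact; being
#'   linear, it preserves the affine-invariance of the relative
#'   threshold.
#' @return `data.frame` with one row per nucleus: `roi`, `area_px`,
#'   `mean_signal`, `sd_signal`, `foci_count`.
#' @export
count_foci <- function(rois, damage_image, k = 1, min_focus_area_px = 4,
                       smooth_sigma = 1) {
  stopifnot(inherits(rois, "nucleus_rois"), is.matrix(damage_image))
  if (!identical(dim(rois$labels), dim(damage_image)))
    stop_domain("damage image and segmentation differ in size")
  check_number(k, "k", lower = 0)
  smoothed <- if (smooth_sigma > 0) {
    EBImage::imageData(
      EBImage::gblur(EBImage::Image(damage_image), sigma = smooth_sigma))
  } else damage_image
  lab <- rois$labels
  n <- nrow(rois$stats)
  out <- rois$stats[, c("roi", "area_px")]
  out$mean_signal <- NA_real_
  out$sd_signal <- NA_real_
  out$foci_count <- 0L
  for (i in seq_len(n)) {
    roi_id <- rois$stats$roi[i]
    inside <- lab == roi_id
    vals <- damage_image[inside]
    mu <- mean(vals); sdv <- stats::sd(vals)
    out$mean_signal[i] <- mu
    out$sd_signal[i] <- sdv
    if (!is.finite(sdv) || sdv == 0) next
    thr <- mu + k * sdv
    sel <- inside & smoothed > thr
    if (!any(sel)) next
    relief <- matrix(0, nrow(lab), ncol(lab))
    relief[sel] <- smoothed[sel] - thr
    fl <- EBImage::imageData(EBImage::watershed(
      EBImage::Image(relief), tolerance = 0.25 * max(relief), ext = 1))
    if (max(fl) == 0) next
    fa <- tabulate(fl[fl > 0])
    out$foci_count[i] <- sum(fa >= min_focus_area_px)
  }
  out
}

#' Foci time-course summary
#'
#' Per-condition and timepoint summary of per-nucleus focus counts:
#' mean, SEM (= SD / sqrt(n)), n, and fold change versus the untreated
#' condition at the same timepoint (omitted when only one condition is
#' present).
#'
#' @param results `data.frame` with columns `condition`, `timepoint_h`,
#'   `foci_count` (one row per nucleus).
#' @param untreated Condition label of the untreated control.
#' @return Summary `data.frame` with `condition`, `timepoint_h`, `n`,
#'   `mean_foci`, `sem`, and `fold_change_vs_untreated` when applicable.
#' @export
focus_timecourse <- function(results, untreated = "untreated") {
  stopifnot(is.data.frame(results),
            all(c("condition", "timepoint_h", "foci_count") %in%
                  names(results)))
  if (!nrow(results)) stop_domain("results is empty")
  agg <- do.call(rbind, lapply(
    split(results, list(results$condition, results$timepoint_h),
          drop = TRUE),
    function(g) data.frame(
      condition = g$condition[1],
      timepoint_h = g$timepoint_h[1],
      n = nrow(g),
      mean_foci = mean(g$foci_count),
      sem = stats::sd(g$foci_count) / sqrt(nrow(g)),
      stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  if (length(unique(agg$condition)) > 1L && untreated %in% agg$condition) {
    ref <- agg[agg$condition == untreated, c("timepoint_h", "mean_foci")]
    names(ref)[2] <- "ref_mean"
    agg <- merge(agg, ref, by = "timepoint_h", all.x = TRUE, sort = FALSE)
    agg$fold_change_vs_untreated <- agg$mean_foci / agg$ref_mean
    agg$ref_mean <- NULL
  }
  agg[order(agg$condition, agg$timepoint_h), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# TIFF I/O for stacks
# ---------------------------------------------------------------------------

#' Write an image stack as a multi-page TIFF
#'
#' Pages are ordered z-fastest within channel: all nuclear planes, then
#' all damage planes (a sidecar is not needed because the two channels
#' have the same number of planes).
#'
#' @param stack An `image_stack`.
#' @param path Output file path (.tif).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  clamp <- function(a) pmin(pmax(a, 0), 1)
  nz <- dim(stack$nuclear)[3L]
  pages <- c(lapply(seq_len(nz), function(k) clamp(stack$nuclear[, , k])),
             lapply(seq_len(nz), function(k) clamp(stack$damage[, , k])))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF file path.
#' @param pixel_size_um Pixel size in micrometres (not stored in the TIFF;
#'   must be supplied).
#' @return An `image_stack`.
#' @export
read_image_stack <- function(path, pixel_size_um) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 2L != 0L)
    stop_domain("expected an even number of pages (two channels)")
  nz <- length(pages) / 2L
  to_arr <- function(lst) {
    a <- array(0, c(dim(lst[[1L]]), length(lst)))
    for (k in seq_along(lst)) a[, , k] <- lst[[k]]
    a
  }
  image_stack(to_arr(pages[seq_len(nz)]), to_arr(pages[nz + seq_len(nz)]),
              pixel_size_um)
}
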