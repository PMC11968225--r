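# Global thresholds computed over an arbitrary set of pixel values.
# Otsu delegates to EBImage on the ROI-restricted values; the triangle
# method (not in EBImage) is the standard histogram construction.

otsu_threshold <- function(vals, levels = 256L) {
  rng <- range(vals)
  if (diff(rng) == 0)
    stopf("cannot compute an Otsu threshold on a constant image")
  vn <- (vals - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(matrix(vn, ncol = 1)),
                       range = c(0, 1), levels = levels)
  rng[1] + thr * diff(rng)
}

triangle_threshold <- function(vals, levels = 256L) {
  rng <- range(vals)
  if (diff(rng) == 0)
    stopf("cannot compute a triangle threshold on a constant image")
  h <- tabulate(pmin(levels, 1L + floor((vals - rng[1]) / diff(rng) * levels)),
                nbins = levels)
  peak <- which.max(h)
  # farthest nonzero bin from the peak defines the hypotenuse end
  nz <- which(h > 0)
  end <- nz[which.max(abs(nz - peak))]
  idx <- seq(min(peak, end), max(peak, end))
  # distance from each histogram point to the peak-end line
  x1 <- peak; y1 <- h[peak]; x2 <- end; y2 <- h[end]
  d <- abs((y2 - y1) * idx - (x2 - x1) * h[idx] + x2 * y1 - y2 * x1)
  best <- idx[which.max(d)]
  rng[1] + (best - 0.5) / levels * diff(rng)
}

#' Threshold a stain channel within the ROI
#'
#' Computes a global threshold over ROI pixels only (so background outside
#' the implant does not bias it) and returns the binary positive mask.
#' The threshold method and value are recorded for provenance, matching
#' per-stain method selection against negative controls.
#'
#' @param channel Numeric matrix, one stain channel.
#' @param roi An [roi_mask()] restricting the threshold computation.
#' @param method `"otsu"` (default), `"triangle"`, or `"fixed"`.
#' @param value Threshold when `method = "fixed"`.
#' @param stain Stain name recorded in the result.
#' @return Object of class `stain_mask`: list with logical `mask` (positive
#'   AND inside ROI), `stain`, `method`, `threshold`, `pixel_size_um`.
#' @export
threshold_channel <- function(channel, roi, method = c("otsu", "triangle", "fixed"),
                              value = NULL, stain = "stain") {
  method <- match.arg(method)
  if (!all(dim(channel) == dim(roi$mask))) stopf("channel and ROI shapes differ")
  vals <- channel[roi$mask]
  thr <- switch(method,
    otsu = otsu_threshold(vals),
    triangle = triangle_threshold(vals),
    fixed = { if (is.null(value)) stopf("method 'fixed' requires a value"); value })
  structure(list(mask = (channel > thr) & roi$mask, stain = stain,
                 method = method, threshold = thr,
                 pixel_size_um = roi$pixel_size_um),
            class = "stain_mask")
}

#' @export
print.stain_mask <- function(x, ...) {
  cat(sprintf("<stain_mask> %s (%s threshold %.4g); %d positive px\n",
              x$stain, x$method, x$threshold, sum(x$mask)))
  invisible(x)
}

as_region_matrix <- function(region) {
  if (inherits(region, "roi_mask")) region$mask
  else if (is.matrix(region)) region > 0
  else stopf("region must be a logical matrix or roi_mask")
}

#' Fraction of positive pixels in a region
#'
#' @param stain A `stain_mask` from [threshold_channel()].
#' @param region Logical matrix or [roi_mask()]; must be non-empty.
#' @return Fraction in \[0, 1\].
#' @export
fraction_positive <- function(stain, region) {
  reg <- as_region_matrix(region)
  if (!all(dim(reg) == dim(stain$mask))) stopf("mask and region shapes differ")
  n <- sum(reg)
  if (n == 0) stopf("region is empty")
  sum(stain$mask & reg) / n
}

#' Fraction-positive profile across depth bands
#'
#' One record per non-empty band: the fraction of positive pixels among the
#' band's pixels, with the band's mid depth `(k - 1/2) * band_width`.  These
#' records are the input rows of the distance-trend mixed model.
#'
#' @param stain A `stain_mask`.
#' @param bands A [band_map()].
#' @param meta Named list of metadata carried into every record
#'   (`image_id`, `group`, `timepoint`, `mouse_id`, `replicate`).
#' @return `band_fractions` data frame.
#' @export
band_profile <- function(stain, bands, meta = list()) {
  if (!all(dim(stain$mask) == dim(bands$labels))) stopf("mask and band map shapes differ")
  lab <- bands$labels
  npix <- tabulate(lab[lab > 0], nbins = bands$n_bands)
  pos <- tabulate(lab[lab > 0 & stain$mask], nbins = bands$n_bands)
  keep <- npix > 0
  md <- function(field, default) meta[[field]] %||% default
  out <- data.frame(image_id = md("image_id", "image1"),
                    group = md("group", NA_character_),
                    timepoint = md("timepoint", NA),
                    mouse_id = md("mouse_id", NA_character_),
                    replicate = md("replicate", 1L),
                    stain = stain$stain,
                    band = which(keep),
                    mid_depth_um = bands$mid_depth_um[keep],
                    fraction_positive = pos[keep] / npix[keep],
                    band_area_um2 = bands$band_areas_um2[keep])
  class(out) <- c("band_fractions", "data.frame")
  out
}

#' Count thresholded objects, optionally split into core/outer regions
#'
#' Labels 8-connected components of the positive mask, removes objects
#' below the minimum area, assigns each remaining object to a region by its
#' centroid, and reports counts and densities per mm^2 — the
#' particle-analysis style readout used for CD31+ vessel counting.
#'
#' @param stain A `stain_mask`.
#' @param min_area_um2 Minimum object area retained (default 20).
#' @param region `NULL` for the whole mask frame, an [roi_mask()] for a
#'   single region, or a [inner_outer_split()] result for core/outer counts.
#' @param image_id Identifier carried into the records.
#' @return `object_counts` data frame: `image_id`, `region`, `count`,
#'   `area_um2`, `density_per_mm2`.
#' @export
count_objects <- function(stain, min_area_um2 = 20, region = NULL,
                          image_id = "image1") {
  px <- stain$pixel_size_um
  lab <- label_components(stain$mask)
  nlab <- max(lab)
  cent <- NULL
  if (nlab > 0) {
    areas <- tabulate(lab[lab > 0], nbins = nlab) * px^2
    keep <- which(areas >= min_area_um2)
    idx <- which(lab > 0, arr.ind = TRUE)
    l <- lab[lab > 0]
    cx <- tapply(idx[, 1], l, mean)[as.character(keep)]
    cy <- tapply(idx[, 2], l, mean)[as.character(keep)]
    cent <- cbind(pmax(1L, round(cx)), pmax(1L, round(cy)))
  } else keep <- integer(0)
  regions <- if (inherits(region, "region_split")) {
    list(inner = region$inner, outer = region$outer)
  } else if (!is.null(region)) {
    list(whole = as_region_matrix(region))
  } else {
    list(whole = matrix(TRUE, nrow(stain$mask), ncol(stain$mask)))
  }
  rows <- lapply(names(regions), function(rn) {
    reg <- regions[[rn]]
    cnt <- if (length(keep)) sum(reg[cent]) else 0L
    area <- sum(reg) * px^2
    data.frame(image_id = image_id, region = rn, count = cnt,
               area_um2 = area, density_per_mm2 = cnt / (area / 1e6))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("object_counts", "data.frame")
  out
}

#' Count objects of one stain colocalized with another
#'
#' Counts objects of `stain_a` (after the area filter) whose pixel overlap
#' with the positive mask of `stain_b` is at least `min_overlap_fraction`
#' of the object's own area — the object-based colocalization used to count
#' double-positive (e.g. CD31+/Podoplanin+) cells.
#'
#' @param stain_a,stain_b Aligned `stain_mask` objects.
#' @param min_overlap_fraction Required overlap fraction (default 0.25).
#' @inheritParams count_objects
#' @return `object_counts` data frame (counts of A-objects overlapping B).
#' @export
colocalize_objects <- function(stain_a, stain_b, min_overlap_fraction = 0.25,
                               min_area_um2 = 20, region = NULL,
                               image_id = "image1") {
  if (!all(dim(stain_a$mask) == dim(stain_b$mask))) stopf("mask shapes differ")
  px <- stain_a$pixel_size_um
  lab <- label_components(stain_a$mask)
  nlab <- max(lab)
  keep <- integer(0); cent <- NULL
  if (nlab > 0) {
    areas_px <- tabulate(lab[lab > 0], nbins = nlab)
    over_px <- tabulate(lab[lab > 0 & stain_b$mask], nbins = nlab)
    keep <- which(areas_px * px^2 >= min_area_um2 &
                    over_px / areas_px >= min_overlap_fraction)
    if (length(keep)) {
      idx <- which(lab > 0, arr.ind = TRUE)
      l <- lab[lab > 0]
      cx <- tapply(idx[, 1], l, mean)[as.character(keep)]
      cy <- tapply(idx[, 2], l, mean)[as.character(keep)]
      cent <- cbind(pmax(1L, round(cx)), pmax(1L, round(cy)))
    }
  }
  regions <- if (inherits(region, "region_split")) {
    list(inner = region$inner, outer = region$outer)
  } else if (!is.null(region)) {
    list(whole = as_region_matrix(region))
  } else {
    list(whole = matrix(TRUE, nrow(stain_a$mask), ncol(stain_a$mask)))
  }
  rows <- lapply(names(regions), function(rn) {
    reg <- regions[[rn]]
    cnt <- if (length(keep)) sum(reg[cent]) else 0L
    area <- sum(reg) * px^2
    data.frame(image_id = image_id, region = rn, count = cnt,
               area_um2 = area, density_per_mm2 = cnt / (area / 1e6))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("object_counts", "data.frame")
  out
}
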