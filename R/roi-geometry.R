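#' Region-of-interest mask
#'
#' A binary implant mask with its physical pixel size.  Matrices are indexed
#' `[x, y]`; the centre of pixel `i` sits at `(i - 0.5) * pixel_size_um`.
#'
#' @param mask Logical matrix (TRUE inside the implant).
#' @param pixel_size_um Isotropic pixel size in micrometres (> 0).
#' @return Object of class `roi_mask`: list with `mask` and `pixel_size_um`.
#' @export
roi_mask <- function(mask, pixel_size_um) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  mask <- mask > 0
  if (!any(mask)) stopf("ROI mask is empty")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stopf("pixel_size_um must be a single value > 0 (anisotropic pixels unsupported)")
  structure(list(mask = mask, pixel_size_um = pixel_size_um), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px at %.3g um/px; area %.4g mm^2\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size_um, roi_area_mm2(x)))
  invisible(x)
}

roi_area_mm2 <- function(roi) sum(roi$mask) * roi$pixel_size_um^2 / 1e6

#' Depth-from-edge map of an ROI
#'
#' Euclidean distance (micrometres) from each interior pixel centre to the
#' continuum ROI boundary, computed from the Euclidean distance transform;
#' the half-pixel offset between the distance to the nearest background
#' pixel centre and the distance to the mask boundary is subtracted.
#' Pixels outside the ROI are `NA`.
#'
#' @param roi An [roi_mask()].
#' @return Numeric matrix of depths in micrometres (`NA` outside).
#' @export
depth_map <- function(roi) {
  nx <- nrow(roi$mask); ny <- ncol(roi$mask)
  # pad with a background ring so the image frame itself acts as a boundary
  pad <- matrix(0, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- roi$mask
  d <- as_mat(EBImage::distmap(pad))[2:(nx + 1), 2:(ny + 1)]
  depth <- (d - 0.5) * roi$pixel_size_um
  depth[!roi$mask] <- NA_real_
  depth
}

#' Derive the implant ROI from a DAPI channel
#'
#' Standard pipeline for isolating the implant from surrounding tissue:
#' Gaussian smoothing, global thresholding (Otsu by default), morphological
#' closing, hole filling, and retention of the largest connected component.
#'
#' @param dapi Numeric matrix, the DAPI channel.
#' @param pixel_size_um Pixel size in micrometres.
#' @param sigma_um Smoothing SD before thresholding (default 5 um).
#' @param method `"otsu"` or `"fixed"`.
#' @param value Threshold value when `method = "fixed"`.
#' @param close_radius_um Radius of the disc structuring element used for
#'   morphological closing (default 10 um).
#' @return An [roi_mask()].
#' @export
derive_roi <- function(dapi, pixel_size_um, sigma_um = 5,
                       method = c("otsu", "fixed"), value = NULL,
                       close_radius_um = 10) {
  method <- match.arg(method)
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  sm <- dapi
  if (sigma_um > 0)
    sm <- as_mat(EBImage::gblur(dapi, sigma = sigma_um / pixel_size_um))
  thr <- if (method == "fixed") {
    if (is.null(value)) stopf("method 'fixed' requires a threshold value")
    value
  } else {
    otsu_threshold(as.vector(sm))
  }
  bin <- sm > thr
  if (!any(bin)) stopf("no foreground found in DAPI channel at threshold %.4g", thr)
  r_px <- max(1L, round(close_radius_um / pixel_size_um))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  bin <- as_mat(EBImage::closing(bin * 1, brush)) > 0
  bin <- as_mat(EBImage::fillHull(bin * 1)) > 0
  lab <- label_components(bin)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  roi_mask(lab == keep, pixel_size_um)
}

#' Concentric depth-band map of an ROI
#'
#' Partitions the ROI into fixed-width concentric shells measured inward
#' from the boundary: band `k` covers depths in `[(k-1)*w, k*w)`.  This is
#' the distance-transform equivalent of iteratively eroding the ROI by `w`
#' micrometres and is exact in physical units.
#'
#' @param roi An [roi_mask()].
#' @param band_width_um Shell width in micrometres (default 100).
#' @return Object of class `band_map`: list with integer `labels` matrix
#'   (0 outside the ROI), `band_width_um`, `band_areas_um2`, `n_bands`,
#'   `mid_depth_um`, and `pixel_size_um`.
#' @export
band_map <- function(roi, band_width_um = 100) {
  if (band_width_um <= 0) stopf("band_width_um must be > 0")
  if (band_width_um < roi$pixel_size_um)
    stopf("band width (%.3g um) is below one pixel (%.3g um)",
          band_width_um, roi$pixel_size_um)
  depth <- depth_map(roi)
  labels <- matrix(0L, nrow(roi$mask), ncol(roi$mask))
  labels[roi$mask] <- as.integer(floor(pmax(depth[roi$mask], 0) / band_width_um)) + 1L
  n_bands <- max(labels)
  areas <- tabulate(labels[labels > 0], nbins = n_bands) * roi$pixel_size_um^2
  structure(list(labels = labels, band_width_um = band_width_um,
                 band_areas_um2 = areas, n_bands = n_bands,
                 mid_depth_um = (seq_len(n_bands) - 0.5) * band_width_um,
                 pixel_size_um = roi$pixel_size_um),
            class = "band_map")
}

#' @export
print.band_map <- function(x, ...) {
  cat(sprintf("<band_map> %d bands of %g um; ROI area %.4g mm^2\n",
              x$n_bands, x$band_width_um, sum(x$band_areas_um2) / 1e6))
  invisible(x)
}

#' Split an ROI into core and outer regions of prescribed area
#'
#' Finds the cutoff depth whose erosion yields an inner (core) region
#' holding the target fraction of the total ROI area — the 50%-area
#' core/outer segmentation used for regional object counts.  The cutoff is
#' located by bisection on the depth-from-edge map and then snapped to the
#' nearest achievable discrete depth level.
#'
#' @param roi An [roi_mask()].
#' @param target_fraction Desired inner-area fraction in (0, 1); default 0.5.
#' @param tol Acceptable deviation of the achieved fraction (default 0.01).
#' @return Object of class `region_split`: list with logical `inner` and
#'   `outer` masks, `cutoff_depth_um`, `inner_area_fraction`, and
#'   `pixel_size_um`.
#' @export
inner_outer_split <- function(roi, target_fraction = 0.5, tol = 0.01) {
  if (target_fraction <= 0 || target_fraction >= 1)
    stopf("target_fraction must lie strictly between 0 and 1")
  depth <- depth_map(roi)
  dvals <- depth[roi$mask]
  n <- length(dvals)
  frac_at <- function(d) sum(dvals >= d) / n
  lo <- 0; hi <- max(dvals) + roi$pixel_size_um
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (frac_at(mid) > target_fraction) lo <- mid else hi <- mid
  }
  # snap to the discrete depth levels bracketing the bisection point
  lev <- sort(unique(dvals))
  cand <- unique(c(lev[findInterval(lo, lev)], lev[pmin(findInterval(lo, lev) + 1L, length(lev))],
                   hi))
  cand <- cand[!is.na(cand)]
  achieved <- vapply(cand, frac_at, numeric(1))
  best <- which.min(abs(achieved - target_fraction))
  d <- cand[best]; f <- achieved[best]
  if (abs(f - target_fraction) > tol)
    stopf("cannot achieve inner fraction %.3f on this mask; best achievable %.3f at depth %.1f um",
          target_fraction, f, d)
  inner <- roi$mask & !is.na(depth) & depth >= d
  outer <- roi$mask & !inner
  structure(list(inner = inner, outer = outer, cutoff_depth_um = d,
                 inner_area_fraction = f, pixel_size_um = roi$pixel_size_um),
            class = "region_split")
}

#' @export
print.region_split <- function(x, ...) {
  cat(sprintf("<region_split> cutoff depth %.1f um; inner fraction %.3f\n",
              x$cutoff_depth_um, x$inner_area_fraction))
  invisible(x)
}

# 8-connected component labeling.  EBImage::bwlabel is 4-connected, so
# labels touching only diagonally are merged with a union-find pass.
label_components <- function(mask, connectivity = 8L) {
  mask <- mask > 0
  lab <- as_mat(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (connectivity == 4L || nlab < 2L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nx <- nrow(lab); ny <- ncol(lab)
  # diagonal adjacencies: (i,j)-(i+1,j+1) and (i+1,j)-(i,j+1)
  a1 <- lab[-nx, -ny]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -ny];  b2 <- lab[-nx, -1]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) unite(pairs[k, 1], pairs[k, 2])
    roots <- vapply(seq_len(nlab), find, integer(1))
    dense <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- dense[lab[lab > 0]]
  }
  lab
}
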