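#' Construct a spot set
#'
#' @param x_um,y_um Spot coordinates in micrometres (image frame).
#' @param intensity Peak intensity of each spot.
#' @param channel Channel name.
#' @return `spot_set` data frame ordered by decreasing intensity.
#' @export
spot_set <- function(x_um = numeric(0), y_um = numeric(0),
                     intensity = numeric(0), channel = "spots") {
  df <- data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                   intensity = rep_len(as.numeric(intensity), length(x_um)),
                   channel = rep_len(channel, length(x_um)))
  o <- order(-df$intensity, df$x_um, df$y_um)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spot_set", "data.frame")
  df
}

#' Detect spots in a fluorescence channel
#'
#' Blob detection at nuclear scale: the channel is smoothed with a Gaussian
#' matched to the expected spot size, strict local maxima of the smoothed
#' response are found, peaks whose height above the robust background (the
#' image median of the smoothed response) falls below `min_prominence` are
#' discarded, and positions are refined to subpixel accuracy by quadratic
#' interpolation.
#'
#' @param channel Numeric matrix.
#' @param pixel_size_um Pixel size (micrometres).
#' @param sigma_um Spot scale (default 3 um, nuclear).
#' @param min_prominence Minimum peak height above background, intensity
#'   units (default 10).
#' @param channel_name Name recorded in the result.
#' @return A [spot_set()].
#' @export
detect_spots <- function(channel, pixel_size_um, sigma_um = 3,
                         min_prominence = 10, channel_name = "spots") {
  if (sigma_um <= 0 || min_prominence <= 0) stopf("detector parameters must be > 0")
  sm <- as_mat(EBImage::gblur(channel, sigma = sigma_um / pixel_size_um))
  nx <- nrow(sm); ny <- ncol(sm)
  if (nx < 3 || ny < 3) return(spot_set(channel = channel_name))
  ctr <- sm[2:(nx - 1), 2:(ny - 1)]
  # plateau ties (possible in noise-free renders) break by raster order:
  # strict inequality against neighbours that precede the pixel, weak
  # inequality against the rest, so exactly one pixel of a plateau wins
  later_max <- pmax(sm[3:nx, 2:(ny - 1)],
                    sm[2:(nx - 1), 3:ny], sm[1:(nx - 2), 3:ny], sm[3:nx, 3:ny])
  earlier_max <- pmax(sm[1:(nx - 2), 2:(ny - 1)],
                      sm[2:(nx - 1), 1:(ny - 2)], sm[1:(nx - 2), 1:(ny - 2)],
                      sm[3:nx, 1:(ny - 2)])
  bg <- median(sm)
  is_peak <- ctr >= later_max & ctr > earlier_max & (ctr - bg) >= min_prominence
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0) return(spot_set(channel = channel_name))
  ix <- idx[, 1] + 1L; iy <- idx[, 2] + 1L
  # subpixel refinement along each axis (clamped quadratic vertex)
  sub_off <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    off <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (fm - fp) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  dx <- sub_off(sm[cbind(ix - 1L, iy)], sm[cbind(ix, iy)], sm[cbind(ix + 1L, iy)])
  dy <- sub_off(sm[cbind(ix, iy - 1L)], sm[cbind(ix, iy)], sm[cbind(ix, iy + 1L)])
  spot_set(x_um = (ix - 0.5 + dx) * pixel_size_um,
           y_um = (iy - 0.5 + dy) * pixel_size_um,
           intensity = sm[cbind(ix, iy)], channel = channel_name)
}

#' Deduplicate spots by a minimum separation
#'
#' Greedy selection in decreasing intensity order (ties broken by x then y):
#' a spot is kept iff it lies at least `min_sep_um` from every spot already
#' kept — the distance filter used to resolve individual cells from
#' clustered detections.  All pairwise distances in the output are
#' `>= min_sep_um`.
#'
#' @param spots A [spot_set()].
#' @param min_sep_um Minimum separation (default 8 um).
#' @return Filtered [spot_set()].
#' @export
deduplicate_spots <- function(spots, min_sep_um = 8) {
  if (min_sep_um < 0) stopf("min_sep_um must be >= 0")
  n <- nrow(spots)
  if (n <= 1 || min_sep_um == 0) return(spots)
  o <- order(-spots$intensity, spots$x_um, spots$y_um)
  x <- spots$x_um[o]; y <- spots$y_um[o]
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(n)) {
    if (length(kx) == 0 || all((kx - x[i])^2 + (ky - y[i])^2 >= min_sep_um^2)) {
      keep[i] <- TRUE
      kx <- c(kx, x[i]); ky <- c(ky, y[i])
    }
  }
  out <- spots[o[keep], , drop = FALSE]
  rownames(out) <- NULL
  out
}

nearest_dist <- function(px, py, qx, qy) {
  # for each point in (px,py), distance to the nearest point in (qx,qy)
  if (length(qx) == 0) return(rep(Inf, length(px)))
  out <- numeric(length(px))
  chunk <- max(1L, floor(4e6 / length(qx)))
  for (s in seq(1, length(px), by = chunk)) {
    e <- min(s + chunk - 1L, length(px))
    d2 <- outer(px[s:e], qx, "-")^2 + outer(py[s:e], qy, "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Flag cells by proximity to marker spots
#'
#' A cell is flagged iff its nearest marker spot lies strictly closer than
#' `max_dist_um` (the "< 8 um" spot-to-spot rule).  If the cell set already
#' carries a `flagged` column, the new flag is intersected with it, so
#' successive rules compose into marker cascades (e.g. CD68 then iNOS).
#'
#' @param cells A [spot_set()], optionally with a logical `flagged` column.
#' @param markers A [spot_set()] of marker detections.
#' @param max_dist_um Strict distance cutoff (micrometres).
#' @return `cells` with a logical `flagged` column.
#' @export
assign_by_proximity <- function(cells, markers, max_dist_um) {
  if (max_dist_um < 0) stopf("max_dist_um must be >= 0")
  d <- nearest_dist(cells$x_um, cells$y_um, markers$x_um, markers$y_um)
  flag <- d < max_dist_um
  if (!is.null(cells$flagged)) flag <- flag & cells$flagged
  cells$flagged <- flag
  cells
}

#' Flag cells by proximity to a stain surface
#'
#' A cell is flagged iff its Euclidean distance to the thresholded stain
#' region is at most `max_dist_um` (inclusive; distance 0 inside the
#' region) — the "within 2 um of a surface" rule used for TE-7 fibroblast
#' identification.  Distance is measured to the region boundary: the
#' distance to the nearest boundary-pixel centre minus half a pixel.
#'
#' @param cells A [spot_set()].
#' @param surface A `stain_mask` from [threshold_channel()].
#' @param max_dist_um Inclusive distance cutoff (default 2 um).
#' @return `cells` with a logical `flagged` column (intersected as in
#'   [assign_by_proximity()]).
#' @export
assign_by_surface <- function(cells, surface, max_dist_um = 2) {
  if (max_dist_um < 0) stopf("max_dist_um must be >= 0")
  px <- surface$pixel_size_um
  m <- surface$mask
  n <- nrow(cells)
  flag <- logical(n)
  if (n > 0 && any(m)) {
    nx <- nrow(m); ny <- ncol(m)
    ix <- pmin(pmax(ceiling(cells$x_um / px), 1L), nx)
    iy <- pmin(pmax(ceiling(cells$y_um / px), 1L), ny)
    inside <- m[cbind(ix, iy)]
    # boundary = positive pixels with any 8-neighbour negative (or at frame edge)
    pad <- matrix(FALSE, nx + 2, ny + 2)
    pad[2:(nx + 1), 2:(ny + 1)] <- m
    nbr_all <- pad[1:nx, 2:(ny + 1)] & pad[3:(nx + 2), 2:(ny + 1)] &
      pad[2:(nx + 1), 1:ny] & pad[2:(nx + 1), 3:(ny + 2)] &
      pad[1:nx, 1:ny] & pad[3:(nx + 2), 1:ny] &
      pad[1:nx, 3:(ny + 2)] & pad[3:(nx + 2), 3:(ny + 2)]
    bnd <- which(m & !nbr_all, arr.ind = TRUE)
    bx <- px_center_um(bnd[, 1], px); by <- px_center_um(bnd[, 2], px)
    d <- nearest_dist(cells$x_um, cells$y_um, bx, by)
    d <- pmax(d - 0.5 * px, 0)
    flag <- inside | d <= max_dist_um
  }
  if (!is.null(cells$flagged)) flag <- flag & cells$flagged
  cells$flagged <- flag
  cells
}

#' Fraction of cells proliferating (Ki67-positive)
#'
#' Fraction of cell spots whose nearest Ki67 spot lies within `max_dist_um`
#' (inclusive), i.e. effectively overlapping the nucleus.
#'
#' @param cells Non-empty [spot_set()] of cell detections.
#' @param ki67 [spot_set()] of Ki67 detections.
#' @param max_dist_um Inclusive overlap distance (default 4 um).
#' @return Fraction in \[0, 1\].
#' @export
ki67_fraction <- function(cells, ki67, max_dist_um = 4) {
  if (nrow(cells) == 0) stopf("cell set is empty")
  d <- nearest_dist(cells$x_um, cells$y_um, ki67$x_um, ki67$y_um)
  mean(d <= max_dist_um)
}

#' Default phenotyping rule set
#'
#' Detection and classification parameters for [phenotype_image()]: spot
#' detector scale and prominence, the 8 um deduplication separation, the
#' strict `< 8 um` spot-to-spot rules gating macrophage (CD68), M1 (iNOS),
#' M2 (Arg1), T cell (CD3e) and T helper (CD4) calls, the inclusive 2 um
#' TE-7 surface rule for fibroblasts, and the 4 um Ki67 overlap distance.
#' The TE-7 surface is thresholded with the triangle method by default:
#' surface stains are sparse foreground over a dominant background mode,
#' the regime the triangle construction is designed for (Otsu can split
#' the background mode there and flood the surface mask).
#'
#' @param ... Overrides of individual defaults.
#' @return Named list of parameters.
#' @export
phenotype_rules <- function(...) {
  rules <- list(sigma_um = 3, min_prominence = 10, dedup_min_sep_um = 8,
                spot_rule_um = 8, surface_rule_um = 2, ki67_rule_um = 4,
                te7_method = "triangle",
                phenotypes = c("macrophage", "M1", "M2", "tcell", "thelper",
                               "fibroblast", "ki67"))
  modifyList(rules, list(...))
}

#' Phenotype all cells in a multiplex image
#'
#' Full spot-based workflow: detect DAPI spots (cells) and marker spots,
#' deduplicate each set at the minimum separation, restrict cells to the
#' ROI, then apply the distance-rule cascade per phenotype.  Counts,
#' fractions of total cells, and densities per implant area are reported.
#' Subclass rules compose: an M1 call requires the macrophage (CD68) flag
#' and proximity to an iNOS spot; M1/M2 are non-exclusive flags.
#'
#' @param image A `multiplex_image` (see [render_scene()]); channels must
#'   include `DAPI` plus the markers needed for the requested phenotypes.
#' @param roi An [roi_mask()].
#' @param rules A [phenotype_rules()] list.
#' @param meta Metadata list merged over the image's own.
#' @return One-row `phenotype_counts` data frame with counts (`n_cells`,
#'   `n_macrophage`, `n_M1`, `n_M2`, `n_tcell`, `n_thelper`,
#'   `n_fibroblast`, `n_ki67`), fractions of total cells, densities per
#'   mm^2, and `implant_area_mm2`.
#' @export
phenotype_image <- function(image, roi, rules = phenotype_rules(), meta = list()) {
  need <- c(DAPI = "DAPI")
  chan_for <- c(macrophage = "CD68", M1 = "iNOS", M2 = "Arg1", tcell = "CD3e",
                thelper = "CD4", fibroblast = "TE7", ki67 = "Ki67")
  wanted <- rules$phenotypes
  need <- unique(c("DAPI", unname(chan_for[wanted]),
                   if (any(c("M1", "M2") %in% wanted)) "CD68",
                   if ("thelper" %in% wanted) "CD3e"))
  missing <- setdiff(need, names(image$channels))
  if (length(missing))
    stopf("image lacks required channel(s): %s", paste(missing, collapse = ", "))
  px <- image$pixel_size_um
  det <- function(ch) deduplicate_spots(
    detect_spots(image$channels[[ch]], px, sigma_um = rules$sigma_um,
                 min_prominence = rules$min_prominence, channel_name = ch),
    rules$dedup_min_sep_um)
  cells <- det("DAPI")
  if (nrow(cells)) {
    ix <- pmin(pmax(ceiling(cells$x_um / px), 1L), nrow(roi$mask))
    iy <- pmin(pmax(ceiling(cells$y_um / px), 1L), ncol(roi$mask))
    cells <- cells[roi$mask[cbind(ix, iy)], , drop = FALSE]
  }
  area_mm2 <- roi_area_mm2(roi)
  n_cells <- nrow(cells)

  flag_count <- function(flagged) sum(flagged)
  res <- list(n_cells = n_cells)
  mac_flag <- tc_flag <- NULL
  if (any(c("macrophage", "M1", "M2") %in% wanted)) {
    mac <- assign_by_proximity(cells, det("CD68"), rules$spot_rule_um)
    mac_flag <- mac$flagged
    res$n_macrophage <- sum(mac_flag)
    if ("M1" %in% wanted)
      res$n_M1 <- sum(assign_by_proximity(mac, det("iNOS"), rules$spot_rule_um)$flagged)
    if ("M2" %in% wanted)
      res$n_M2 <- sum(assign_by_proximity(mac, det("Arg1"), rules$spot_rule_um)$flagged)
  }
  if (any(c("tcell", "thelper") %in% wanted)) {
    tc <- assign_by_proximity(cells, det("CD3e"), rules$spot_rule_um)
    res$n_tcell <- sum(tc$flagged)
    if ("thelper" %in% wanted)
      res$n_thelper <- sum(assign_by_proximity(tc, det("CD4"), rules$spot_rule_um)$flagged)
  }
  if ("fibroblast" %in% wanted) {
    surf <- threshold_channel(image$channels$TE7, roi, method = rules$te7_method,
                              stain = "TE7")
    res$n_fibroblast <- sum(assign_by_surface(cells, surf, rules$surface_rule_um)$flagged)
  }
  if ("ki67" %in% wanted)
    res$n_ki67 <- if (n_cells > 0)
      round(ki67_fraction(cells, det("Ki67"), rules$ki67_rule_um) * n_cells) else 0L

  meta_all <- modifyList(image$meta %||% list(), meta)
  out <- data.frame(image_id = meta_all$image_id %||% "image1",
                    group = meta_all$group %||% NA_character_,
                    timepoint = meta_all$timepoint %||% NA,
                    mouse_id = meta_all$mouse_id %||% NA_character_,
                    replicate = meta_all$replicate %||% 1L)
  out <- cbind(out, as.data.frame(res))
  for (nm in setdiff(names(res), "n_cells")) {
    frac_nm <- sub("^n_", "frac_", nm)
    dens_nm <- sub("^n_", "density_", nm)
    out[[frac_nm]] <- if (n_cells > 0) res[[nm]] / n_cells else NA_real_
    out[[dens_nm]] <- res[[nm]] / area_mm2
  }
  out$density_cells <- n_cells / area_mm2
  out$implant_area_mm2 <- area_mm2
  class(out) <- c("phenotype_counts", "data.frame")
  out
}
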