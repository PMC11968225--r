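#' Particle size distributions of the two microgel formulations
#'
#' Default microparticle diameter distributions (mean and SD, micrometres)
#' for the heparin-containing and plain formulations.  The two formulations
#' are size-matched by design so that scaffolds built from either have
#' equivalent pore architecture; the spread values are treated as standard
#' deviations of the particle population.
#'
#' @param formulation `"heparin"` or `"no_heparin"`.
#' @return Named numeric vector with elements `mean_um` and `sd_um`.
#' @export
#' @examples
#' formulation_defaults("heparin")
formulation_defaults <- function(formulation = c("heparin", "no_heparin")) {
  formulation <- match.arg(formulation)
  switch(formulation,
    heparin    = c(mean_um = 69.7, sd_um = 2.25),
    no_heparin = c(mean_um = 68.8, sd_um = 1.87))
}

#' Default marker probabilities conditional on cell class
#'
#' Conditional probability of each immunofluorescence marker given the cell
#' phenotype, used by [generate_cells()].  Lineage-defining markers (CD68 for
#' macrophages, CD3e for T cells, TE7 for fibroblasts, CD31 for endothelial
#' cells) have probability 1 for their class and 0 elsewhere; polarization
#' and subset markers (iNOS, Arg1, CD4, Podoplanin) are conditional; Ki67
#' marks a proliferating fraction of every class.
#'
#' @return Named list (one element per class) of named probability vectors.
#' @export
default_marker_probs <- function() {
  list(
    macrophage  = c(CD68 = 1, iNOS = 0.4, Arg1 = 0.5, Ki67 = 0.2),
    tcell       = c(CD3e = 1, CD4 = 0.6, Ki67 = 0.2),
    fibroblast  = c(TE7 = 1, Ki67 = 0.2),
    endothelial = c(CD31 = 1, Podo = 0.3, Ki67 = 0.2),
    other       = c(Ki67 = 0.2)
  )
}

# The fixed marker panel every synthetic scene carries.
marker_panel <- function() c("CD68", "iNOS", "Arg1", "CD3e", "CD4", "TE7",
                             "Ki67", "CD31", "Podo")

#' Synthetic-scene configuration
#'
#' Parameters of one synthetic implant cross-section: image geometry, ROI
#' shape, particle scaffold, radial cell-density gradient, phenotype mix,
#' marker probabilities, and rendering/noise levels.  Defaults emulate a
#' subcutaneous MAP implant section: a ~1 mm implant ROI packed with ~70 um
#' particles, a cell density that declines with depth from the implant edge,
#' and a phenotype mix of macrophages, T cells, fibroblasts and endothelial
#' cells with a residual unlabeled class.
#'
#' @param image_size_px Integer pair, image width and height in pixels.
#' @param pixel_size_um Physical pixel size (micrometres); isotropic.
#' @param roi_shape List with `type` in `"disk"`, `"ellipse"`, `"blob"` and
#'   size parameters in micrometres (`radius_um`; for ellipse `a_um`,`b_um`;
#'   for blob `radius_um` plus perturbation `amp`).
#' @param n_particles Number of scaffold microparticles to pack.
#' @param particle_diam_mean_um,particle_diam_sd_um Particle diameter
#'   distribution; defaults are the heparin formulation
#'   (see [formulation_defaults()]).
#' @param heparin_fraction Fraction of particles flagged heparin-containing
#'   (default 0.10, the 1:10 heparin-to-total mixing ratio).
#' @param cell_density_intercept Cell density at the ROI edge, cells/mm^2.
#' @param cell_density_slope Change in density per micrometre of depth
#'   (cells/mm^2/um); negative values put fewer cells in the core.
#' @param class_fractions Named fractions of phenotype classes; remainder is
#'   the unlabeled "other" class.  Must sum to at most 1.
#' @param marker_probs Named list of per-class marker probabilities
#'   (see [default_marker_probs()]).
#' @param marker_offset_sd_um SD of the random offset between a cell's
#'   nuclear (DAPI) position and its marker signal, micrometres.
#' @param background_level,signal_level,noise_sd Rendering intensities:
#'   additive background, Gaussian blob peak amplitude, and Gaussian noise SD
#'   (arbitrary units).
#' @param tissue_level Diffuse intensity added to every channel inside the
#'   implant ROI, emulating in-tissue autofluorescence and unresolved
#'   staining that makes the implant footprint visibly brighter than the
#'   slide; this is what makes DAPI-based ROI derivation well-posed.
#' @param blob_sigma_um SD of the rendered Gaussian blob (nuclear scale).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `scene_config` (validated list).
#' @export
#' @examples
#' cfg <- scene_config(seed = 7)
#' cfg$heparin_fraction
scene_config <- function(image_size_px = c(560L, 560L),
                         pixel_size_um = 2,
                         roi_shape = list(type = "disk", radius_um = 500),
                         n_particles = 80L,
                         particle_diam_mean_um = 69.7,
                         particle_diam_sd_um = 2.25,
                         heparin_fraction = 0.10,
                         cell_density_intercept = 500,
                         cell_density_slope = -0.3,
                         class_fractions = c(macrophage = 0.30, tcell = 0.10,
                                             fibroblast = 0.20, endothelial = 0.10),
                         marker_probs = default_marker_probs(),
                         marker_offset_sd_um = 1,
                         background_level = 10,
                         signal_level = 100,
                         noise_sd = 5,
                         tissue_level = 15,
                         blob_sigma_um = 3,
                         seed = 1L) {
  cfg <- list(image_size_px = as.integer(image_size_px),
              pixel_size_um = pixel_size_um, roi_shape = roi_shape,
              n_particles = as.integer(n_particles),
              particle_diam_mean_um = particle_diam_mean_um,
              particle_diam_sd_um = particle_diam_sd_um,
              heparin_fraction = heparin_fraction,
              cell_density_intercept = cell_density_intercept,
              cell_density_slope = cell_density_slope,
              class_fractions = class_fractions,
              marker_probs = marker_probs,
              marker_offset_sd_um = marker_offset_sd_um,
              background_level = background_level,
              signal_level = signal_level,
              noise_sd = noise_sd,
              tissue_level = tissue_level,
              blob_sigma_um = blob_sigma_um,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  if (length(cfg$image_size_px) != 2 || any(cfg$image_size_px < 8))
    stopf("image_size_px must be a pair of dimensions >= 8 px")
  if (!is.numeric(cfg$pixel_size_um) || cfg$pixel_size_um <= 0)
    stopf("pixel_size_um must be > 0")
  if (cfg$heparin_fraction < 0 || cfg$heparin_fraction > 1)
    stopf("heparin_fraction must lie in [0, 1]")
  if (cfg$particle_diam_sd_um < 0) stopf("particle_diam_sd_um must be >= 0")
  if (cfg$particle_diam_mean_um <= 0) stopf("particle_diam_mean_um must be > 0")
  cf <- cfg$class_fractions
  if (any(cf < 0 | cf > 1) || sum(cf) > 1 + 1e-12)
    stopf("class_fractions must lie in [0,1] and sum to <= 1 (got sum %.3f)", sum(cf))
  probs <- unlist(cfg$marker_probs)
  if (any(probs < 0 | probs > 1)) stopf("marker_probs must lie in [0, 1]")
  if (cfg$marker_offset_sd_um < 0) stopf("marker_offset_sd_um must be >= 0")
  if (cfg$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!cfg$roi_shape$type %in% c("disk", "ellipse", "blob"))
    stopf("roi_shape$type must be disk, ellipse or blob")
  invisible(cfg)
}

#' Build the true ROI mask for a scene configuration
#'
#' Rasterizes the configured ROI shape (disk, ellipse, or smooth random blob)
#' at the scene's pixel size, centred in the image.
#'
#' @param config A [scene_config()].
#' @return An `roi_mask` (see [roi_mask()]).
#' @export
make_roi <- function(config) {
  nx <- config$image_size_px[1]; ny <- config$image_size_px[2]
  px <- config$pixel_size_um
  cx <- nx * px / 2; cy <- ny * px / 2
  x <- px_center_um(seq_len(nx), px)
  y <- px_center_um(seq_len(ny), px)
  X <- matrix(x, nx, ny) - cx
  Y <- matrix(y, nx, ny, byrow = TRUE) - cy
  sh <- config$roi_shape
  mask <- switch(sh$type,
    disk = (X^2 + Y^2) <= sh$radius_um^2,
    ellipse = (X / sh$a_um)^2 + (Y / sh$b_um)^2 <= 1,
    blob = {
      amp <- sh$amp %||% 0.15
      with_seed(derive_seed(config$seed, "scaffold"), {
        a <- runif(3, 0, amp); phi <- runif(3, 0, 2 * pi)
      })
      th <- atan2(Y, X)
      r_um <- sqrt(X^2 + Y^2)
      rmax <- sh$radius_um * (1 + a[1] * cos(2 * th + phi[1]) +
                                a[2] * cos(3 * th + phi[2]) +
                                a[3] * cos(4 * th + phi[3]))
      r_um <= rmax
    })
  if (!any(mask)) stopf("configured ROI does not intersect the image")
  roi_mask(mask, px)
}

#' Caliper-series configuration
#'
#' Parameters of a synthetic longitudinal caliper dataset: number of
#' implants, measurement timepoints (months), expected volume and height
#' fold changes at each timepoint relative to implantation, and measurement
#' noise.  Defaults emulate the observed long-term trajectory of
#' subcutaneous MAP implants: a slight volume increase at 1 month followed
#' by slow loss, reaching a 0.45 volume fold (a ~55% decrease) at 12 months.
#'
#' @param n_implants Number of implants.
#' @param timepoints Months at which implants are measured; must include 0.
#' @param volume_fold_by_time,height_fold_by_time Named numeric vectors
#'   (names = months as character) of expected fold change vs month 0.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise applied to each caliper dimension.
#' @param baseline_length_mm,baseline_width_mm,baseline_height_mm Mean
#'   implant dimensions at implantation.
#' @param baseline_cv Between-implant CV of baseline dimensions.
#' @param groups Treatment labels assigned round-robin to implants.
#' @param seed Integer seed.
#' @return Object of class `caliper_series_config`.
#' @export
caliper_series_config <- function(n_implants = 6L,
                                  timepoints = c(0, 1, 3, 6, 12),
                                  volume_fold_by_time = c(`0` = 1, `1` = 1.1, `3` = 0.85,
                                                          `6` = 0.7, `12` = 0.45),
                                  height_fold_by_time = c(`0` = 1, `1` = 1.0, `3` = 0.9,
                                                          `6` = 0.8, `12` = 0.7),
                                  noise_cv = 0.05,
                                  baseline_length_mm = 8,
                                  baseline_width_mm = 8,
                                  baseline_height_mm = 3,
                                  baseline_cv = 0.05,
                                  groups = c("Hep", "NoHep"),
                                  seed = 1L) {
  if (!0 %in% timepoints) stopf("timepoints must include 0 (implantation)")
  tp_chr <- as.character(timepoints)
  missing_v <- setdiff(tp_chr, names(volume_fold_by_time))
  missing_h <- setdiff(tp_chr, names(height_fold_by_time))
  if (length(missing_v) || length(missing_h))
    stopf("fold maps must cover every timepoint (missing: %s)",
          paste(union(missing_v, missing_h), collapse = ", "))
  if (any(volume_fold_by_time <= 0) || any(height_fold_by_time <= 0))
    stopf("fold changes must be > 0")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  structure(list(n_implants = as.integer(n_implants), timepoints = timepoints,
                 volume_fold_by_time = volume_fold_by_time,
                 height_fold_by_time = height_fold_by_time,
                 noise_cv = noise_cv,
                 baseline_length_mm = baseline_length_mm,
                 baseline_width_mm = baseline_width_mm,
                 baseline_height_mm = baseline_height_mm,
                 baseline_cv = baseline_cv, groups = groups,
                 seed = as.integer(seed)),
            class = "caliper_series_config")
}
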