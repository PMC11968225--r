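#' Construct a particle set
#'
#' @param x_um,y_um Particle centre coordinates (micrometres).
#' @param diameter_um Particle diameters (> 0).
#' @param heparin Logical, heparin-containing flag.
#' @return `particle_set` data frame.
#' @export
particle_set <- function(x_um, y_um, diameter_um, heparin = FALSE) {
  if (any(diameter_um <= 0)) stopf("particle diameters must be > 0")
  df <- data.frame(x_um = x_um, y_um = y_um, diameter_um = diameter_um,
                   heparin = rep_len(as.logical(heparin), length(x_um)))
  class(df) <- c("particle_set", "data.frame")
  df
}

#' Pack a synthetic microparticle scaffold into the ROI
#'
#' Random sequential addition of hard disks: particle diameters are drawn
#' from a truncated normal (the configured formulation), centres are placed
#' uniformly inside the ROI (each particle fully contained), and candidates
#' overlapping an accepted particle are rejected.  Exactly
#' `round(n_particles * heparin_fraction)` particles are flagged as
#' heparin-containing, emulating the 1:10 heparin-to-total mixing ratio.
#'
#' @param config A [scene_config()].
#' @param roi Optional [roi_mask()]; defaults to [make_roi()] of the config.
#' @param overlap_tol Allowed fractional overlap of radii sums (default 0,
#'   hard disks).
#' @param max_attempts Total candidate placements before giving up.
#' @return A [particle_set()].
#' @export
#' @examples
#' ps <- generate_scaffold(scene_config(n_particles = 20, seed = 1))
#' nrow(ps)
generate_scaffold <- function(config, roi = make_roi(config), overlap_tol = 0,
                              max_attempts = 2000L * config$n_particles) {
  n <- config$n_particles
  if (n == 0L) return(particle_set(numeric(0), numeric(0), numeric(0), logical(0)))
  depth <- depth_map(roi)
  px <- roi$pixel_size_um
  inside <- which(roi$mask, arr.ind = TRUE)
  with_seed(derive_seed(config$seed, "scaffold"), {
    diam <- rtruncnorm_pos(n, config$particle_diam_mean_um, config$particle_diam_sd_um)
    hep <- rep(FALSE, n)
    hep[sample.int(n, round(n * config$heparin_fraction))] <- TRUE
    xs <- ys <- numeric(n)
    placed <- 0L
    attempts <- 0L
    while (placed < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      k <- placed + 1L
      idx <- inside[sample.int(nrow(inside), 1L), ]
      cand_x <- (idx[1] - 1 + runif(1)) * px
      cand_y <- (idx[2] - 1 + runif(1)) * px
      r <- diam[k] / 2
      # fully inside the ROI: depth at the candidate pixel must exceed r
      if (is.na(depth[idx[1], idx[2]]) || depth[idx[1], idx[2]] < r) next
      if (placed > 0L) {
        dd <- sqrt((xs[1:placed] - cand_x)^2 + (ys[1:placed] - cand_y)^2)
        lim <- (diam[1:placed] / 2 + r) * (1 - overlap_tol)
        if (any(dd < lim)) next
      }
      xs[k] <- cand_x; ys[k] <- cand_y
      placed <- k
    }
  })
  if (placed < n) {
    cover <- sum(pi * (diam[1:placed] / 2)^2) / (sum(roi$mask) * px^2)
    stopf("particle packing failed: placed %d of %d after %d attempts (area coverage %.2f)",
          placed, n, max_attempts, cover)
  }
  particle_set(xs, ys, diam, hep)
}

#' Sample particle diameters from a formulation's size distribution
#'
#' Draws diameters from the truncated normal used by [generate_scaffold()],
#' without packing — convenient for sizing experiments where particles are
#' laid out on a grid and measured with [measure_particles()].
#'
#' @param n Number of particles.
#' @param mean_um,sd_um Size distribution; defaults are the
#'   heparin-containing formulation (see [formulation_defaults()]).
#' @param seed Integer seed.
#' @return Numeric vector of diameters (micrometres).
#' @export
sample_particle_diameters <- function(n, mean_um = 69.7, sd_um = 2.25, seed = 1L) {
  with_seed(derive_seed(seed, "scaffold"), rtruncnorm_pos(n, mean_um, sd_um))
}

# Normal truncated at 0 by resampling.
rtruncnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Place synthetic cells with a radial density gradient
#'
#' Inhomogeneous Poisson point process on the ROI whose intensity is linear
#' in depth from the implant edge:
#' `lambda(depth) = intercept + slope * depth` (cells/mm^2, depth in um),
#' sampled by thinning.  Each cell receives a phenotype label drawn from
#' `class_fractions` (remainder = "other") and marker flags drawn from
#' `marker_probs` conditional on the label.
#'
#' @param config A [scene_config()].
#' @param roi An [roi_mask()]; defaults to the config's true ROI.
#' @return `ground_truth` data frame: `x_um`, `y_um`, `depth_um`,
#'   `phenotype`, and one logical column per marker in the panel.
#' @export
generate_cells <- function(config, roi = make_roi(config)) {
  depth <- depth_map(roi)
  dv <- depth[roi$mask]
  lam <- function(d) config$cell_density_intercept + config$cell_density_slope * d
  lams <- lam(dv)
  if (any(lams < 0))
    stopf("cell intensity is negative at depth %.0f um; adjust intercept/slope",
          dv[which.min(lams)])
  px <- roi$pixel_size_um
  area_mm2 <- roi_area_mm2(roi)
  lmax <- max(lams)
  inside <- which(roi$mask, arr.ind = TRUE)
  classes <- c(names(config$class_fractions), "other")
  pclass <- c(config$class_fractions, other = max(0, 1 - sum(config$class_fractions)))
  panel <- marker_panel()
  with_seed(derive_seed(config$seed, "cells"), {
    n_cand <- rpois(1, lmax * area_mm2)
    out <- NULL
    if (n_cand > 0) {
      sel <- sample.int(nrow(inside), n_cand, replace = TRUE)
      ix <- inside[sel, 1]; iy <- inside[sel, 2]
      d <- depth[cbind(ix, iy)]
      keep <- runif(n_cand) < lam(d) / lmax
      ix <- ix[keep]; iy <- iy[keep]; d <- d[keep]
      nc <- length(ix)
      if (nc > 0) {
        x <- (ix - 1 + runif(nc)) * px
        y <- (iy - 1 + runif(nc)) * px
        phen <- sample(classes, nc, replace = TRUE, prob = pclass)
        flags <- matrix(FALSE, nc, length(panel), dimnames = list(NULL, panel))
        for (cl in unique(phen)) {
          rows <- which(phen == cl)
          probs <- config$marker_probs[[cl]]
          for (m in names(probs))
            flags[rows, m] <- runif(length(rows)) < probs[[m]]
        }
        out <- data.frame(x_um = x, y_um = y, depth_um = d, phenotype = phen)
        out <- cbind(out, as.data.frame(flags))
      }
    }
  })
  if (is.null(out)) {
    out <- data.frame(x_um = numeric(0), y_um = numeric(0), depth_um = numeric(0),
                      phenotype = character(0))
    out <- cbind(out, as.data.frame(matrix(logical(0), 0, length(panel),
                                           dimnames = list(NULL, panel))))
  }
  class(out) <- c("ground_truth", "data.frame")
  attr(out, "pixel_size_um") <- px
  out
}

#' Render a multi-channel fluorescence scene
#'
#' Renders DAPI plus one channel per marker in the panel.  Every cell
#' contributes an isotropic 2D Gaussian blob (nuclear scale,
#' `blob_sigma_um`) of amplitude `signal_level` to DAPI; cells carrying a
#' marker contribute the same blob to that marker's channel at a position
#' jittered by `marker_offset_sd_um`.  Channels share the frame and pixel
#' size and receive independent additive Gaussian noise over the constant
#' background.
#'
#' @param particles A [particle_set()] (carried for provenance; particles
#'   are not fluorescent in any default channel).
#' @param truth A `ground_truth` table from [generate_cells()].
#' @param config A [scene_config()].
#' @param meta Named list of section metadata (image_id, mouse, group,
#'   timepoint, replicate).
#' @param roi The true [roi_mask()]; the diffuse `tissue_level` intensity is
#'   added inside it in every channel.
#' @return Object of class `multiplex_image`: list with named `channels`
#'   (numeric matrices), `pixel_size_um`, and `meta`.
#' @export
render_scene <- function(particles, truth, config,
                         meta = list(image_id = "scene1"),
                         roi = make_roi(config)) {
  nx <- config$image_size_px[1]; ny <- config$image_size_px[2]
  px <- config$pixel_size_um
  sigma <- config$blob_sigma_um
  panel <- marker_panel()
  size_um <- c(nx, ny) * px
  if (nrow(truth) && (any(truth$x_um < 0 | truth$x_um > size_um[1]) ||
                      any(truth$y_um < 0 | truth$y_um > size_um[2])))
    stopf("ground-truth cells fall outside the image bounds")
  with_seed(derive_seed(config$seed, "render"), {
    channels <- list()
    blank <- matrix(config$background_level, nx, ny)
    if ((config$tissue_level %||% 0) > 0)
      blank <- blank + config$tissue_level * roi$mask
    add_blobs <- function(img, xs, ys) {
      w <- ceiling(4 * sigma / px)
      for (i in seq_along(xs)) {
        cx <- xs[i] / px + 0.5; cy <- ys[i] / px + 0.5   # pixel-index coordinates
        i0 <- max(1L, floor(cx - w)); i1 <- min(nx, ceiling(cx + w))
        j0 <- max(1L, floor(cy - w)); j1 <- min(ny, ceiling(cy + w))
        if (i0 > i1 || j0 > j1) next
        gx <- exp(-((i0:i1 - cx) * px)^2 / (2 * sigma^2))
        gy <- exp(-((j0:j1 - cy) * px)^2 / (2 * sigma^2))
        img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + config$signal_level * outer(gx, gy)
      }
      img
    }
    channels$DAPI <- add_blobs(blank, truth$x_um, truth$y_um)
    for (m in panel) {
      img <- blank
      if (nrow(truth)) {
        rows <- which(truth[[m]])
        if (length(rows)) {
          jx <- truth$x_um[rows] + rnorm(length(rows), 0, config$marker_offset_sd_um)
          jy <- truth$y_um[rows] + rnorm(length(rows), 0, config$marker_offset_sd_um)
          img <- add_blobs(img, jx, jy)
        }
      }
      channels[[m]] <- img
    }
    if (config$noise_sd > 0)
      channels <- lapply(channels, function(ch) ch + rnorm(length(ch), 0, config$noise_sd))
  })
  structure(list(channels = channels, pixel_size_um = px, meta = meta),
            class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  cat(sprintf("<multiplex_image> %d x %d px at %.3g um/px; channels: %s\n",
              nrow(x$channels[[1]]), ncol(x$channels[[1]]), x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Measure particle diameters from a rasterized image
#'
#' Rasterizes each particle as a filled disk at the given pixel size,
#' labels connected components, and reports the equivalent-circle diameter
#' `2 * sqrt(area / pi)` of each object — the image-based diameter readout
#' used to size microgel particles.
#'
#' @param particles A [particle_set()].
#' @param pixel_size_um Rasterization pixel size (default 1 um/px).
#' @return Data frame with `particle`, `area_um2`, `diameter_um`.
#' @export
measure_particles <- function(particles, pixel_size_um = 1) {
  n <- nrow(particles)
  if (n == 0L)
    return(data.frame(particle = integer(0), area_um2 = numeric(0),
                      diameter_um = numeric(0)))
  r <- particles$diameter_um / 2
  pad <- max(r) + 2 * pixel_size_um
  x0 <- min(particles$x_um - r) - pad; y0 <- min(particles$y_um - r) - pad
  nx <- ceiling((max(particles$x_um + r) + pad - x0) / pixel_size_um)
  ny <- ceiling((max(particles$y_um + r) + pad - y0) / pixel_size_um)
  img <- matrix(FALSE, nx, ny)
  ctr_px <- cbind((particles$x_um - x0) / pixel_size_um + 0.5,
                  (particles$y_um - y0) / pixel_size_um + 0.5)
  for (k in seq_len(n)) {
    rp <- r[k] / pixel_size_um
    i0 <- max(1L, floor(ctr_px[k, 1] - rp)); i1 <- min(nx, ceiling(ctr_px[k, 1] + rp))
    j0 <- max(1L, floor(ctr_px[k, 2] - rp)); j1 <- min(ny, ceiling(ctr_px[k, 2] + rp))
    xs <- i0:i1; ys <- j0:j1
    disk <- outer((xs - ctr_px[k, 1])^2, (ys - ctr_px[k, 2])^2, "+") <= rp^2
    img[xs, ys] <- img[xs, ys] | disk
  }
  lab <- label_components(img)
  owner <- lab[cbind(pmin(pmax(round(ctr_px[, 1]), 1), nx),
                     pmin(pmax(round(ctr_px[, 2]), 1), ny))]
  if (anyDuplicated(owner)) {
    dup <- owner[duplicated(owner)][1]
    pair <- which(owner == dup)
    stopf("particles merged after rasterization: particles %s share one component",
          paste(pair, collapse = " and "))
  }
  areas <- tabulate(lab[lab > 0], nbins = max(lab)) * pixel_size_um^2
  data.frame(particle = seq_len(n), area_um2 = areas[owner],
             diameter_um = 2 * sqrt(areas[owner] / pi))
}

#' Generate a synthetic longitudinal caliper dataset
#'
#' Draws length/width/height for each implant at each timepoint so that the
#' expected volume and height fold changes match the configured trajectories,
#' with independent multiplicative lognormal measurement noise (unit mean,
#' CV `noise_cv`) on every dimension.  Height scales by the height fold;
#' length and width share the remaining volume fold equally.
#'
#' @param config A [caliper_series_config()].
#' @param volume_formula Passed to [implant_volume()].
#' @return `caliper_records` data frame: `implant_id`, `mouse_id`, `group`,
#'   `timepoint`, `length_mm`, `width_mm`, `height_mm`, `volume_mm3`.
#' @export
#' @examples
#' cal <- generate_caliper_series(caliper_series_config(noise_cv = 0, seed = 1))
#' head(cal)
generate_caliper_series <- function(config, volume_formula = "ellipsoid") {
  ln_noise <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    sdl <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  tps <- config$timepoints
  with_seed(derive_seed(config$seed, "calipers"), {
    nI <- config$n_implants
    l0 <- config$baseline_length_mm * ln_noise(nI, config$baseline_cv)
    w0 <- config$baseline_width_mm * ln_noise(nI, config$baseline_cv)
    h0 <- config$baseline_height_mm * ln_noise(nI, config$baseline_cv)
    grp <- rep_len(config$groups, nI)
    rows <- vector("list", length(tps))
    for (t in seq_along(tps)) {
      fv <- config$volume_fold_by_time[[as.character(tps[t])]]
      fh <- config$height_fold_by_time[[as.character(tps[t])]]
      flw <- sqrt(fv / fh)   # length and width share the residual volume fold
      l <- l0 * flw * ln_noise(nI, config$noise_cv)
      w <- w0 * flw * ln_noise(nI, config$noise_cv)
      h <- h0 * fh * ln_noise(nI, config$noise_cv)
      rows[[t]] <- data.frame(implant_id = sprintf("imp%02d", seq_len(nI)),
                              mouse_id = sprintf("m%02d", seq_len(nI)),
                              group = grp, timepoint = tps[t],
                              length_mm = l, width_mm = w, height_mm = h)
    }
  })
  out <- do.call(rbind, rows)
  out$volume_mm3 <- implant_volume(out$length_mm, out$width_mm, out$height_mm,
                                   formula = volume_formula)
  rownames(out) <- NULL
  class(out) <- c("caliper_records", "data.frame")
  out
}
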