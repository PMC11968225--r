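#' Build a pipeline run configuration
#'
#' A single configuration drives the full synthetic run: scene generation
#' per mouse/timepoint/replicate, ROI derivation, band quantification,
#' phenotyping, caliper morphometry, and the distance-trend model.  All
#' randomness flows from the single root `seed` via per-stage substreams.
#'
#' @param scene A [scene_config()] used as the template scene; per-image
#'   seeds are derived from the run seed.
#' @param calipers A [caliper_series_config()].
#' @param groups Group labels.
#' @param n_mice Mice per group.
#' @param timepoints Imaged timepoints (months).
#' @param n_replicates Replicate sections per mouse and timepoint.
#' @param band_width_um Depth-band width for ECM/DAPI profiles.
#' @param stains Named character vector mapping profiled channels to their
#'   threshold method.
#' @param rules A [phenotype_rules()] list.
#' @param adjust Multiplicity adjustment for slope contrasts.
#' @param seed Root seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(scene = scene_config(image_size_px = c(400L, 400L),
                                            roi_shape = list(type = "disk", radius_um = 350),
                                            n_particles = 0L),
                       calipers = caliper_series_config(),
                       groups = c("Hep", "NoHep"),
                       n_mice = 2L, timepoints = 1, n_replicates = 2L,
                       band_width_um = 100,
                       stains = c(DAPI = "otsu"),
                       rules = phenotype_rules(),
                       adjust = "tukey",
                       seed = 1L) {
  cfg <- structure(list(scene = scene, calipers = calipers, groups = groups,
                        n_mice = as.integer(n_mice), timepoints = timepoints,
                        n_replicates = as.integer(n_replicates),
                        band_width_um = band_width_um, stains = stains,
                        rules = rules, adjust = adjust, seed = as.integer(seed)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks the whole configuration before any stage executes and reports
#' every violation at once.
#'
#' @param config A `run_config` (or plain list with the same fields).
#' @return The config, invisibly; errors list all violations.
#' @export
validate_run_config <- function(config) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  if (is.null(config$scene)) add("missing scene configuration")
  else {
    ok <- tryCatch({ validate_scene_config(config$scene); TRUE },
                   error = function(e) { add(paste("scene:", conditionMessage(e))); FALSE })
  }
  if (is.null(config$scene$pixel_size_um)) add("missing pixel size")
  if (!is.null(config$band_width_um) && config$band_width_um <= 0)
    add("band_width_um must be > 0")
  if (is.null(config$seed)) add("missing seed")
  if (!is.null(config$n_mice) && config$n_mice < 1) add("n_mice must be >= 1")
  if (length(config$groups %||% character(0)) < 1) add("at least one group required")
  if (length(problems))
    stopf("invalid run configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  invisible(config)
}

#' Run the full synthetic quantification pipeline
#'
#' Stages: (1) simulate one scene per group x mouse x timepoint x replicate
#' and a caliper series; (2) derive the ROI from each DAPI channel; (3)
#' band-profile the configured stains; (4) phenotype each image; (5)
#' compute caliper fold changes; (6) fit the distance-trend mixed model and
#' slope contrasts.  Outputs (CSV tables, model summary JSON, provenance
#' manifest) are written under `out_dir`; any stage failure aborts naming
#' the stage.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param write_images If `TRUE`, also write every scene's channel TIFFs
#'   (off by default; images can be large).
#' @return Invisibly, a list with the collected tables and the fit.
#' @export
run_pipeline <- function(config, out_dir, write_images = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  band_rows <- list(); pheno_rows <- list(); truth_rows <- list()
  img_index <- 0L
  stage("simulate+quantify", {
    for (g in seq_along(config$groups)) {
      for (m in seq_len(config$n_mice)) {
        for (tp in config$timepoints) {
          for (r in seq_len(config$n_replicates)) {
            img_index <- img_index + 1L
            meta <- list(image_id = sprintf("img%03d", img_index),
                         group = config$groups[g],
                         mouse_id = sprintf("%s_m%02d", config$groups[g], m),
                         timepoint = tp, replicate = r)
            sc <- config$scene
            sc$seed <- derive_seed(config$seed, "pipeline") + img_index
            true_roi <- make_roi(sc)
            particles <- if (sc$n_particles > 0) generate_scaffold(sc, true_roi)
                         else particle_set(numeric(0), numeric(0), numeric(0))
            truth <- generate_cells(sc, true_roi)
            img <- render_scene(particles, truth, sc, meta = meta, roi = true_roi)
            if (write_images)
              write_multiplex(img, file.path(out_dir, "images", meta$image_id))
            roi <- derive_roi(img$channels$DAPI, sc$pixel_size_um)
            bands <- band_map(roi, config$band_width_um)
            for (st in names(config$stains)) {
              sm <- threshold_channel(img$channels[[st]], roi,
                                      method = config$stains[[st]], stain = st)
              band_rows[[length(band_rows) + 1L]] <- band_profile(sm, bands, meta)
            }
            pheno_rows[[length(pheno_rows) + 1L]] <-
              phenotype_image(img, roi, config$rules, meta)
            tr <- truth
            tr$image_id <- meta$image_id
            truth_rows[[length(truth_rows) + 1L]] <- tr
          }
        }
      }
    }
  })
  band_fractions <- do.call(rbind, band_rows)
  phenotypes <- do.call(rbind, pheno_rows)
  truth_all <- do.call(rbind, truth_rows)
  calipers <- stage("morphometry", generate_caliper_series(config$calipers))
  folds <- stage("morphometry", fold_change(calipers))
  fit <- stage("stats", fit_distance_trend(band_fractions))
  slopes <- stage("stats", marginal_slopes(fit))
  contrasts <- stage("stats", if (nrow(slopes) > 1)
    slope_contrasts(slopes, adjust = config$adjust) else NULL)

  wcsv <- function(x, f) if (!is.null(x))
    write.csv(x, file.path(out_dir, f), row.names = FALSE)
  stage("write", {
    wcsv(band_fractions, "band_fractions.csv")
    wcsv(phenotypes, "phenotype_counts.csv")
    wcsv(truth_all, "ground_truth.csv")
    wcsv(calipers, "calipers.csv")
    wcsv(folds, "fold_changes.csv")
    wcsv(as.data.frame(slopes), "slopes.csv")
    wcsv(if (!is.null(contrasts)) as.data.frame(contrasts), "contrasts.csv")
    jsonlite::write_json(
      list(coefficients = as.list(coef(fit)), singular = fit$singular,
           converged = fit$converged),
      file.path(out_dir, "model_summary.json"), auto_unbox = TRUE, digits = NA)
    manifest <- list(package = "implantquant",
                     version = as.character(packageVersion("implantquant")),
                     seed = config$seed,
                     config_hash = object_hash(unclass(config)),
                     n_images = img_index,
                     outputs = c("band_fractions.csv", "phenotype_counts.csv",
                                 "ground_truth.csv", "calipers.csv",
                                 "fold_changes.csv", "slopes.csv",
                                 "contrasts.csv", "model_summary.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(list(band_fractions = band_fractions, phenotypes = phenotypes,
                 truth = truth_all, calipers = calipers, folds = folds,
                 fit = fit, slopes = slopes, contrasts = contrasts,
                 out_dir = out_dir))
}
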