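# Spot detection, deduplication, proximity/surface rules, phenotype cascade.

test_that("spot detection finds isolated blobs and nothing in blank images", {
  blank <- matrix(10, 80, 80)
  expect_equal(nrow(detect_spots(blank, 2)), 0)

  cfg <- tiny_scene(seed = 1, noise_sd = 0)
  truth <- data.frame(x_um = c(150, 170), y_um = c(200, 200), depth_um = 0,
                      phenotype = "other")
  for (m in c("CD68", "iNOS", "Arg1", "CD3e", "CD4", "TE7", "Ki67", "CD31", "Podo"))
    truth[[m]] <- FALSE
  img <- render_scene(particle_set(numeric(0), numeric(0), numeric(0)), truth, cfg)
  sp <- detect_spots(img$channels$DAPI, 2)
  expect_equal(nrow(sp), 2)
  expect_true(all(abs(sort(sp$x_um) - c(150, 170)) < 2))
})

test_that("default-scene spot detection recovers true cells with few spurious peaks", {
  cfg <- scene_config(seed = 3)   # noise_sd / signal_level = 0.05
  roi <- make_roi(cfg)
  tr <- generate_cells(cfg, roi)
  img <- render_scene(particle_set(numeric(0), numeric(0), numeric(0)), tr, cfg, roi = roi)
  sp <- detect_spots(img$channels$DAPI, cfg$pixel_size_um)
  d_true <- oracle_nearest(tr$x_um, tr$y_um, sp$x_um, sp$y_um)
  d_spot <- oracle_nearest(sp$x_um, sp$y_um, tr$x_um, tr$y_um)
  expect_gte(mean(d_true <= 3), 0.95)
  expect_lte(mean(d_spot > 3), 0.05)
})

test_that("deduplication keeps the brightest of close pairs", {
  sp <- spot_set(x_um = c(0, 5, 20), y_um = c(0, 0, 0), intensity = c(10, 8, 5))
  out <- deduplicate_spots(sp, 8)
  expect_equal(sort(out$x_um), c(0, 20))
  # all spots already separated: identity
  far <- spot_set(x_um = c(0, 10, 25), y_um = c(0, 0, 0), intensity = c(3, 2, 1))
  expect_equal(nrow(deduplicate_spots(far, 8)), 3)
  expect_identical(deduplicate_spots(far, 0), far)
})

test_that("deduplication equals the brute-force greedy oracle and ignores input order", {
  set.seed(11)
  for (trial in 1:25) {
    n <- sample(5:120, 1)
    x <- runif(n, 0, 200); y <- runif(n, 0, 200)
    i <- runif(n, 1, 100)
    sep <- runif(1, 4, 20)
    out <- deduplicate_spots(spot_set(x, y, i), sep)
    got <- cbind(out$x_um, out$y_um)
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    expect_equal(got, oracle_dedup(x, y, i, sep))
    # permutation invariance (intensities distinct with probability 1)
    perm <- sample(n)
    out2 <- deduplicate_spots(spot_set(x[perm], y[perm], i[perm]), sep)
    expect_equal(sort(out2$x_um), sort(out$x_um))
    # kept spots pairwise >= sep apart
    if (nrow(out) > 1) expect_gte(min(dist(got)), sep)
  }
})

test_that("ties in intensity break by lexicographic position", {
  sp <- spot_set(x_um = c(3, 0), y_um = c(0, 0), intensity = c(1, 1))
  out <- deduplicate_spots(sp, 5)
  expect_equal(out$x_um, 0)   # (0,0) sorts first, wins
})

test_that("proximity flags use a strict distance inequality", {
  cells <- spot_set(x_um = c(0, 20), y_um = c(0, 0), intensity = c(1, 1))
  mk <- spot_set(x_um = 21, y_um = 0, intensity = 1)
  fl <- assign_by_proximity(cells, mk, 8)
  expect_equal(sum(fl$flagged), 1)
  expect_true(fl$flagged[fl$x_um == 20])
  # empty marker set: nothing flagged
  expect_equal(sum(assign_by_proximity(cells, spot_set(), 8)$flagged), 0)
  # boundary: marker at exactly 8 um is NOT within < 8 um
  mk8 <- spot_set(x_um = 8, y_um = 0, intensity = 1)
  expect_false(assign_by_proximity(cells, mk8, 8)$flagged[cells$x_um == 0])
})

test_that("successive proximity rules intersect and are monotone in distance", {
  set.seed(5)
  cells <- spot_set(runif(100, 0, 300), runif(100, 0, 300), runif(100))
  mkA <- spot_set(runif(30, 0, 300), runif(30, 0, 300), runif(30))
  mkB <- spot_set(runif(30, 0, 300), runif(30, 0, 300), runif(30))
  ab <- assign_by_proximity(assign_by_proximity(cells, mkA, 15), mkB, 15)
  a <- assign_by_proximity(cells, mkA, 15)
  expect_true(all(ab$flagged <= a$flagged))
  wide <- assign_by_proximity(cells, mkA, 30)
  expect_true(all(a$flagged <= wide$flagged))
})

test_that("surface distance follows point-to-region geometry", {
  m <- matrix(FALSE, 50, 50)
  m[1:20, 10:40] <- TRUE   # rectangle, right edge at x = 20 um (1 um px)
  surf <- structure(list(mask = m, stain = "TE7", method = "fixed", threshold = 0,
                         pixel_size_um = 1), class = "stain_mask")
  cells <- spot_set(x_um = c(21.5, 25, 15), y_um = c(25, 25, 25),
                    intensity = c(3, 2, 1))
  fl <- assign_by_surface(cells, surf, 2)
  expect_true(fl$flagged[fl$x_um == 21.5])    # distance 1.5
  expect_false(fl$flagged[fl$x_um == 25])     # distance 5
  expect_true(fl$flagged[fl$x_um == 15])      # inside the region
  # empty mask: zero flags
  es <- surf; es$mask <- matrix(FALSE, 50, 50)
  expect_equal(sum(assign_by_surface(cells, es, 2)$flagged), 0)
})

test_that("Ki67 fraction counts coincident spots inclusively", {
  cells <- spot_set(x_um = c(10, 30, 50), y_um = c(10, 10, 10), intensity = 1)
  expect_equal(ki67_fraction(cells, cells, 4), 1.0)
  expect_equal(ki67_fraction(cells, spot_set(), 4), 0.0)
  expect_error(ki67_fraction(spot_set(), cells, 4), "empty")
})

test_that("Ki67-positive fraction is recovered from a jitter-free scene", {
  probs <- default_marker_probs()
  cfg <- tiny_scene(seed = 33, marker_offset_sd_um = 0,
                    class_fractions = c(macrophage = 0.5),
                    cell_density_intercept = 400, cell_density_slope = 0)
  roi <- make_roi(cfg)
  tr <- generate_cells(cfg, roi)
  img <- render_scene(particle_set(numeric(0), numeric(0), numeric(0)), tr, cfg, roi = roi)
  px <- cfg$pixel_size_um
  cells <- deduplicate_spots(detect_spots(img$channels$DAPI, px), 8)
  ki <- deduplicate_spots(detect_spots(img$channels$Ki67, px), 8)
  fr <- ki67_fraction(cells, ki, 4)
  truefr <- mean(tr$Ki67)
  expect_lt(abs(fr - truefr), 3 * sqrt(truefr * (1 - truefr) / nrow(tr)) + 0.02)
})

test_that("phenotype cascade recovers configured class fractions on the default scene", {
  cfg <- scene_config(seed = 5)
  roi <- make_roi(cfg)
  tr <- generate_cells(cfg, roi)
  img <- render_scene(particle_set(numeric(0), numeric(0), numeric(0)), tr, cfg, roi = roi)
  der <- derive_roi(img$channels$DAPI, cfg$pixel_size_um)
  pc <- phenotype_image(img, der)
  expect_lt(abs(pc$frac_macrophage - cfg$class_fractions[["macrophage"]]), 0.05)
  expect_lt(abs(pc$frac_tcell - cfg$class_fractions[["tcell"]]), 0.05)
  expect_lt(abs(pc$frac_fibroblast - cfg$class_fractions[["fibroblast"]]), 0.05)
})

test_that("a pure-M2 macrophage scene classifies every macrophage as M2 and none as M1", {
  probs <- default_marker_probs()
  probs$macrophage <- c(CD68 = 1, iNOS = 0, Arg1 = 1, Ki67 = 0.2)
  cfg <- tiny_scene(seed = 14, class_fractions = c(macrophage = 1.0),
                    marker_probs = probs, cell_density_intercept = 300,
                    cell_density_slope = 0)
  roi <- make_roi(cfg)
  tr <- generate_cells(cfg, roi)
  img <- render_scene(particle_set(numeric(0), numeric(0), numeric(0)), tr, cfg, roi = roi)
  pc <- phenotype_image(img, roi)
  expect_gt(pc$n_macrophage, 0)
  expect_equal(pc$n_M1, 0)
  expect_equal(pc$n_M2 / pc$n_macrophage, 1.0)
})

test_that("subclass counts never exceed their parent across random scenes", {
  for (seed in 1:12) {
    cfg <- scene_config(image_size_px = c(160L, 160L), pixel_size_um = 2,
                        roi_shape = list(type = "disk", radius_um = 130),
                        n_particles = 0L, seed = seed)
    roi <- make_roi(cfg)
    tr <- generate_cells(cfg, roi)
    img <- render_scene(particle_set(numeric(0), numeric(0), numeric(0)), tr, cfg, roi = roi)
    pc <- phenotype_image(img, roi)
    expect_lte(pc$n_M1, pc$n_macrophage)
    expect_lte(pc$n_M2, pc$n_macrophage)
    expect_lte(pc$n_macrophage, pc$n_cells)
    expect_lte(pc$n_thelper, pc$n_tcell)
    expect_lte(pc$n_tcell, pc$n_cells)
  }
})

test_that("phenotyping errors name any missing channel", {
  cfg <- tiny_scene(seed = 2)
  roi <- make_roi(cfg)
  tr <- generate_cells(cfg, roi)
  img <- render_scene(particle_set(numeric(0), numeric(0), numeric(0)), tr, cfg, roi = roi)
  img$channels$CD68 <- NULL
  expect_error(phenotype_image(img, roi), "CD68")
})
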