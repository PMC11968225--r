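# Thresholding, fraction-positive, band profiles, object counts.

square_roi <- function(n = 100, px = 1) roi_mask(matrix(TRUE, n, n), px)

test_that("Otsu separates a two-level image and is invariant to monotone rescaling", {
  roi <- square_roi(80)
  ch <- matrix(10, 80, 80)
  ch[1:40, ] <- 200
  sm <- threshold_channel(ch, roi, "otsu")
  expect_gt(sm$threshold, 10); expect_lt(sm$threshold, 200)
  expect_equal(fraction_positive(sm, roi), 0.5)
  # monotone rescale (square) keeps the mask identical
  sm2 <- threshold_channel(ch^2, roi, "otsu")
  expect_identical(sm$mask, sm2$mask)
  # constant image has no Otsu threshold
  expect_error(threshold_channel(matrix(5, 80, 80), roi, "otsu"), "constant")
})

test_that("fixed thresholds behave literally", {
  roi <- square_roi(50)
  ch <- matrix(runif(2500, 0, 100), 50, 50)
  sm <- threshold_channel(ch, roi, "fixed", value = 1000)
  expect_equal(sum(sm$mask), 0)
  expect_error(threshold_channel(ch, roi, "fixed"), "requires a value")
})

test_that("a designed positive fraction is recovered after thresholding", {
  set.seed(41)
  roi <- square_roi(120)
  ch <- matrix(10 + rnorm(120^2, 0, 2), 120, 120)
  pos <- sample(length(ch), round(0.3 * length(ch)))
  ch[pos] <- 200 + rnorm(length(pos), 0, 2)
  sm <- threshold_channel(ch, roi, "otsu")
  expect_lt(abs(fraction_positive(sm, roi) - 0.3), 0.03)
  # triangle method also lands between the modes here
  smt <- threshold_channel(ch, roi, "triangle")
  expect_lt(abs(fraction_positive(smt, roi) - 0.3), 0.05)
})

test_that("fraction_positive counts literally and rejects empty regions", {
  roi <- square_roi(20)
  all_pos <- structure(list(mask = matrix(TRUE, 20, 20), stain = "s", method = "fixed",
                            threshold = 0, pixel_size_um = 1), class = "stain_mask")
  expect_equal(fraction_positive(all_pos, roi), 1.0)
  none <- all_pos; none$mask <- !none$mask
  expect_equal(fraction_positive(none, roi), 0.0)
  chk <- all_pos
  chk$mask <- outer(1:20, 1:20, function(i, j) (i + j) %% 2 == 0)
  expect_equal(fraction_positive(chk, roi), 0.5)
  expect_error(fraction_positive(all_pos, matrix(FALSE, 20, 20)), "empty")
})

test_that("band profiles are flat for uniform masks and conserve the whole-ROI fraction", {
  cfg <- tiny_scene(seed = 19)
  roi <- make_roi(cfg)
  bm <- band_map(roi, 40)
  set.seed(7)
  m <- matrix(runif(prod(dim(roi$mask))) < 0.3, nrow(roi$mask)) & roi$mask
  sm <- structure(list(mask = m, stain = "ecm", method = "fixed", threshold = 0,
                       pixel_size_um = roi$pixel_size_um), class = "stain_mask")
  prof <- band_profile(sm, bm, list(image_id = "u1"))
  npx <- prof$band_area_um2 / roi$pixel_size_um^2
  expect_true(all(abs(prof$fraction_positive - 0.3) <= 4 * sqrt(0.3 * 0.7 / npx)))
  # conservation: area-weighted band fractions reconstruct the ROI fraction exactly
  whole <- fraction_positive(sm, roi)
  expect_equal(sum(prof$fraction_positive * prof$band_area_um2) / sum(prof$band_area_um2),
               whole, tolerance = 1e-12)
})

test_that("staining confined to the edge band leaves deeper bands empty", {
  cfg <- tiny_scene(seed = 20)
  roi <- make_roi(cfg)
  bm <- band_map(roi, 50)
  m <- bm$labels == 1
  m[which(m)[seq(2, sum(m), by = 2)]] <- FALSE   # sparse positive pixels in band 1
  sm <- structure(list(mask = m, stain = "s", method = "fixed", threshold = 0,
                       pixel_size_um = roi$pixel_size_um), class = "stain_mask")
  prof <- band_profile(sm, bm)
  expect_gt(prof$fraction_positive[prof$band == 1], 0)
  expect_true(all(prof$fraction_positive[prof$band > 1] == 0))
})

test_that("a rendered radial gradient yields a negative fitted band slope", {
  cfg <- tiny_scene(seed = 29, cell_density_intercept = 900, cell_density_slope = -4)
  roi <- make_roi(cfg)
  tr <- generate_cells(cfg, roi)
  img <- render_scene(particle_set(numeric(0), numeric(0), numeric(0)), tr, cfg, roi = roi)
  sm <- threshold_channel(img$channels$DAPI, roi, "otsu", stain = "DAPI")
  prof <- band_profile(sm, band_map(roi, 30))
  fit <- lm(fraction_positive ~ mid_depth_um, data = prof)
  expect_lt(coef(fit)[["mid_depth_um"]], 0)
})

test_that("object counting filters by area and assigns by centroid", {
  m <- matrix(FALSE, 60, 60)
  m[5:11, 5:11] <- TRUE        # 49 um^2
  m[30:36, 30:36] <- TRUE      # 49 um^2
  m[50:56, 5:11] <- TRUE       # 49 um^2
  sm <- structure(list(mask = m, stain = "CD31", method = "fixed", threshold = 0,
                       pixel_size_um = 1), class = "stain_mask")
  expect_equal(count_objects(sm, min_area_um2 = 20)$count, 3)
  m2 <- m; m2[50:56, 5:11] <- FALSE; m2[50:52, 5:7] <- TRUE  # 9 um^2 blob
  sm2 <- sm; sm2$mask <- m2
  expect_equal(count_objects(sm2, min_area_um2 = 20)$count, 2)
  empty <- sm; empty$mask <- matrix(FALSE, 60, 60)
  rec <- count_objects(empty, min_area_um2 = 20)
  expect_equal(rec$count, 0); expect_equal(rec$density_per_mm2, 0)
})

test_that("8-connected labeling equals a flood-fill oracle on random masks", {
  set.seed(3)
  for (trial in 1:200) {
    m <- matrix(runif(32 * 32) < 0.3, 32, 32)
    sm <- structure(list(mask = m, stain = "s", method = "fixed", threshold = 0,
                         pixel_size_um = 1), class = "stain_mask")
    expect_equal(count_objects(sm, min_area_um2 = 0)$count,
                 oracle_component_count(m, 8))
  }
})

test_that("colocalization counts objects by pixel-overlap fraction", {
  m <- matrix(FALSE, 40, 40)
  m[5:12, 5:12] <- TRUE
  m[25:32, 25:32] <- TRUE
  a <- structure(list(mask = m, stain = "CD31", method = "fixed", threshold = 0,
                      pixel_size_um = 1), class = "stain_mask")
  # identical masks: every object colocalizes at any threshold <= 1
  expect_equal(colocalize_objects(a, a, 1)$count, count_objects(a, 20)$count)
  disj <- a; disj$mask <- matrix(FALSE, 40, 40); disj$mask[35:39, 1:5] <- TRUE
  expect_equal(colocalize_objects(a, disj, 0.25)$count, 0)
  # half-covered object: counted at 0.25, not at 0.75
  half <- a; half$mask <- matrix(FALSE, 40, 40); half$mask[5:12, 5:8] <- TRUE
  one <- a; one$mask <- matrix(FALSE, 40, 40); one$mask[5:12, 5:12] <- TRUE
  expect_equal(colocalize_objects(one, half, 0.25)$count, 1)
  expect_equal(colocalize_objects(one, half, 0.75)$count, 0)
})

test_that("core/outer object counts split by centroid region", {
  X <- matrix(seq_len(100), 100, 100); Y <- t(X)
  roi <- roi_mask((X - 50)^2 + (Y - 50)^2 <= 48^2, 2)  # disk, 96 um radius
  sp <- inner_outer_split(roi, 0.5)
  m <- matrix(FALSE, 100, 100)
  m[48:52, 48:52] <- TRUE   # centre blob -> inner
  m[10:14, 48:52] <- TRUE   # edge blob -> outer
  sm <- structure(list(mask = m, stain = "CD31", method = "fixed", threshold = 0,
                       pixel_size_um = 2), class = "stain_mask")
  rec <- count_objects(sm, min_area_um2 = 20, region = sp)
  expect_equal(rec$count[rec$region == "inner"], 1)
  expect_equal(rec$count[rec$region == "outer"], 1)
  expect_equal(rec$density_per_mm2, rec$count / (rec$area_um2 / 1e6))
})
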