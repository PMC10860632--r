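# Binarization, mask algebra, ROI handling, puncta and batch quantification.

test_that("binarize_channel handles fixed thresholds and bad input", {
  z <- volume_image(array(0, c(1, 2, 4, 4)), c(1, 1, 1), "a")
  m <- binarize_channel(z, "a", method = "fixed", fixed_value = 1)
  expect_false(any(m$data))
  const <- volume_image(array(100, c(1, 2, 4, 4)), c(1, 1, 1), "a")
  m2 <- binarize_channel(const, "a", method = "fixed", fixed_value = 50)
  expect_true(all(m2$data))
  expect_error(binarize_channel(const, "missing"), "unknown channel")
  expect_error(binarize_channel(const, "a", method = "otsu"),
               "fixed threshold")
  expect_error(binarize_channel(const, "a", method = "fixed"), "fixed_value")
})

test_that("otsu equals the exhaustive within-class-variance minimiser", {
  set.seed(42)
  # 8-bit two-Gaussian mixture, modes 20 and 200
  x <- round(c(rnorm(4000, 20, 10), rnorm(1000, 200, 15)))
  x <- pmin(pmax(x, 0), 255)
  thr <- otsu_threshold(x)
  # oracle: scan every integer cut point, minimise within-class variance
  cuts <- 0:254
  wcv <- vapply(cuts, function(c) {
    lo <- x[x <= c]; hi <- x[x > c]
    if (!length(lo) || !length(hi)) return(Inf)
    (length(lo) * mean((lo - mean(lo))^2) +
       length(hi) * mean((hi - mean(hi))^2)) / length(x)
  }, 0)
  best <- cuts[which.min(wcv)]
  # equivalence as classifiers of the data
  expect_identical(x > thr, x > best)
})

test_that("intersect_masks is correct, idempotent, and validated", {
  vs <- c(1, 1, 1)
  set.seed(1)
  a <- binary_mask(random_mask(c(5, 6, 7)), vs)
  b <- binary_mask(random_mask(c(5, 6, 7)), vs)
  co <- binary_mask(random_mask(c(5, 6, 7)), vs)
  res <- intersect_masks(list(a, b, co))
  expect_identical(sum(res$data), oracle_triple_overlap(a$data, b$data, co$data))
  # idempotence and commutativity
  expect_identical(intersect_masks(list(a, a))$data, a$data)
  expect_identical(intersect_masks(list(a, b))$data,
                   intersect_masks(list(b, a))$data)
  # disjoint -> empty
  d1 <- binary_mask(array(c(TRUE, FALSE), c(2, 1, 1)), vs)
  d2 <- binary_mask(array(c(FALSE, TRUE), c(2, 1, 1)), vs)
  expect_false(any(intersect_masks(list(d1, d2))$data))
  bad <- binary_mask(random_mask(c(5, 6, 8)), vs)
  expect_error(intersect_masks(list(a, bad)), "shape")
  bad2 <- binary_mask(random_mask(c(5, 6, 7)), c(2, 1, 1))
  expect_error(intersect_masks(list(a, bad2)), "voxel-size")
})

test_that("mask_volume is count times voxel volume", {
  m <- array(FALSE, c(4, 10, 10))
  m[seq_len(120)] <- TRUE
  expect_equal(mask_volume(binary_mask(m, c(0.5, 0.1, 0.1))), 0.6)
  expect_equal(mask_volume(binary_mask(m, c(1.0, 0.1, 0.1))), 1.2)
  expect_equal(mask_volume(binary_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1))),
               0)
})

test_that("crop_roi implements half-open um->voxel conversion", {
  v <- volume_image(array(seq_len(4 * 500 * 140), c(1, 4, 500, 140)),
                    c(2, 0.5, 0.5))
  cr <- crop_roi(v, roi_spec("LI-II", c(0, 0), c(245, 65)))
  expect_identical(dim(cr$data), c(1L, 4L, 490L, 130L))
  # full-volume ROI is the identity
  full <- crop_roi(v, roi_spec("all", c(0, 0), c(250, 70)))
  expect_identical(full$data, v$data)
  # origin floored, far edge ceiled
  cr2 <- crop_roi(v, roi_spec("off", c(0.3, 0.3), c(1, 1)))
  expect_identical(dim(cr2$data)[3:4], c(3L, 3L))
  expect_error(crop_roi(v, roi_spec("big", c(0, 0), c(251, 65))), "exceeds")
  # cropping can only lose foreground
  mfull <- binarize_channel(v, 1, method = "fixed", fixed_value = 0)
  mcrop <- binarize_channel(cr, 1, method = "fixed", fixed_value = 0)
  expect_lte(mask_volume(mcrop), mask_volume(mfull))
})

test_that("quantify_puncta counts 26-connected components with size filter", {
  arr <- array(0, c(8, 8, 8))
  arr[2:4, 2:4, 2:4] <- 200           # solid cube
  arr[7, 7, 7] <- 200                 # single voxel
  arr[6, 6, 6] <- 200                 # diagonal neighbour of the voxel above
  v <- volume_image(array(arr, c(1, 8, 8, 8)), c(1, 0.5, 0.5))
  r <- quantify_puncta(v, 1, threshold = 100)
  expect_identical(r$count, 2L)       # diagonal pair merges under 26-conn
  expect_equal(r$total_um3, 29 * 0.25)
  r2 <- quantify_puncta(v, 1, threshold = 100, min_voxels = 3)
  expect_identical(r2$count, 1L)
  expect_equal(r2$total_um3, 27 * 0.25)
  empty <- volume_image(array(0, c(1, 4, 4, 4)), c(1, 1, 1))
  r0 <- quantify_puncta(empty, 1, threshold = 1)
  expect_identical(r0$count, 0L)
  expect_identical(r0$total_um3, 0)
})

test_that("puncta results are translation invariant", {
  pp <- gen_puncta_phantom(n_puncta = 10, grid_shape = c(16, 48, 48),
                           seed = 3)
  base <- quantify_puncta(pp$volume, threshold = 100)
  # translate by 2 voxels in y into a padded array so nothing is clipped
  d <- dim(pp$volume$data)
  arr <- array(0, d + c(0, 0, 4, 0))
  arr[, , 3:(d[3] + 2), ] <- pp$volume$data
  tr <- quantify_puncta(volume_image(arr, pp$volume$voxel_size), 1,
                        threshold = 100)
  expect_identical(tr$count, base$count)
  expect_equal(tr$total_um3, base$total_um3)
})

test_that("engulfment nesting invariant holds under any threshold", {
  ph <- gen_engulfment_phantom(engulfment_phantom_spec(seed = 13))
  r <- quantify_engulfment(ph$volume)
  expect_lte(r$engulfed_um3, r$lysosome_um3)
  expect_lte(r$lysosome_um3, r$microglia_um3)
  r2 <- quantify_engulfment(ph$volume,
                            thresholds = c(microglia = 30, lysosome = 150,
                                           fiber = 80))
  expect_lte(r2$engulfed_um3, r2$lysosome_um3)
  expect_lte(r2$lysosome_um3, r2$microglia_um3)
})

test_that("batch_quantify aggregates and raises section-count QC", {
  ph <- gen_engulfment_phantom(engulfment_phantom_spec(
    blur_sigma = 0, noise_sd = 0, grid_shape = c(20, 64, 64), seed = 21))
  vols <- rep(list(ph$volume), 6)
  meta <- data.frame(animal = "m1", section = 1:6)
  rois <- list(roi_spec("upper", c(0, 0), c(6.4, 12.8)),
               roi_spec("lower", c(6.4, 0), c(6.4, 12.8)))
  bq <- batch_quantify(vols, meta, rois = rois,
                       thresholds = c(microglia = 100, lysosome = 100,
                                      fiber = 100))
  expect_identical(nrow(bq$sections), 12L)        # sections x ROIs
  expect_identical(length(bq$warnings), 0L)
  # identical sections -> per-animal mean equals the single-section value
  one <- bq$sections[bq$sections$roi == "upper", ][1, ]
  agg <- bq$animals[bq$animals$roi == "upper", ]
  expect_equal(agg$engulfed_um3, one$engulfed_um3)
  # fewer than 6 sections -> QC warning naming the animal
  expect_warning(
    bq4 <- batch_quantify(vols[1:4], data.frame(animal = "m2", section = 1:4),
                          thresholds = c(microglia = 100, lysosome = 100,
                                         fiber = 100)),
    "m2")
  expect_match(bq4$warnings, "only 4 section")
  expect_error(batch_quantify(vols[1:2], data.frame(animal = "m1")),
               "one row per volume")
  expect_error(batch_quantify(vols[1:2], data.frame(id = 1:2, section = 1:2)),
               "animal")
})
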