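# Compartment detection, the size-limit formula, geometry features,
# nearest-neighbour distances and EGFP coverage.

test_that("the size-limit formula follows its printed form exactly", {
  expect_identical(lower_size_limit(100, 96), 100 / 10^2)
  expect_identical(lower_size_limit(100, 90), 100 / 10^5)
  expect_identical(lower_size_limit(77, 77), 77)    # 10^0 = 1
  expect_error(lower_size_limit(50, 60), "exceed")
  expect_error(lower_size_limit(0, 0), "> 0")
})

test_that("an all-background scene yields no compartments", {
  sm <- make_scene(scene_spec(50, 50, background_level = 0.1))
  comps <- detect_compartments(sm$scene, "F-actin", threshold = 0.5,
                               max_compartment_area = 100, single_cell_area = 96)
  expect_equal(nrow(comps), 0)
  expect_error(detect_compartments(sm$scene, "nope", min_area = 0), "not present")
})

test_that("well-separated discs are recovered with areas near ground truth", {
  sm <- make_scene(scene_spec(260, 160, compartments = list(
    disc_spec(c(50, 60), 25), disc_spec(c(130, 80), 30), disc_spec(c(215, 50), 20)
  )))
  comps <- detect_compartments(sm$scene, "F-actin", threshold = 0.5,
                               max_compartment_area = 100, single_cell_area = 96)
  expect_equal(nrow(comps), 3)
  truth_areas <- vapply(sm$manifest$compartments, `[[`, numeric(1), "true_area_um2")
  # ids sorted by centroid row then column; match by centroid proximity
  for (i in seq_len(3)) {
    truth <- sm$manifest$compartments[[i]]
    j <- which.min((comps$centroid_x - truth$centroid_px[1])^2 +
                     (comps$centroid_y - truth$centroid_px[2])^2)
    expect_lt(abs(comps$area[j] - truth$true_area_um2) / truth$true_area_um2, 0.02)
  }
  # noiseless detection recovers the ground-truth masks exactly
  for (i in seq_len(3)) {
    truth <- sm$manifest$compartments[[i]]
    j <- which.min((comps$centroid_x - truth$centroid_px[1])^2 +
                     (comps$centroid_y - truth$centroid_px[2])^2)
    expect_identical(which(comps$mask[[j]]), as.integer(truth$true_mask_idx))
  }
})

test_that("the size filter removes components below the computed limit", {
  # two square blobs of area 0.5 and 2.0 um^2 (pixel_size 0.5 um => 2 and 8 px)
  img <- matrix(0, 30, 30)
  img[5:6, 5] <- 1          # 2 px = 0.5 um^2
  img[15:18, 15:16] <- 1    # 8 px = 2.0 um^2
  scene <- new_scene(list(nuc = img), pixel_size = 0.5)
  comps <- detect_compartments(scene, "nuc", threshold = 0.5,
                               max_compartment_area = 100, single_cell_area = 96)
  expect_equal(nrow(comps), 1)   # limit = 100 / 10^2 = 1.0 um^2
  expect_equal(comps$area, 2.0)
})

test_that("feature geometry behaves like its continuous limits", {
  g <- expand.grid(r = 1:111, c = 1:111)
  disc <- matrix((g$r - 56)^2 + (g$c - 56)^2 <= 50^2, 111, 111)
  f <- compartment_features(disc, pixel_size = 1)
  expect_gte(f$circularity, 0.95)
  expect_lte(f$circularity, 1.1)
  expect_equal(f$equivalent_radius, sqrt(f$area / pi))

  sq <- matrix(FALSE, 110, 110); sq[6:105, 6:105] <- TRUE
  fs <- compartment_features(sq, pixel_size = 1)
  expect_lt(abs(fs$circularity - pi / 4) / (pi / 4), 0.05)

  px <- matrix(FALSE, 10, 10); px[3, 7] <- TRUE
  fp <- compartment_features(px, pixel_size = 2)
  expect_equal(fp$area, 4)
  expect_equal(c(fp$centroid_x, fp$centroid_y), c(6.5 * 2, 2.5 * 2))
  expect_error(compartment_features(matrix(FALSE, 3, 3)), "empty")
})

test_that("nearest-compartment distances are pairwise minima", {
  two <- tibble::tibble(centroid_x = c(0, 100), centroid_y = c(0, 0))
  expect_equal(nearest_compartment_distance(two)$nn_distance, c(100, 100))
  one <- tibble::tibble(centroid_x = 5, centroid_y = 5)
  expect_true(is.na(nearest_compartment_distance(one)$nn_distance))
  three <- tibble::tibble(centroid_x = c(0, 10, 25), centroid_y = 0)
  expect_equal(nearest_compartment_distance(three)$nn_distance, c(10, 10, 15))
})

test_that("coverage is strict at one half", {
  img <- matrix(0, 20, 20); img[5:14, 5:14] <- 1
  egfp_none <- matrix(0, 20, 20)
  egfp_half <- matrix(0, 20, 20); egfp_half[5:14, 5:9] <- 1   # half the mask
  egfp_all <- matrix(1, 20, 20)
  scene <- new_scene(list(nuc = img, EGFP = egfp_none))
  comps <- detect_compartments(scene, "nuc", threshold = 0.5, min_area = 0)
  expect_equal(coverage_call(comps, scene, "EGFP", 0.5)$coverage_fraction, 0)
  expect_false(coverage_call(comps, scene, "EGFP", 0.5)$covered)

  scene$channels$EGFP <- egfp_half
  cc <- coverage_call(comps, scene, "EGFP", 0.5)
  expect_equal(cc$coverage_fraction, 0.5)
  expect_false(cc$covered)  # "greater than 50%" is strict

  scene$channels$EGFP <- egfp_all
  cc <- coverage_call(comps, scene, "EGFP", 0.5)
  expect_equal(cc$coverage_fraction, 1)
  expect_true(cc$covered)
})

test_that("raising the single-cell area never increases retained compartments", {
  sm <- make_scene(scene_spec(200, 120, compartments = list(
    disc_spec(c(40, 60), 10), disc_spec(c(100, 60), 18), disc_spec(c(165, 60), 25)
  )))
  # limit grows toward max_compartment_area as cell area approaches it
  retained <- vapply(c(90, 94, 96, 98, 100), function(cell) {
    nrow(detect_compartments(sm$scene, "F-actin", threshold = 0.5,
                             max_compartment_area = 3000, single_cell_area = 2990 + (cell - 90)))
  }, numeric(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("areas and distances scale with pixel size; circularity does not", {
  build <- function(p) {
    sm <- make_scene(scene_spec(140, 80, pixel_size = p, compartments = list(
      disc_spec(c(40, 40), 20 * p), disc_spec(c(100, 40), 15 * p)
    )))
    detect_compartments(sm$scene, "F-actin", threshold = 0.5, min_area = 0)
  }
  a <- build(1); b <- build(3)
  expect_equal(b$area, a$area * 9)
  expect_equal(b$nn_distance, a$nn_distance * 3)
  expect_equal(b$circularity, a$circularity)
  expect_lte(sum(a$area), 140 * 80)  # detected area cannot exceed the image
})
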