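# Inward line sampling, per-position means, alignment and length
# equalization.

make_disc_record <- function(radius = 50, size = 121, levels = c(marker = 1)) {
  sm <- make_scene(scene_spec(size, size, compartments = list(
    disc_spec(c((size + 1) / 2, (size + 1) / 2), radius,
              channel_levels = c("F-actin" = 1, levels))
  )))
  comps <- detect_compartments(sm$scene, "F-actin", threshold = 0.5, min_area = 0)
  list(scene = sm$scene, record = comps[1, ], manifest = sm$manifest)
}

test_that("a uniform channel yields a constant profile", {
  d <- make_disc_record(radius = 30, size = 81, levels = c(marker = 2))
  ps <- sample_inward(d$scene, d$record, depth = 10)
  prof <- ps$channels[["marker"]]
  # inside the disc the channel is background + 2; all lines stay inside
  expect_equal(sum(ps$skipped), 0)
  expect_true(all(abs(prof - (0.05 + 2)) < 1e-6))
  expect_equal(mean_radial_expression(ps, "marker"), 2.05, tolerance = 1e-6)
  expect_error(sample_inward(d$scene, d$record, depth = 40), "equivalent radius")
})

test_that("a linear radial ramp averages to the analytic line integral", {
  size <- 121; R <- 50
  cx <- (size + 1) / 2
  g <- expand.grid(r = 1:size, c = 1:size)
  rr <- sqrt((g$r - cx)^2 + (g$c - cx)^2)
  ramp <- matrix(rr, size, size)             # I(r) = r, in um
  mask_img <- matrix(as.numeric(rr <= R), size, size)
  scene <- new_scene(list(det = mask_img, ramp = ramp))
  comps <- detect_compartments(scene, "det", threshold = 0.5, min_area = 0)
  ps <- sample_inward(scene, comps[1, ], depth = 10)
  expected <- (R + (R - 10)) / 2            # mean of a linear ramp over depth
  profile <- rowMeans(ps$channels[["ramp"]])
  expect_lt(max(abs(profile - expected)) / expected, 0.03)
})

test_that("lines exiting a crescent are skipped, matching a containment oracle", {
  sm <- make_scene(scene_spec(141, 141, compartments = list(
    disc_spec(c(71, 71), 45, shape = "crescent")
  )))
  comps <- detect_compartments(sm$scene, "F-actin", threshold = 0.5, min_area = 0)
  rec <- comps[1, ]
  depth <- 6
  ps <- sample_inward(sm$scene, rec, depth = depth)
  expect_gt(sum(ps$skipped), 0)
  expect_lt(sum(!ps$skipped), ps$border_length)
  mask <- rec$mask[[1]]
  bt <- border_trace(mask, 1)
  oracle <- !vapply(seq_len(nrow(bt)), function(i) {
    segment_in_mask_oracle(mask, bt$x[i], bt$y[i],
                           rec$centroid_x, rec$centroid_y, depth, 1)
  }, logical(1))
  expect_equal(ps$skipped, oracle)
})

test_that("skipped positions are excluded from means, not zeroed", {
  ps <- structure(list(
    compartment = 1L,
    channels = list(m = matrix(c(1, 1, NA, 1), 4, 1)),
    skipped = c(FALSE, FALSE, TRUE, FALSE),
    angle_deg = c(0, 90, 180, 270), border_length = 4L,
    depth = 1, pixel_size = 1, equivalent_radius = 5, centroid = c(0, 0)
  ), class = "radial_profile_set")
  expect_equal(mean_radial_expression(ps, "m"), 1)
  ps$skipped <- rep(TRUE, 4)
  expect_error(mean_radial_expression(ps, "m"), "skipped")
  expect_error(mean_radial_expression(ps, "absent"), "not sampled")
})

test_that("alignment puts the alignment-channel maximum at position 1", {
  mk_ps <- function(values, n = length(values)) {
    structure(list(
      compartment = 1L,
      channels = list(CER1 = matrix(values, n, 1), other = matrix(seq_len(n), n, 1)),
      skipped = rep(FALSE, n),
      angle_deg = (seq_len(n) - 1) * 360 / n, border_length = n,
      depth = 1, pixel_size = 1, equivalent_radius = 5, centroid = c(0, 0)
    ), class = "radial_profile_set")
  }
  # max already at index 1: no shift, values unchanged at equal length
  ps <- mk_ps(c(9, 1, 2, 3, 4, 5, 6, 7))
  al <- align_and_equalize(list(ps), "CER1", target_length = 8)
  expect_equal(al$value[al$channel == "CER1"], c(9, 1, 2, 3, 4, 5, 6, 7))
  expect_equal(attr(al, "alignment")$alignment_offset, 0L)

  # max at index k: output position 1 equals former index k for every channel
  ps2 <- mk_ps(c(1, 2, 9, 3, 4, 5, 6, 7))
  al2 <- align_and_equalize(list(ps2), "CER1", target_length = 8)
  expect_equal(al2$value[al2$channel == "CER1"][1], 9)
  expect_equal(al2$value[al2$channel == "other"][1], 3)
  expect_equal(attr(al2, "alignment")$alignment_offset, 2L)

  # constant profiles resample to constants of the target length
  ps3 <- mk_ps(rep(4, 6))
  al3 <- align_and_equalize(list(ps3), "CER1", target_length = 11)
  expect_equal(al3$value[al3$channel == "CER1"], rep(4, 11))

  expect_equal(nrow(align_and_equalize(list())), 0)
})

test_that("profiles are linear in the image intensities", {
  d <- make_disc_record(radius = 25, size = 71, levels = c(marker = 1.5))
  ps1 <- sample_inward(d$scene, d$record, depth = 8)
  scaled <- d$scene
  scaled$channels$marker <- scaled$channels$marker * 3
  ps3 <- sample_inward(scaled, d$record, depth = 8)
  expect_equal(ps3$channels$marker, ps1$channels$marker * 3)
})

test_that("CER1-aligned profiles are invariant to a 90-degree scene rotation", {
  spec <- polarity_scene_spec(40, 220, radius = 30, size = 101)
  sm <- make_scene(spec)
  rot <- sm$scene
  rot$channels <- lapply(rot$channels, function(m) t(m)[, nrow(m):1, drop = FALSE])
  rot$channels <- lapply(rot$channels, function(m) matrix(m, 101, 101))
  run <- function(scene) {
    comps <- detect_compartments(scene, "F-actin", threshold = 0.5, min_area = 0)
    ps <- sample_inward(scene, comps[1, ], depth = 8)
    align_and_equalize(list(ps), "CER1", target_length = 180)
  }
  a <- run(sm$scene); b <- run(rot)
  va <- a$value[a$channel == "CER1"]
  vb <- b$value[b$channel == "CER1"]
  expect_lt(max(abs(va - vb)), 0.02 * max(va))
})

test_that("aligned peaks recover the true polar-domain angle", {
  for (theta in c(15, 123, 297)) {
    spec <- polarity_scene_spec(theta, (theta + 180) %% 360, radius = 35, size = 121)
    sm <- make_scene(spec)
    comps <- detect_compartments(sm$scene, "F-actin", threshold = 0.5, min_area = 0)
    ps <- sample_inward(sm$scene, comps[1, ], depth = 8)
    prof <- rowMeans(ps$channels[["CER1"]])
    peak_angle <- ps$angle_deg[which.max(prof)]
    step <- 360 / ps$border_length
    d <- min(abs(peak_angle - theta), 360 - abs(peak_angle - theta))
    expect_lte(d, step + 1e-9)
  }
})
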