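# Per-cell objects, haemoglobin ratios, CD34 area, focus classification,
# z-profiles and relative qPCR expression.

blob_scene <- function(n_blobs, value = 1, size = 140) {
  img <- matrix(0, size, size)
  centers <- expand.grid(r = seq(10, size - 10, by = 15),
                         c = seq(10, size - 10, by = 15))[seq_len(n_blobs), ]
  for (i in seq_len(n_blobs)) {
    img[centers$r[i] + (-1:1), centers$c[i] + (-1:1)] <- value
  }
  new_scene(list(CD43 = img, other = img * 2))
}

test_that("cell detection counts isolated objects and their mean intensities", {
  blank <- new_scene(list(CD43 = matrix(0, 20, 20)))
  expect_equal(nrow(detect_cells(blank, "CD43", threshold = 0.5)), 0)
  expect_error(detect_cells(blank, "CD34"), "not present")

  sc <- blob_scene(50, value = 3)
  cells <- detect_cells(sc, "CD43", threshold = 0.5)
  expect_equal(nrow(cells), 50)
  expect_true(all(cells$CD43 == 3))     # flat blobs: mean equals the value
  expect_true(all(cells$other == 6))
})

test_that("WT-region exclusion removes cells under the mask", {
  sc <- blob_scene(20, value = 2)
  empty_mask <- matrix(FALSE, 140, 140)
  expect_equal(nrow(detect_cells(exclude_wt_regions(sc, empty_mask), "CD43",
                                 threshold = 0.5)), 20)
  full_mask <- matrix(TRUE, 140, 140)
  expect_equal(nrow(detect_cells(exclude_wt_regions(sc, full_mask), "CD43",
                                 threshold = 0.5)), 0)
  # mask the left half: only right-half cells remain
  half_mask <- matrix(FALSE, 140, 140); half_mask[, 1:70] <- TRUE
  cells_all <- detect_cells(sc, "CD43", threshold = 0.5)
  n_right <- sum(cells_all$x > 70)
  cells_masked <- detect_cells(exclude_wt_regions(sc, half_mask), "CD43",
                               threshold = 0.5)
  expect_equal(nrow(cells_masked), n_right)
  expect_error(exclude_wt_regions(sc, matrix(FALSE, 5, 5)), "grid")
})

test_that("haemoglobin ratios normalize by the coverslip pan-Hb mean", {
  cells <- tibble::tibble(
    cell = 1:3, HbE = c(4, 2, 1), HbG = c(2, 2, 1), HbPan = c(2, 2, 2)
  )
  hb <- haemoglobin_ratios(cells)
  expect_equal(hb$eps_norm, c(2, 1, 0.5))
  expect_equal(hb$gamma_norm, c(1, 1, 0.5))
  expect_equal(hb$ratio, c(2, 1, 1))
  # equal intensities give unit ratios; scaling everything changes nothing
  scaled <- haemoglobin_ratios(dplyr::mutate(cells, HbE = HbE * 7,
                                             HbG = HbG * 7, HbPan = HbPan * 7))
  expect_equal(scaled$ratio, hb$ratio)
  expect_equal(scaled$eps_norm, hb$eps_norm)
  # zero gamma: missing ratio, reported not dropped
  z <- haemoglobin_ratios(tibble::tibble(HbE = 1, HbG = 0, HbPan = 1))
  expect_equal(nrow(z), 1)
  expect_true(is.na(z$ratio))
  expect_error(haemoglobin_ratios(tibble::tibble(HbE = 1)), "missing")
})

test_that("haemoglobin ratio medians recover the generating log-ratio", {
  mu <- 0.8   # true log2 ratio: median ratio should be 2^0.8
  set.seed(17)
  n <- 1000
  gamma <- exp(rnorm(n, 1, 0.2))
  eps <- gamma * 2^rnorm(n, mu, 0.3)
  cells <- tibble::tibble(HbE = eps, HbG = gamma, HbPan = (eps + gamma) / 2)
  hb <- haemoglobin_ratios(cells)
  expect_lt(abs(median(hb$ratio) - 2^mu) / 2^mu, 0.05)
})

test_that("CD34 coverage is a percentage of total image area", {
  blank <- new_scene(list(CD34 = matrix(0, 40, 40)))
  expect_equal(cd34_area_fraction(blank, threshold = 0.5), 0)
  full <- new_scene(list(CD34 = matrix(1, 40, 40)))
  expect_equal(cd34_area_fraction(full, threshold = 0.5), 100)
  quad <- matrix(0, 40, 40); quad[1:20, 1:20] <- 1
  expect_equal(cd34_area_fraction(new_scene(list(CD34 = quad)), threshold = 0.5), 25)
  # WT pixels are excluded from the positive area but stay in the denominator
  wt <- matrix(FALSE, 40, 40); wt[1:10, 1:20] <- TRUE
  expect_equal(cd34_area_fraction(new_scene(list(CD34 = quad)), threshold = 0.5,
                                  wt_mask = wt), 12.5)
})

make_focus_cells <- function(n, pos_a, pos_b = 0, cd43_only = 0) {
  # intensities: positive = 2, negative = 0; CD43 follows the lineage
  # markers except for the cd43_only cells, which express CD43 alone
  a <- c(rep(2, pos_a), rep(0, n - pos_a))
  b <- c(rep(0, n - pos_b), rep(2, pos_b))
  cd43 <- ifelse(a > 0 | b > 0, 2, 0)
  if (cd43_only > 0) {
    pick <- seq(n - cd43_only + 1, n)
    a[pick] <- 0; b[pick] <- 0; cd43[pick] <- 2
  }
  tibble::tibble(cell = seq_len(n), x = runif(n), y = runif(n), A = a, B = b, CD43 = cd43)
}

test_that("focus rules: boundary cases behave exactly as stated", {
  thr <- c(A = 1, B = 1, CD43 = 1)
  # 25 cells, 24 A-positive, 1 negative (and CD43-negative) -> uni-lineage(A)
  f <- classify_focus(make_focus_cells(25, 24, 0), thr)
  expect_equal(f$classification, "uni_lineage")
  expect_equal(f$markers, "A")
  # 10 A-only, 10 B-only, 5 A+B -> multi-lineage({A, B})
  cells <- tibble::tibble(
    A = c(rep(2, 10), rep(0, 10), rep(2, 5)),
    B = c(rep(0, 10), rep(2, 10), rep(2, 5)),
    CD43 = rep(2, 25), x = runif(25), y = runif(25)
  )
  f2 <- classify_focus(cells, thr)
  expect_equal(f2$classification, "multi_lineage")
  expect_setequal(strsplit(f2$markers, ",")[[1]], c("A", "B"))
  # exactly 20 cells: "more than 20" is strict
  f3 <- classify_focus(make_focus_cells(20, 20), thr)
  expect_equal(f3$classification, "unclassified")
  # a CD43-only cell vetoes the uni call
  cells4 <- make_focus_cells(25, 23, cd43_only = 2)
  f4 <- classify_focus(cells4, thr)
  expect_equal(f4$classification, "unclassified")
  expect_error(classify_focus(make_focus_cells(0, 0), thr), "empty")
})

test_that("focus classification agrees with the exhaustive rule-table oracle", {
  thr <- c(A = 1, B = 1, CD43 = 1)
  for (n in c(15, 18, 20, 21, 24, 27, 30)) {
    for (n_neg_a in 0:5) {
      for (n_pos_b in c(0, 2, 3, 5)) {
        n_pos_a <- n - n_neg_a
        # B-positive cells drawn from the A-negative ones where possible
        A <- c(rep(2, n_pos_a), rep(0, n_neg_a))
        B <- rep(0, n)
        if (n_pos_b > 0) B[seq(n, by = -1, length.out = min(n_pos_b, n))] <- 2
        CD43 <- rep(2, n)
        cells <- tibble::tibble(A = A, B = B, CD43 = CD43)
        got <- classify_focus(cells, thr)$classification
        pos <- cbind(A = A > 1, B = B > 1)
        want <- focus_rule_oracle(pos, CD43 > 1)
        expect_equal(got, want,
                     info = sprintf("n=%d neg_a=%d pos_b=%d", n, n_neg_a, n_pos_b))
      }
    }
  }
})

test_that("spatial grouping plus per-focus classification composes", {
  set.seed(5)
  field <- make_cell_field(
    60, list(A = list(positive_fraction = 1, pos_mean = 5, neg_mean = 1, sd = 0.2),
             CD43 = list(positive_fraction = 1, pos_mean = 5, neg_mean = 1, sd = 0.2)),
    cluster_centers = tibble::tibble(x = c(100, 400), y = c(100, 400), radius = 30),
    seed = 9L
  )
  grouped <- group_foci(field, link_radius = 50)
  expect_equal(length(unique(grouped$focus)), 2)
  res <- classify_foci(grouped, positivity_thresholds = c(A = 3, CD43 = 3))
  expect_equal(nrow(res), 2)
  expect_true(all(res$classification == "uni_lineage"))
})

test_that("z-profiles normalize to percent of maximum above the bottom", {
  zs <- make_zstack(list(
    list(channel = "CD34", z_center = 1, z_sd = 0, mean_intensity = 2),
    list(channel = "CD34", z_center = 2, z_sd = 0, mean_intensity = 4)
  ), n_slices = 2)
  zp <- z_distribution(zs$scene, noise_floor = 0)
  expect_equal(zp$pct_of_max, c(50, 100))
  # single nonzero slice -> [100]
  one <- make_zstack(list(list(channel = "M", z_center = 1, z_sd = 0,
                               mean_intensity = 5)), n_slices = 1)
  expect_equal(z_distribution(one$scene)$pct_of_max, 100)
  # scale invariance
  scaled <- zs$scene
  scaled$channels$CD34 <- scaled$channels$CD34 * 13
  expect_equal(z_distribution(scaled, noise_floor = 0)$pct_of_max, zp$pct_of_max)
  # bottom-index: slices below the first in-focus slice are discarded
  late <- make_zstack(list(list(channel = "M", z_center = 3, z_sd = 0,
                                mean_intensity = 2)), n_slices = 4)
  zp_late <- z_distribution(late$scene, noise_floor = 0.1)
  expect_equal(attr(zp_late, "bottom_index"), 3)
  expect_equal(zp_late$slice, c(3, 4))
  blank <- make_zstack(list(list(channel = "M", z_center = 1, z_sd = 0,
                                 mean_intensity = 0.05)), n_slices = 2)
  expect_error(z_distribution(blank$scene, noise_floor = 1), "bottom")
})

test_that("replicate z-profiles average index-wise then renormalize", {
  mk <- function(m1, m2) {
    zs <- make_zstack(list(
      list(channel = "M", z_center = 1, z_sd = 0, mean_intensity = m1),
      list(channel = "M", z_center = 2, z_sd = 0, mean_intensity = m2)
    ), n_slices = 2)
    z_distribution(zs$scene, noise_floor = 0)
  }
  # identical replicates: averaging changes nothing
  same <- average_z_profiles(list(mk(2, 4), mk(2, 4), mk(2, 4)))
  expect_equal(same$pct_of_max, c(50, 100))
  # [2,4] and [4,2]: per-replicate percentages average to (75, 75),
  # renormalized to (100, 100)
  cross <- average_z_profiles(list(mk(2, 4), mk(4, 2)))
  expect_equal(cross$pct_of_max, c(100, 100))
  expect_error(average_z_profiles(list()), "no profiles")
})

test_that("relative expression follows 2^-ddCt", {
  expect_equal(fold_change_ddct(10, 10, 10, 10), 1)
  expect_equal(fold_change_ddct(11, 10, 10, 10), 0.5)   # ddCt = 1
  expect_equal(fold_change_ddct(8, 10, 10, 10), 4)      # ddCt = -2
  expect_error(fold_change_ddct(NA, 10, 10, 10), "finite")

  ct <- tibble::tibble(
    sample = rep(c("d12", "d21"), each = 4),
    gene = rep(c("HBE1", "HBE1", "RNA18S", "RNA18S"), 2),
    ct = c(20, 20, 10, 10, 23, 23, 10, 10)
  )
  fc <- ddct_fold_changes(ct, reference_gene = "RNA18S", calibrator_sample = "d12")
  expect_equal(fc$fold_change[fc$sample == "d12"], 1)
  expect_equal(fc$fold_change[fc$sample == "d21"], 2^-3)
})
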