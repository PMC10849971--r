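# Haematopoietic quantification: per-cell objects and marker intensities,
# haemoglobin ratios, CD34 area fraction, z-stack marker distributions,
# uni-/multilineage focus classification and relative qPCR expression.

#' Detect cell objects in one channel
#'
#' Threshold + 8-connected components + size gate on the given marker
#' channel; every retained object yields one cell with its centroid and the
#' mean object intensity in every channel of the scene. The number of rows
#' is the object count used for e.g. CD43 bar charts.
#'
#' @param scene A [new_scene()] object (2D).
#' @param marker_channel Channel segmented into objects.
#' @param threshold `"otsu"` or fixed intensity.
#' @param min_area Minimum object area in micrometres squared.
#' @return Tibble: `cell`, `x`, `y`, `area`, one mean-intensity column per
#'   channel.
#' @export
detect_cells <- function(scene, marker_channel, threshold = "otsu",
                         min_area = 0) {
  ch <- scene_channel(scene, marker_channel)
  thr <- resolve_threshold(ch, threshold)
  mask <- !is.na(ch) & ch > thr
  p <- scene$pixel_size
  empty <- tibble(cell = integer(), x = numeric(), y = numeric(), area = numeric())
  for (nm in names(scene$channels)) empty[[nm]] <- numeric(0)
  if (!any(mask)) return(empty)
  labels <- label_components(mask)
  nr <- nrow(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  npx <- tabulate(lab)
  keep <- which(npx * p^2 >= min_area & npx > 0)
  if (length(keep) == 0) return(empty)
  out <- tibble(
    cell = seq_along(keep),
    x = vapply(keep, function(l) mean(cols[lab == l] - 0.5) * p, numeric(1)),
    y = vapply(keep, function(l) mean(rows[lab == l] - 0.5) * p, numeric(1)),
    area = npx[keep] * p^2
  )
  for (nm in names(scene$channels)) {
    chv <- scene$channels[[nm]][idx]
    out[[nm]] <- vapply(keep, function(l) mean(chv[lab == l], na.rm = TRUE), numeric(1))
  }
  out
}

#' Remove wild-type compartment regions from a scene
#'
#' Pixels inside the WT mask are set to missing in every channel, so they
#' are invisible to all downstream thresholding and object detection.
#'
#' @param scene A [new_scene()] object.
#' @param wt_mask Logical matrix on the same grid (`TRUE` = WT compartment).
#' @return The masked scene.
#' @export
exclude_wt_regions <- function(scene, wt_mask) {
  stopifnot(inherits(scene, "multichannel_scene"))
  d <- dim(scene$channels[[1]])
  if (!all(dim(wt_mask) == d[1:2])) abort("`wt_mask` does not match the scene's pixel grid.")
  scene$channels <- lapply(scene$channels, function(ch) {
    ch[wt_mask] <- NA_real_
    ch
  })
  scene
}

#' Haemoglobin epsilon/gamma expression ratios per cell
#'
#' Normalizes the embryonic (epsilon) and fetal (gamma) haemoglobin mean
#' object intensities by the coverslip-wide mean pan-haemoglobin object
#' intensity, and forms the per-cell epsilon/gamma ratio. Cells with zero
#' gamma intensity get a missing ratio (reported, not dropped).
#'
#' @param cells Tibble of cell objects (e.g. [detect_cells()] output).
#' @param eps_channel,gamma_channel,pan_channel Column names of the
#'   epsilon, gamma and pan-haemoglobin intensities.
#' @return `cells` with `eps_norm`, `gamma_norm` and `ratio` columns.
#' @export
haemoglobin_ratios <- function(cells, eps_channel = "HbE",
                               gamma_channel = "HbG", pan_channel = "HbPan") {
  for (col in c(eps_channel, gamma_channel, pan_channel)) {
    if (!col %in% names(cells)) abort(sprintf("column '%s' missing from `cells`.", col))
  }
  pan <- mean(cells[[pan_channel]])
  cells$eps_norm <- cells[[eps_channel]] / pan
  cells$gamma_norm <- cells[[gamma_channel]] / pan
  cells$ratio <- ifelse(cells[[gamma_channel]] == 0, NA_real_,
                        cells[[eps_channel]] / cells[[gamma_channel]])
  cells
}

#' CD34-positive area fraction of an image
#'
#' Percentage of the total (cropped) image area whose CD34 intensity exceeds
#' the threshold, with WT-compartment pixels excluded from the positive
#' count but retained in the denominator (the total image area).
#'
#' @param scene A [new_scene()] object.
#' @param cd34_channel CD34 channel name.
#' @param threshold `"otsu"` or fixed intensity.
#' @param wt_mask Optional logical matrix of WT pixels to exclude.
#' @return Percentage in `[0, 100]`.
#' @export
cd34_area_fraction <- function(scene, cd34_channel = "CD34",
                               threshold = "otsu", wt_mask = NULL) {
  ch <- scene_channel(scene, cd34_channel)
  thr <- resolve_threshold(ch, threshold)
  pos <- !is.na(ch) & ch > thr
  if (!is.null(wt_mask)) pos <- pos & !wt_mask
  100 * sum(pos) / length(ch)
}

#' Group cells into candidate foci by spatial proximity
#'
#' Single-linkage grouping: cells linked whenever closer than `link_radius`
#' form one candidate focus. This is the reproducible replacement for the
#' manual partitioning of blood islands; externally supplied groupings can
#' be passed to [classify_focus()] directly instead.
#'
#' @param cells Tibble with `x`, `y`.
#' @param link_radius Linking distance in micrometres.
#' @return `cells` with an integer `focus` column.
#' @export
group_foci <- function(cells, link_radius) {
  n <- nrow(cells)
  if (n == 0) {
    cells$focus <- integer(0)
    return(cells)
  }
  if (n == 1) {
    cells$focus <- 1L
    return(cells)
  }
  hc <- hclust(dist(cbind(cells$x, cells$y)), method = "single")
  cells$focus <- as.integer(cutree(hc, h = link_radius))
  cells
}

#' Classify one haematopoietic focus
#'
#' Applies the blood-island rules to a candidate focus:
#' \itemize{
#'   \item a focus must contain more than 20 cells (strictly); otherwise it
#'     is `unclassified`;
#'   \item \emph{uni-lineage} for marker m: fewer than 3 cells lack m, and no
#'     cell is positive only for the pan-haematopoietic progenitor marker
#'     (CD43) while negative for m;
#'   \item \emph{multi-lineage}: at least 3 cells positive for each of two or
#'     more assessed markers.
#' }
#' Uni-lineage takes precedence when exactly one marker satisfies its rule;
#' co-expression of several markers throughout the focus falls through to
#' the multi-lineage rule. The progenitor marker itself is never counted as
#' a lineage.
#'
#' @param cells Tibble of the focus's cells with one intensity column per
#'   marker.
#' @param positivity_thresholds Named numeric vector: marker -> positivity
#'   threshold (strict `>`).
#' @param assessed_markers Markers assessed for lineage (defaults to the
#'   names of `positivity_thresholds` minus the progenitor marker).
#' @param progenitor_marker Pan-haematopoietic progenitor marker column
#'   (used for the CD43-only exception; ignored if absent).
#' @param min_cells A focus must have strictly more cells than this.
#' @return One-row tibble: `n_cells`, `classification`
#'   (`"uni_lineage"`, `"multi_lineage"` or `"unclassified"`), `markers`
#'   (comma-separated), and a `positive_counts` list-column.
#' @export
classify_focus <- function(cells, positivity_thresholds,
                           assessed_markers = NULL,
                           progenitor_marker = "CD43",
                           min_cells = 20) {
  if (nrow(cells) == 0) abort("cannot classify an empty focus.")
  if (is.null(assessed_markers)) {
    assessed_markers <- setdiff(names(positivity_thresholds), progenitor_marker)
  }
  for (m in c(assessed_markers, intersect(progenitor_marker, names(positivity_thresholds)))) {
    if (!m %in% names(cells)) abort(sprintf("marker column '%s' missing from `cells`.", m))
  }
  n <- nrow(cells)
  pos <- vapply(assessed_markers,
                function(m) cells[[m]] > positivity_thresholds[[m]],
                logical(n))
  pos <- matrix(pos, nrow = n,
                dimnames = list(NULL, assessed_markers))
  pos_counts <- colSums(pos)
  has_prog <- progenitor_marker %in% names(cells) &&
    progenitor_marker %in% names(positivity_thresholds)
  prog_pos <- if (has_prog) {
    cells[[progenitor_marker]] > positivity_thresholds[[progenitor_marker]]
  } else {
    rep(FALSE, n)
  }

  result <- function(classification, markers) {
    tibble(
      n_cells = n,
      classification = classification,
      markers = paste(markers, collapse = ","),
      positive_counts = list(tibble(marker = assessed_markers,
                                    n_positive = as.integer(pos_counts)))
    )
  }
  if (n <= min_cells) return(result("unclassified", character(0)))

  uni_ok <- vapply(assessed_markers, function(m) {
    neg <- !pos[, m]
    sum(neg) < 3 && !any(prog_pos & neg)
  }, logical(1))
  multi_markers <- assessed_markers[pos_counts >= 3]
  if (sum(uni_ok) == 1) {
    result("uni_lineage", assessed_markers[uni_ok])
  } else if (length(multi_markers) >= 2) {
    result("multi_lineage", multi_markers)
  } else {
    result("unclassified", character(0))
  }
}

#' Classify every focus of a grouped cell table
#'
#' @param cells Tibble with a `focus` column (see [group_foci()]).
#' @param ... Passed to [classify_focus()].
#' @return Tibble with one row per focus (`focus` + [classify_focus()]
#'   columns).
#' @export
classify_foci <- function(cells, ...) {
  stopifnot("focus" %in% names(cells))
  ids <- sort(unique(cells$focus))
  bind_rows(lapply(ids, function(f) {
    res <- classify_focus(cells[cells$focus == f, , drop = FALSE], ...)
    res$focus <- f
    res[, c("focus", setdiff(names(res), "focus"))]
  }))
}

#' Per-slice marker distribution of a z-stack
#'
#' Computes each channel's per-slice mean pixel intensity, defines the stack
#' bottom as the lowest slice where any channel's mean exceeds the noise
#' floor (the in-focus criterion), discards slices below it, and normalizes
#' each channel to percent of its own maximum.
#'
#' @param stack A z-stack scene (3D channels).
#' @param channels Channels to profile (default: all).
#' @param noise_floor Minimum per-slice mean for the bottom criterion.
#' @return A tibble of class `z_profile`: `slice` (original index),
#'   `channel`, `mean_intensity`, `pct_of_max`; the bottom index is attached
#'   as attribute `"bottom_index"`.
#' @export
z_distribution <- function(stack, channels = NULL, noise_floor = 0) {
  stopifnot(inherits(stack, "multichannel_scene"))
  if (!scene_is_stack(stack)) abort("`stack` must contain 3D channels.")
  if (is.null(channels)) channels <- names(stack$channels)
  n_slices <- dim(stack$channels[[1]])[3]
  means <- vapply(channels, function(nm) {
    ch <- scene_channel(stack, nm)
    vapply(seq_len(n_slices), function(s) mean(ch[, , s], na.rm = TRUE), numeric(1))
  }, numeric(n_slices))
  means <- matrix(means, nrow = n_slices, dimnames = list(NULL, channels))
  in_focus <- apply(means > noise_floor, 1, any)
  if (!any(in_focus)) abort("no slice passes the bottom (in-focus) criterion.")
  bottom <- which(in_focus)[1]
  kept <- bottom:n_slices
  out <- bind_rows(lapply(channels, function(nm) {
    m <- unname(means[kept, nm])
    mx <- max(m)
    tibble(
      slice = kept, channel = nm, mean_intensity = m,
      pct_of_max = if (mx > 0) 100 * m / mx else NA_real_
    )
  }))
  class(out) <- c("z_profile", class(out))
  attr(out, "bottom_index") <- bottom
  out
}

#' Average z-profiles across replicate stacks
#'
#' Profiles are aligned at their bottom slice, the normalized percentages
#' averaged index-wise (shorter profiles contribute nothing beyond their
#' length), and the result renormalized to percent of maximum per channel.
#'
#' @param profiles List of [z_distribution()] outputs.
#' @return A `z_profile` tibble with `position` (1 = bottom), `channel`,
#'   `pct_of_max`, and `n_profiles` contributing at each position.
#' @export
average_z_profiles <- function(profiles) {
  if (length(profiles) == 0) abort("no profiles to average.")
  long <- bind_rows(lapply(seq_along(profiles), function(i) {
    pr <- profiles[[i]]
    pr %>%
      group_by(.data$channel) %>%
      mutate(position = .data$slice - min(.data$slice) + 1L, replicate = i) %>%
      ungroup()
  }))
  out <- long %>%
    group_by(.data$channel, .data$position) %>%
    summarise(
      pct_mean = mean(.data$pct_of_max, na.rm = TRUE),
      n_profiles = sum(!is.na(.data$pct_of_max)),
      .groups = "drop"
    ) %>%
    group_by(.data$channel) %>%
    mutate(pct_of_max = 100 * .data$pct_mean / max(.data$pct_mean)) %>%
    ungroup() %>%
    select("channel", "position", "pct_of_max", "n_profiles")
  class(out) <- c("z_profile", class(out))
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' \eqn{2^{-((Ct_{t,s} - Ct_{r,s}) - (Ct_{t,c} - Ct_{r,c}))}} for a target
#' gene `t` against an endogenous reference `r` (e.g. 18S rRNA), in a sample
#' `s` relative to a calibrator `c`. Vectorized.
#'
#' @param ct_target_sample,ct_ref_sample Target/reference Ct in the sample.
#' @param ct_target_calibrator,ct_ref_calibrator Same in the calibrator.
#' @return Fold change(s).
#' @export
fold_change_ddct <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  if (any(!is.finite(c(ct_target_sample, ct_ref_sample,
                       ct_target_calibrator, ct_ref_calibrator)))) {
    abort("all Ct values must be finite.")
  }
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Fold changes for a tidy Ct table
#'
#' Averages replicate Ct values per sample and gene, then applies
#' [fold_change_ddct()] against the reference gene and calibrator sample.
#'
#' @param ct Tibble with columns `sample`, `gene`, `ct`.
#' @param reference_gene Endogenous control gene.
#' @param calibrator_sample Calibrator sample name.
#' @return Tibble: `sample`, `gene`, `fold_change` (reference gene omitted).
#' @export
ddct_fold_changes <- function(ct, reference_gene, calibrator_sample) {
  for (col in c("sample", "gene", "ct")) {
    if (!col %in% names(ct)) abort(sprintf("column '%s' missing from `ct`.", col))
  }
  if (!reference_gene %in% ct$gene) abort("`reference_gene` not present in `ct`.")
  if (!calibrator_sample %in% ct$sample) abort("`calibrator_sample` not present in `ct`.")
  mean_ct <- ct %>%
    group_by(.data$sample, .data$gene) %>%
    summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- mean_ct %>%
    filter(.data$gene == reference_gene) %>%
    select("sample", ref_ct = "ct")
  cal <- mean_ct %>%
    filter(.data$sample == calibrator_sample) %>%
    select("gene", cal_ct = "ct")
  cal_ref <- ref$ref_ct[ref$sample == calibrator_sample]
  mean_ct %>%
    filter(.data$gene != reference_gene) %>%
    left_join(ref, by = "sample") %>%
    left_join(cal, by = "gene") %>%
    mutate(fold_change = fold_change_ddct(.data$ct, .data$ref_ct,
                                          .data$cal_ct, cal_ref)) %>%
    select("sample", "gene", "fold_change")
}
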