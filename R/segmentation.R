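# Compartment detection: threshold the detect channel, label 8-connected
# components, drop components below the size filter, and record per-
# compartment geometry.

#' Lower size limit of the compartment filter
#'
#' Compartments with areas close to the (manually defined) single-cell area
#' are removed using
#' \deqn{\mathrm{lower\ size\ limit} = \frac{A_{max}}
#'   {10^{(A_{max} - A_{cell})/2}}}
#' where \eqn{A_{max}} is the maximum individual compartment area and
#' \eqn{A_{cell}} the average single-cell area, both in the user's working
#' area unit. The formula is applied exactly as stated; note that for
#' realistic micrometre-squared inputs the exponent is enormous and the limit
#' correspondingly tiny, so [detect_compartments()] also accepts an absolute
#' `min_area` as a practical alternative.
#'
#' @param max_compartment_area Maximum individual compartment area.
#' @param single_cell_area Average single-cell area (> 0, <= max area).
#' @return The lower size limit, in the same unit as the inputs.
#' @export
#' @examples
#' lower_size_limit(100, 96) # 1
#' lower_size_limit(50, 50)  # 50: equal areas leave the limit at the maximum
lower_size_limit <- function(max_compartment_area, single_cell_area) {
  check_number(max_compartment_area, "max_compartment_area", min = 0, strict_min = TRUE)
  check_number(single_cell_area, "single_cell_area", min = 0, strict_min = TRUE)
  if (single_cell_area > max_compartment_area) {
    abort("`single_cell_area` must not exceed `max_compartment_area`.")
  }
  max_compartment_area / 10^((max_compartment_area - single_cell_area) / 2)
}

#' Geometric features of a single mask
#'
#' Area is the pixel count times `pixel_size^2`; the perimeter is the length
#' of the traced boundary polygon (circularly smoothed to remove the
#' digitization staircase); circularity is \eqn{4\pi A / P^2} and may
#' slightly exceed 1 on digitized discs.
#'
#' @param mask Logical matrix.
#' @param pixel_size Micrometres per pixel.
#' @return One-row tibble: `n_pixels`, `area`, `perimeter`, `circularity`,
#'   `centroid_x`, `centroid_y`, `equivalent_radius` (micrometre units).
#' @export
compartment_features <- function(mask, pixel_size = 1) {
  if (!any(mask, na.rm = TRUE)) abort("cannot compute features of an empty mask.")
  idx <- which(mask)
  nr <- nrow(mask)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  area <- length(idx) * pixel_size^2
  perim <- perimeter_px(mask) * pixel_size
  tibble(
    n_pixels = length(idx),
    area = area,
    perimeter = perim,
    circularity = 4 * pi * area / perim^2,
    centroid_x = mean(cols - 0.5) * pixel_size,
    centroid_y = mean(rows - 0.5) * pixel_size,
    equivalent_radius = sqrt(area / pi)
  )
}

#' Detect wild-type compartments in a scene
#'
#' Thresholds the detect channel (Otsu by default), labels 8-connected
#' components of the suprathreshold mask, removes components smaller than
#' [lower_size_limit()] (or, alternatively, an absolute `min_area`), and
#' returns per-compartment geometry plus nearest-compartment distances.
#' Compartment ids are stable: sorted by centroid row, then column.
#'
#' @param scene A [new_scene()] object.
#' @param detect_channel Channel to threshold (nuclear dye, F-actin or a
#'   constitutive fluorophore).
#' @param max_compartment_area,single_cell_area Size-filter inputs in
#'   micrometres squared (both required unless `min_area` is given).
#' @param threshold `"otsu"` or a fixed intensity.
#' @param min_area Optional absolute minimum area (micrometres squared) used
#'   instead of the size-limit formula.
#' @return A tibble with one row per retained compartment: `compartment`,
#'   geometry columns as in [compartment_features()], `nn_distance`
#'   (micrometres; `NA` when only one compartment), and a `mask` list-column
#'   of logical matrices. The pixel size is attached as attribute
#'   `"pixel_size"`. An all-background scene yields a zero-row tibble.
#' @export
detect_compartments <- function(scene, detect_channel,
                                max_compartment_area = NULL,
                                single_cell_area = NULL,
                                threshold = "otsu", min_area = NULL) {
  ch <- scene_channel(scene, detect_channel)
  thr <- resolve_threshold(ch, threshold)
  mask <- !is.na(ch) & ch > thr
  limit <- if (!is.null(min_area)) {
    check_number(min_area, "min_area", min = 0)
  } else {
    if (is.null(max_compartment_area) || is.null(single_cell_area)) {
      abort("supply `max_compartment_area` and `single_cell_area` (or `min_area`).")
    }
    lower_size_limit(max_compartment_area, single_cell_area)
  }

  empty <- tibble(
    compartment = integer(), n_pixels = integer(), area = numeric(),
    perimeter = numeric(), circularity = numeric(), centroid_x = numeric(),
    centroid_y = numeric(), equivalent_radius = numeric(),
    nn_distance = numeric(), mask = list()
  )
  if (!any(mask)) return(structure(empty, pixel_size = scene$pixel_size))

  labels <- label_components(mask)
  n_lab <- max(labels)
  p <- scene$pixel_size
  rows <- lapply(seq_len(n_lab), function(l) {
    m <- labels == l
    if (sum(m) * p^2 < limit) return(NULL)
    f <- compartment_features(m, p)
    f$mask <- list(m)
    f
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(structure(empty, pixel_size = p))
  out <- bind_rows(rows)
  out <- out[order(out$centroid_y, out$centroid_x), ]
  out$compartment <- seq_len(nrow(out))
  out <- nearest_compartment_distance(out)
  out <- out[, c(
    "compartment", "n_pixels", "area", "perimeter", "circularity",
    "centroid_x", "centroid_y", "equivalent_radius", "nn_distance", "mask"
  )]
  structure(out, pixel_size = p)
}

#' Nearest-compartment distances
#'
#' Adds (or recomputes) `nn_distance`: the Euclidean centroid-to-centroid
#' distance to the nearest other compartment. With a single compartment the
#' distance is missing (`NA`).
#'
#' @param records Tibble with `centroid_x`, `centroid_y`.
#' @return The tibble with an `nn_distance` column.
#' @export
nearest_compartment_distance <- function(records) {
  n <- nrow(records)
  if (n == 0) {
    records$nn_distance <- numeric(0)
    return(records)
  }
  if (n == 1) {
    records$nn_distance <- NA_real_
    return(records)
  }
  d <- as.matrix(dist(cbind(records$centroid_x, records$centroid_y)))
  diag(d) <- Inf
  records$nn_distance <- unname(apply(d, 1, min))
  records
}

#' EGFP coverage of detected compartments
#'
#' For each compartment, the coverage fraction is the share of mask pixels
#' whose EGFP intensity exceeds the threshold; a compartment is `covered`
#' when strictly more than half of its area is EGFP-positive (a fraction of
#' exactly 0.5 is not covered).
#'
#' @param records Output of [detect_compartments()] (needs the `mask`
#'   list-column).
#' @param scene The scene the compartments were detected in.
#' @param egfp_channel EGFP channel name.
#' @param egfp_threshold Positivity threshold (`"otsu"` or fixed).
#' @return `records` with `coverage_fraction` and `covered` columns.
#' @export
coverage_call <- function(records, scene, egfp_channel = "EGFP",
                          egfp_threshold = "otsu") {
  ch <- scene_channel(scene, egfp_channel)
  thr <- resolve_threshold(ch, egfp_threshold)
  frac <- vapply(records$mask, function(m) {
    v <- ch[m]
    sum(!is.na(v) & v > thr) / length(v)
  }, numeric(1))
  records$coverage_fraction <- frac
  records$covered <- frac > 0.5
  records
}
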