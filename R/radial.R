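# Radial profiling: sample marker intensity along lines drawn from each
# border point a fixed distance towards the compartment centroid, average
# per border position, then align profiles on the CER1 maximum and equalize
# lengths across compartments.

#' Ordered border trace of a compartment
#'
#' Moore-neighbour boundary of the mask, ordered along the perimeter, with
#' physical coordinates and the angular position of each border point
#' relative to the compartment centroid (degrees, counter-clockwise, 0 at
#' the +x axis).
#'
#' @param mask Logical matrix.
#' @param pixel_size Micrometres per pixel.
#' @return Tibble: `point`, `row`, `col`, `x`, `y`, `angle_deg`.
#' @export
border_trace <- function(mask, pixel_size = 1) {
  b <- trace_boundary(mask)
  x <- (b[, 2] - 0.5) * pixel_size
  y <- (b[, 1] - 0.5) * pixel_size
  f <- compartment_features(mask, pixel_size)
  tibble(
    point = seq_len(nrow(b)),
    row = b[, 1], col = b[, 2], x = x, y = y,
    angle_deg = pixel_angle_deg(x - f$centroid_x, y - f$centroid_y)
  )
}

#' Sample marker intensity inward from a compartment's border
#'
#' For every border point a straight line is drawn toward the compartment
#' centroid and each channel is sampled at 1-pixel steps (bilinear
#' interpolation) over the requested depth. Lines that would leave the
#' compartment mask (e.g. across the concave gap of a crescent) or the
#' image are skipped entirely; skipped positions carry `NA`, never 0.
#'
#' @param scene A [new_scene()] object.
#' @param record One-row tibble from [detect_compartments()] (uses `mask`,
#'   `centroid_x`, `centroid_y`, `equivalent_radius`), or a bare list with
#'   those fields.
#' @param depth Sampling depth in micrometres; must be smaller than the
#'   compartment's equivalent radius.
#' @return A `radial_profile_set`: list with `channels` (named list of
#'   `border position x depth step` matrices), `skipped` (logical), border
#'   geometry (`angle_deg`, `border_length`), `depth`, `pixel_size`,
#'   `equivalent_radius` and `compartment`.
#' @export
sample_inward <- function(scene, record, depth) {
  mask <- if (is.list(record$mask)) record$mask[[1]] else record$mask
  p <- scene$pixel_size
  eq_r <- record$equivalent_radius
  check_number(depth, "depth", min = 0, strict_min = TRUE)
  if (depth >= eq_r) {
    abort(sprintf("`depth` (%.3g um) must be smaller than the equivalent radius (%.3g um).", depth, eq_r))
  }
  bt <- border_trace(mask, p)
  n_b <- nrow(bt)
  cx <- record$centroid_x; cy <- record$centroid_y
  # unit direction toward the centroid, physical units
  dx <- cx - bt$x; dy <- cy - bt$y
  len <- sqrt(dx^2 + dy^2)
  len[len == 0] <- 1
  ux <- dx / len; uy <- dy / len
  n_steps <- floor(depth / p)
  steps <- (0:n_steps) * p  # physical distances along the line
  # positions: n_b x (n_steps + 1), in pixel units for sampling
  px <- (outer(bt$x, rep(1, length(steps))) + outer(ux, steps)) / p
  py <- (outer(bt$y, rep(1, length(steps))) + outer(uy, steps)) / p
  nr <- nrow(mask); nc <- ncol(mask)
  # containing pixel of every sample point
  ci <- floor(py) + 1L
  cj <- floor(px) + 1L
  in_img <- ci >= 1 & ci <= nr & cj >= 1 & cj <= nc
  in_mask <- matrix(FALSE, n_b, length(steps))
  in_mask[in_img] <- mask[cbind(ci[in_img], cj[in_img])]
  skipped <- !apply(in_mask, 1, all)

  channels <- lapply(scene$channels, function(ch) {
    v <- matrix(NA_real_, n_b, length(steps))
    if (any(!skipped)) {
      keep <- !skipped
      v[keep, ] <- bilinear_sample(ch, px[keep, , drop = FALSE], py[keep, , drop = FALSE])
    }
    v
  })
  structure(list(
    compartment = if (!is.null(record$compartment)) record$compartment else NA_integer_,
    channels = channels,
    skipped = skipped,
    angle_deg = bt$angle_deg,
    border_length = n_b,
    depth = depth,
    pixel_size = p,
    equivalent_radius = eq_r,
    centroid = c(cx, cy)
  ), class = "radial_profile_set")
}

#' @export
print.radial_profile_set <- function(x, ...) {
  cat(sprintf(
    "<radial_profile_set> compartment %s: %d border points (%d skipped), depth %g um\n  channels: %s\n",
    x$compartment, x$border_length, sum(x$skipped), x$depth,
    paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

# per-border-position mean profile of one channel (NA at skipped positions)
position_profile <- function(profiles, channel) {
  m <- profiles$channels[[channel]]
  if (is.null(m)) abort(sprintf("channel '%s' was not sampled.", channel))
  rowMeans(m)
}

#' Mean radial expression of a channel
#'
#' The mean over all sampled (non-skipped) border positions and depth steps —
#' the per-compartment summary used for markers quantified as a single
#' radial-average value (e.g. ISL1).
#'
#' @param profiles A `radial_profile_set`.
#' @param channel Channel name.
#' @return Scalar mean intensity.
#' @export
mean_radial_expression <- function(profiles, channel) {
  m <- profiles$channels[[channel]]
  if (is.null(m)) abort(sprintf("channel '%s' was not sampled.", channel))
  if (all(profiles$skipped)) abort("all border positions were skipped.")
  mean(m[!profiles$skipped, , drop = FALSE])
}

# circular linear interpolation of y (length n, may contain NA) onto
# target_length equally spaced positions over the same circle
resample_circular <- function(y, target_length) {
  n <- length(y)
  ok <- which(!is.na(y))
  if (length(ok) == 0) return(rep(NA_real_, target_length))
  if (length(ok) == 1) return(rep(y[ok], target_length))
  # source positions on [0, 1); wrap the first non-NA point past the end so
  # approx() can interpolate across the seam (and across NA gaps)
  xs <- (ok - 1) / n
  ys <- y[ok]
  xs <- c(xs, xs[1] + 1)
  ys <- c(ys, ys[1])
  xt <- (seq_len(target_length) - 1) / target_length
  xt_wrapped <- ifelse(xt < xs[1], xt + 1, xt)
  approx(xs, ys, xout = xt_wrapped, method = "linear", rule = 2)$y
}

#' Align profiles on the CER1 maximum and equalize lengths
#'
#' Each compartment's per-position mean profile (every channel) is shifted
#' circularly so that the alignment channel's maximum sits at position 1,
#' then resampled by linear interpolation to a common length — by default
#' the longest border recorded. Compartments lacking the alignment channel
#' are resampled without shifting. Ties at the maximum break to the lowest
#' index; `NA` (skipped) positions are interpolated across.
#'
#' @param profile_sets List of `radial_profile_set` objects.
#' @param align_channel Channel whose maximum defines position 1.
#' @param target_length Common profile length; default: longest border.
#' @return A tibble in long format: `compartment`, `channel`, `position`
#'   (1..L), `value`, with per-compartment `alignment_offset` (0-based index
#'   of the former maximum) and `source_length` attached as attribute
#'   `"alignment"` (a tibble).
#' @export
align_and_equalize <- function(profile_sets, align_channel = "CER1",
                               target_length = NULL) {
  if (length(profile_sets) == 0) {
    out <- tibble(compartment = integer(), channel = character(),
                  position = integer(), value = numeric())
    attr(out, "alignment") <- tibble(compartment = integer(),
                                     alignment_offset = integer(),
                                     source_length = integer())
    return(out)
  }
  L <- if (is.null(target_length)) {
    max(vapply(profile_sets, `[[`, numeric(1), "border_length"))
  } else target_length
  rows <- list(); align_rows <- list()
  for (ps in profile_sets) {
    prof <- lapply(names(ps$channels), function(nm) position_profile(ps, nm))
    names(prof) <- names(ps$channels)
    offset <- 0L
    if (align_channel %in% names(prof) && any(!is.na(prof[[align_channel]]))) {
      offset <- which.max(prof[[align_channel]]) - 1L  # lowest index on ties
    }
    n <- ps$border_length
    shift_idx <- ((seq_len(n) - 1L + offset) %% n) + 1L
    for (nm in names(prof)) {
      shifted <- prof[[nm]][shift_idx]
      res <- resample_circular(shifted, L)
      rows[[length(rows) + 1L]] <- tibble(
        compartment = ps$compartment, channel = nm,
        position = seq_len(L), value = res
      )
    }
    align_rows[[length(align_rows) + 1L]] <- tibble(
      compartment = ps$compartment, alignment_offset = offset, source_length = n
    )
  }
  out <- bind_rows(rows)
  attr(out, "alignment") <- bind_rows(align_rows)
  out
}
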