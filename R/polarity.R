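# Polarity calling: normalize marker profiles by cell density (F-actin),
# smooth with a circular rolling average whose half-window is one-eighth of
# the disc radius, call a marker polar when max - min of the smoothed
# profile exceeds 0.1 normalized intensity, and classify the CER1/TBXT axis.

#' Normalize a marker profile to cell density
#'
#' Pointwise division of the marker by the density (F-actin) profile;
#' `epsilon` guards against division by zero. Missing (skipped) positions
#' stay missing.
#'
#' @param marker,density Numeric circular profiles of equal length.
#' @param epsilon Small constant added to the denominator.
#' @return Normalized profile.
#' @export
normalize_to_density <- function(marker, density, epsilon = 1e-6) {
  if (length(marker) != length(density)) {
    abort("marker and density profiles must have the same length.")
  }
  marker / (density + epsilon)
}

#' Circular rolling average over one-eighth of the disc radius
#'
#' For each position the mean of all values whose arc distance along the
#' perimeter is at most `disc_radius * window_fraction` on either side, with
#' circular wrap-around (window boundaries inclusive). Profile positions are
#' assumed equally spaced around a circle of radius `disc_radius`, so the
#' half-window in index units is `floor(length(x) * window_fraction / (2*pi))`;
#' pass `half_window` directly to override. Missing values are excluded from
#' each window's mean; a window covering the whole circle returns the global
#' mean everywhere.
#'
#' @param x Numeric circular profile (length >= 3).
#' @param disc_radius Disc radius (same unit as the arc; only the ratio to
#'   the perimeter matters).
#' @param window_fraction Window half-width as a fraction of the radius.
#' @param half_window Optional half-window in index units (overrides the
#'   geometric computation).
#' @return Smoothed profile of the same length.
#' @export
rolling_average <- function(x, disc_radius = NULL, window_fraction = 1 / 8,
                            half_window = NULL) {
  n <- length(x)
  if (n < 3) abort("profile must have length >= 3.")
  if (is.null(half_window)) {
    # arc <= R * wf with n positions spanning 2*pi*R: depends only on n and wf
    half_window <- max(1L, floor(n * window_fraction / (2 * pi)))
  }
  half_window <- as.integer(half_window)
  if (2L * half_window + 1L >= n) {
    return(rep(mean(x, na.rm = TRUE), n))
  }
  offs <- -half_window:half_window
  idx0 <- seq_len(n) - 1L
  acc <- matrix(NA_real_, n, length(offs))
  for (k in seq_along(offs)) {
    acc[, k] <- x[((idx0 + offs[k]) %% n) + 1L]
  }
  rowMeans(acc, na.rm = TRUE)
}

#' Call polarity of a smoothed profile
#'
#' A marker is polar when the range (max - min) of its circular rolling
#' average strictly exceeds the threshold (0.1 normalized intensity by
#' default); a range of exactly the threshold is not polar. The peak is the
#' argmax, lowest index on ties.
#'
#' @param smoothed Smoothed circular profile (>= 1 non-missing value).
#' @param threshold Polarity threshold on the normalized-intensity range.
#' @return List: `polar` (logical), `peak_index` (1-based), `rolling_range`.
#' @export
call_polarity <- function(smoothed, threshold = 0.1) {
  if (all(is.na(smoothed))) abort("smoothed profile has no non-missing values.")
  rng <- max(smoothed, na.rm = TRUE) - min(smoothed, na.rm = TRUE)
  list(
    polar = rng > threshold,
    peak_index = which.max(smoothed),
    rolling_range = rng
  )
}

#' Classify the CER1/TBXT axis configuration
#'
#' With `d` the circular difference (TBXT - CER1) modulo 360: a TBXT peak
#' between 135 and 225 degrees away from the CER1 peak (closed interval) is
#' anti-polar; a TBXT peak within 45 degrees of the CER1 peak is syn-polar;
#' anything else is unrelated.
#'
#' @param cer1_peak_angle,tbxt_peak_angle Peak angles in degrees
#'   (vectorized).
#' @param anti_window Closed `[lo, hi]` anti-polar window on `d`.
#' @param syn_window Maximum circular separation for syn-polar.
#' @return Character vector in `{"anti_polar", "syn_polar", "unrelated"}`.
#' @export
classify_axis <- function(cer1_peak_angle, tbxt_peak_angle,
                          anti_window = c(135, 225), syn_window = 45) {
  d <- (tbxt_peak_angle - cer1_peak_angle) %% 360
  sep <- pmin(d, 360 - d)
  dplyr::case_when(
    d >= anti_window[1] & d <= anti_window[2] ~ "anti_polar",
    sep <= syn_window ~ "syn_polar",
    TRUE ~ "unrelated"
  )
}

#' Count distinct poles of a smoothed circular profile
#'
#' A pole is a local maximum of the smoothed profile exceeding
#' `min + threshold`. Two maxima count as distinct poles only when they are
#' separated by more than `min_separation` indices \emph{and} by a genuine
#' dip: the profile between them must fall at least `threshold` below the
#' weaker maximum (a prominence condition; without it, noise ripples on the
#' flank of a single pole would be counted). Two or more poles flag the
#' compartment for exclusion (ambiguous polarization).
#'
#' @param smoothed Smoothed circular profile.
#' @param threshold Height above the profile minimum a pole must reach, and
#'   the minimum dip separating distinct poles.
#' @param min_separation Minimum index separation between distinct poles
#'   (default: the rolling half-window used to smooth).
#' @return Integer number of poles.
#' @export
detect_multiple_poles <- function(smoothed, threshold = 0.1,
                                  min_separation = NULL) {
  n <- length(smoothed)
  if (is.null(min_separation)) min_separation <- max(1L, floor(n / (16 * pi)))
  v <- smoothed
  if (all(is.na(v))) return(0L)
  lo <- min(v, na.rm = TRUE)
  left <- v[c(n, seq_len(n - 1))]
  right <- v[c(2:n, 1)]
  is_max <- !is.na(v) & v >= ifelse(is.na(left), -Inf, left) &
    v >= ifelse(is.na(right), -Inf, right) & v > lo + threshold
  cand <- which(is_max)
  if (length(cand) == 0) return(0L)
  # shorter circular arc between two indices (excluding the endpoints)
  arc_min <- function(i, j) {
    d_fwd <- (j - i) %% n
    if (d_fwd <= n - d_fwd) {
      path <- ((i - 1 + seq_len(max(d_fwd - 1, 0))) %% n) + 1
    } else {
      d_bwd <- n - d_fwd
      path <- ((j - 1 + seq_len(max(d_bwd - 1, 0))) %% n) + 1
    }
    if (length(path) == 0) return(Inf)
    min(v[path], na.rm = TRUE)
  }
  ord <- cand[order(v[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord) {
    distinct <- TRUE
    for (j in accepted) {
      gap <- min((i - j) %% n, (j - i) %% n)
      if (gap <= min_separation || arc_min(i, j) > v[i] - threshold) {
        distinct <- FALSE
        break
      }
    }
    if (distinct) accepted <- c(accepted, i)
  }
  length(accepted)
}

#' Per-compartment polarity calls from radial profiles
#'
#' Runs the full polarity protocol on each compartment's radial profile set:
#' density normalization, circular rolling average, per-marker polarity
#' call, multi-pole screening and axis classification. The axis class is
#' `excluded_multi_pole` if either marker shows several poles,
#' `no_polarity` unless both markers are polar, and otherwise the
#' [classify_axis()] window call.
#'
#' @param profile_sets List of `radial_profile_set` objects (see
#'   [sample_inward()]).
#' @param markers Two marker channels: anterior then posterior
#'   (default CER1, TBXT).
#' @param density_channel Cell-density channel for normalization.
#' @param threshold Polarity threshold (normalized intensity).
#' @param window_fraction Rolling-average half-window as a fraction of the
#'   disc radius.
#' @param epsilon Guard for the density division.
#' @param exclude_multi_pole Screen out compartments with several poles?
#' @return A tibble, one row per compartment: per-marker `\*_polar`,
#'   `\*_peak_angle`, `\*_range`, `\*_n_poles` columns (prefixed `cer1_` /
#'   `tbxt_` positionally), `angular_separation_deg` and `axis_class`.
#' @export
classify_polarity <- function(profile_sets,
                              markers = c("CER1", "TBXT"),
                              density_channel = "F-actin",
                              threshold = 0.1, window_fraction = 1 / 8,
                              epsilon = 1e-6, exclude_multi_pole = TRUE) {
  stopifnot(length(markers) == 2)
  rows <- lapply(profile_sets, function(ps) {
    if (!density_channel %in% names(ps$channels)) {
      abort(sprintf("density channel '%s' absent from profile set.", density_channel))
    }
    dens <- position_profile(ps, density_channel)
    res <- list(compartment = ps$compartment)
    prefixes <- c("cer1", "tbxt")
    peaks <- numeric(2); polar <- logical(2); npoles <- integer(2)
    for (k in 1:2) {
      mk <- markers[k]
      if (!mk %in% names(ps$channels)) {
        abort(sprintf("marker channel '%s' absent from profile set.", mk))
      }
      norm <- normalize_to_density(position_profile(ps, mk), dens, epsilon)
      sm <- rolling_average(norm, window_fraction = window_fraction)
      cp <- call_polarity(sm, threshold)
      npoles[k] <- detect_multiple_poles(sm, threshold)
      peaks[k] <- ps$angle_deg[cp$peak_index]
      polar[k] <- cp$polar
      res[[paste0(prefixes[k], "_polar")]] <- cp$polar
      res[[paste0(prefixes[k], "_peak_angle")]] <- peaks[k]
      res[[paste0(prefixes[k], "_range")]] <- cp$rolling_range
      res[[paste0(prefixes[k], "_n_poles")]] <- npoles[k]
    }
    res$angular_separation_deg <- circular_separation(peaks[2], peaks[1])
    res$axis_class <- if (exclude_multi_pole && any(polar & npoles >= 2)) {
      "excluded_multi_pole"
    } else if (all(polar)) {
      classify_axis(peaks[1], peaks[2])
    } else {
      "no_polarity"
    }
    as_tibble(res)
  })
  bind_rows(rows)
}

#' Summarize polarity calls across a cohort
#'
#' Counts and fractions of marker polarity and axis classes — the tabular
#' analogue of a cohort pie chart. Axis-class fractions are computed among
#' compartments where both markers are polar; with zero calls all counts are
#' 0 and fractions missing.
#'
#' @param calls Output of [classify_polarity()].
#' @return One-row tibble of counts (`n_*`) and fractions (`frac_*`).
#' @export
summarize_polarity <- function(calls) {
  n <- nrow(calls)
  if (n == 0) {
    return(tibble(
      n = 0L, n_cer1_polar = 0L, n_tbxt_polar = 0L, n_both_polar = 0L,
      n_anti_polar = 0L, n_syn_polar = 0L, n_unrelated = 0L,
      n_no_polarity = 0L, n_excluded = 0L,
      frac_cer1_polar = NA_real_, frac_tbxt_polar = NA_real_,
      frac_anti_polar = NA_real_, frac_syn_polar = NA_real_,
      frac_unrelated = NA_real_
    ))
  }
  both <- calls$cer1_polar & calls$tbxt_polar
  n_axis <- sum(calls$axis_class %in% c("anti_polar", "syn_polar", "unrelated"))
  frac_of_axis <- function(cls) {
    if (n_axis == 0) NA_real_ else sum(calls$axis_class == cls) / n_axis
  }
  tibble(
    n = n,
    n_cer1_polar = sum(calls$cer1_polar),
    n_tbxt_polar = sum(calls$tbxt_polar),
    n_both_polar = sum(both),
    n_anti_polar = sum(calls$axis_class == "anti_polar"),
    n_syn_polar = sum(calls$axis_class == "syn_polar"),
    n_unrelated = sum(calls$axis_class == "unrelated"),
    n_no_polarity = sum(calls$axis_class == "no_polarity"),
    n_excluded = sum(calls$axis_class == "excluded_multi_pole"),
    frac_cer1_polar = sum(calls$cer1_polar) / n,
    frac_tbxt_polar = sum(calls$tbxt_polar) / n,
    frac_anti_polar = frac_of_axis("anti_polar"),
    frac_syn_polar = frac_of_axis("syn_polar"),
    frac_unrelated = frac_of_axis("unrelated")
  )
}
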