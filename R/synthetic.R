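# Synthetic-scene generators. Every generator is a pure function of its spec
# (including the seed) and returns both the artifact and a ground-truth
# manifest, so downstream stages can be validated against known truth.

#' Specify a synthetic compartment
#'
#' Describes one disc-like wild-type compartment: a baseline intensity per
#' channel inside the shape, optional angularly localized marker domains
#' (wrapped-Gaussian bumps in perimeter angle, e.g. a CER1 or TBXT pole), and
#' an optional fraction of the compartment covered by an EGFP-positive layer.
#'
#' @param centroid Numeric `(x, y)` centre in pixels.
#' @param radius Compartment radius in micrometres.
#' @param shape One of `"disc"`, `"ellipse"`, `"crescent"`.
#' @param channel_levels Named numeric vector of baseline intensities inside
#'   the shape (e.g. `c("F-actin" = 1, CER1 = 0.2)`).
#' @param polar_domains Optional list of polar domains; each element a list
#'   with `channel`, `peak_angle_deg` (stored modulo 360), `angular_width_deg`
#'   (the wrapped-Gaussian SD) and `amplitude` (added intensity at the peak).
#' @param egfp_cover_fraction Fraction of the compartment area covered by the
#'   EGFP channel (`NA` = no EGFP layer drawn for this compartment).
#' @param axis_ratio Minor/major axis ratio used when `shape = "ellipse"`.
#' @return A `disc_spec` list.
#' @export
disc_spec <- function(centroid, radius, shape = c("disc", "ellipse", "crescent"),
                      channel_levels = c("F-actin" = 1),
                      polar_domains = list(),
                      egfp_cover_fraction = NA_real_,
                      axis_ratio = 0.6) {
  shape <- match.arg(shape)
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  stopifnot(length(centroid) == 2, is.numeric(centroid))
  if (is.null(names(channel_levels)) || any(names(channel_levels) == "")) {
    abort("`channel_levels` must be a named numeric vector.")
  }
  for (pd in polar_domains) {
    stopifnot(all(c("channel", "peak_angle_deg", "angular_width_deg", "amplitude") %in% names(pd)))
    if (pd$amplitude < 0) abort("polar domain `amplitude` must be >= 0.")
    pd$peak_angle_deg <- pd$peak_angle_deg %% 360
  }
  polar_domains <- lapply(polar_domains, function(pd) {
    pd$peak_angle_deg <- pd$peak_angle_deg %% 360
    pd
  })
  structure(list(
    centroid = as.numeric(centroid), radius = radius, shape = shape,
    channel_levels = channel_levels, polar_domains = polar_domains,
    egfp_cover_fraction = egfp_cover_fraction, axis_ratio = axis_ratio
  ), class = "disc_spec")
}

#' Specify a synthetic scene
#'
#' @param width,height Image size in pixels.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param compartments List of [disc_spec()] objects.
#' @param background_level Background intensity added to every channel.
#' @param noise_sd SD of additive Gaussian noise (clipped at 0).
#' @param seed Integer seed; identical specs (including seed) generate
#'   pixel-identical scenes.
#' @param density_channel Name of the cell-density channel drawn inside every
#'   compartment (the F-actin analogue used for normalization).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width, height, pixel_size = 1, compartments = list(),
                       background_level = 0.05, noise_sd = 0, seed = 1L,
                       density_channel = "F-actin") {
  check_number(width, "width", min = 0, strict_min = TRUE)
  check_number(height, "height", min = 0, strict_min = TRUE)
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    pixel_size = pixel_size, compartments = compartments,
    background_level = background_level, noise_sd = noise_sd,
    seed = as.integer(seed), density_channel = density_channel
  ), class = "scene_spec")
}

# angle of pixel positions relative to a centre: degrees CCW (y-down grid),
# 0 at the +x axis, in [0, 360)
pixel_angle_deg <- function(dx, dy) (atan2(-dy, dx) * 180 / pi) %% 360

# logical mask of a disc_spec on a (nr, nc) pixel grid; px-unit geometry
rasterize_shape <- function(ds, nr, nc, pixel_size) {
  r_px <- ds$radius / pixel_size
  cx <- ds$centroid[1]; cy <- ds$centroid[2]
  col_x <- (seq_len(nc) - 0.5)
  row_y <- (seq_len(nr) - 0.5)
  dx <- matrix(col_x, nr, nc, byrow = TRUE) - cx
  dy <- matrix(row_y, nr, nc) - cy
  mask <- switch(ds$shape,
    disc = dx^2 + dy^2 <= r_px^2,
    ellipse = (dx / r_px)^2 + (dy / (r_px * ds$axis_ratio))^2 <= 1,
    crescent = (dx^2 + dy^2 <= r_px^2) &
      !((dx - 0.6 * r_px)^2 + dy^2 <= (0.8 * r_px)^2)
  )
  list(mask = mask, dx = dx, dy = dy, r_px = r_px)
}

wrapped_gaussian_bump <- function(angle_deg, peak_deg, width_deg, amplitude) {
  amplitude * exp(-0.5 * (circular_separation(angle_deg, peak_deg) / width_deg)^2)
}

# derived per-compartment RNG seed: independent streams so that adding a
# compartment does not perturb earlier ones
derive_seed <- function(seed, i) (as.integer(seed) %% 1000003L) * 1009L + 7919L * as.integer(i)

#' Generate a synthetic multichannel scene with ground truth
#'
#' Rasterizes each compartment on the pixel grid, adds wrapped-Gaussian polar
#' domains in perimeter angle, an EGFP cover layer where requested, a uniform
#' cell-density channel inside every compartment, and additive Gaussian noise
#' clipped at zero. The returned manifest records every true parameter:
#' per-compartment masks, areas, peak angles and the implied
#' anterior-posterior axis class.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `scene` (a [new_scene()] object) and
#'   `manifest` (a `ground_truth_manifest` list).
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$height; nc <- spec$width
  p <- spec$pixel_size
  comps <- spec$compartments

  # compartments must be separable: pairwise circumradius gap > 1 px
  if (length(comps) >= 2) {
    for (i in seq_along(comps)) for (j in seq_len(i - 1)) {
      ci <- comps[[i]]; cj <- comps[[j]]
      gap <- sqrt(sum((ci$centroid - cj$centroid)^2)) -
        (ci$radius + cj$radius) / p
      if (gap <= 1) {
        abort(sprintf("compartments %d and %d overlap or touch (gap %.2f px <= 1).", j, i, gap))
      }
    }
  }

  channel_names <- unique(c(
    spec$density_channel,
    unlist(lapply(comps, function(d) names(d$channel_levels))),
    unlist(lapply(comps, function(d) vapply(d$polar_domains, `[[`, "", "channel"))),
    if (any(!is.na(vapply(comps, `[[`, numeric(1), "egfp_cover_fraction")))) "EGFP"
  ))
  channels <- setNames(
    lapply(channel_names, function(nm) matrix(spec$background_level, nr, nc)),
    channel_names
  )

  manifest_comps <- list()
  for (i in seq_along(comps)) {
    ds <- comps[[i]]
    ras <- rasterize_shape(ds, nr, nc, p)
    mask <- ras$mask
    if (!any(mask)) abort(sprintf("compartment %d rasterizes to an empty mask.", i))
    ang <- pixel_angle_deg(ras$dx[mask], ras$dy[mask])

    levels <- ds$channel_levels
    if (!spec$density_channel %in% names(levels)) {
      levels[spec$density_channel] <- 1
    }
    for (nm in names(levels)) {
      channels[[nm]][mask] <- channels[[nm]][mask] + levels[[nm]]
    }
    peak_angles <- list()
    for (pd in ds$polar_domains) {
      bump <- wrapped_gaussian_bump(ang, pd$peak_angle_deg, pd$angular_width_deg, pd$amplitude)
      channels[[pd$channel]][mask] <- channels[[pd$channel]][mask] + bump
      peak_angles[[pd$channel]] <- pd$peak_angle_deg %% 360
    }
    if (!is.na(ds$egfp_cover_fraction)) {
      r_cov <- ras$r_px * sqrt(ds$egfp_cover_fraction)
      cov <- mask & (ras$dx^2 + ras$dy^2 <= r_cov^2)
      channels[["EGFP"]][cov] <- channels[["EGFP"]][cov] + 1
    }

    axis_class <- NA_character_
    if (all(c("CER1", "TBXT") %in% names(peak_angles))) {
      axis_class <- classify_axis(peak_angles[["CER1"]], peak_angles[["TBXT"]])
    }
    entry <- list(
      id = i,
      centroid_px = ds$centroid,
      radius_um = ds$radius,
      shape = ds$shape,
      true_area_um2 = sum(mask) * p^2,
      true_mask_idx = which(mask),
      peak_angles_deg = peak_angles
    )
    # NA-valued optional fields are omitted so manifests round-trip JSON
    if (!is.na(ds$egfp_cover_fraction)) entry$egfp_cover_fraction <- ds$egfp_cover_fraction
    if (!is.na(axis_class)) entry$true_axis_class <- axis_class
    manifest_comps[[i]] <- entry
  }

  if (spec$noise_sd > 0) {
    old <- .Random.seed_store()
    on.exit(.Random.seed_restore(old), add = TRUE)
    for (k in seq_along(channels)) {
      set.seed(derive_seed(spec$seed, k))
      channels[[k]] <- pmax(channels[[k]] + rnorm(nr * nc, sd = spec$noise_sd), 0)
    }
  }

  manifest <- structure(list(
    type = "scene", seed = spec$seed, pixel_size = p,
    width = nc, height = nr,
    compartments = manifest_comps
  ), class = "ground_truth_manifest")
  list(scene = new_scene(channels, pixel_size = p), manifest = manifest)
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic z-stack with known per-slice means
#'
#' Each channel's intensity is uniform within a slice and follows a Gaussian
#' profile over slice index (`z_sd = 0` puts all signal in `z_center`),
#' emulating layered tissue (e.g. basal Desmin, middle CD34, apical FOXA2).
#'
#' @param layers List of layers; each a list with `channel`, `z_center`
#'   (1-based slice index), `z_sd` (in slices), `mean_intensity` (peak slice
#'   mean).
#' @param n_slices Number of slices (>= 1).
#' @param width,height Slice size in pixels.
#' @param noise_sd Additive Gaussian pixel noise SD (clipped at 0).
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed.
#' @return List with `scene` (3D channels) and `manifest` holding each
#'   channel's true per-slice means.
#' @export
make_zstack <- function(layers, n_slices, width = 32, height = 32,
                        noise_sd = 0, pixel_size = 1, seed = 1L) {
  if (!is.numeric(n_slices) || n_slices < 1) abort("`n_slices` must be >= 1.")
  n_slices <- as.integer(n_slices)
  channels <- list()
  true_means <- list()
  for (ly in layers) {
    stopifnot(all(c("channel", "z_center", "z_sd", "mean_intensity") %in% names(ly)))
    s <- seq_len(n_slices)
    m <- if (ly$z_sd <= 0) {
      ifelse(s == ly$z_center, ly$mean_intensity, 0)
    } else {
      ly$mean_intensity * exp(-0.5 * ((s - ly$z_center) / ly$z_sd)^2)
    }
    arr <- array(rep(m, each = height * width), c(height, width, n_slices))
    if (is.null(channels[[ly$channel]])) {
      channels[[ly$channel]] <- arr
      true_means[[ly$channel]] <- m
    } else {
      channels[[ly$channel]] <- channels[[ly$channel]] + arr
      true_means[[ly$channel]] <- true_means[[ly$channel]] + m
    }
  }
  if (noise_sd > 0) {
    old <- .Random.seed_store()
    on.exit(.Random.seed_restore(old), add = TRUE)
    for (k in seq_along(channels)) {
      set.seed(derive_seed(seed, k))
      channels[[k]] <- pmax(channels[[k]] + rnorm(length(channels[[k]]), sd = noise_sd), 0)
    }
  }
  manifest <- structure(list(
    type = "zstack", seed = as.integer(seed), n_slices = n_slices,
    true_slice_means = true_means
  ), class = "ground_truth_manifest")
  list(scene = new_scene(channels, pixel_size = pixel_size), manifest = manifest)
}

#' Generate a synthetic cell field with per-marker intensities
#'
#' Cells receive a centroid (uniform over the field or within the given
#' cluster geometry), a true positive/negative label per marker
#' (Bernoulli with the marker's `positive_fraction`), and a Gaussian
#' intensity around the label's mean, clipped at zero.
#'
#' @param n_cells Number of cells (>= 0).
#' @param marker_model Named list: marker -> list(`positive_fraction`,
#'   `pos_mean`, `neg_mean`, `sd`).
#' @param field_size `(width, height)` of the field in micrometres.
#' @param cluster_centers Optional tibble/data frame with columns `x`, `y`,
#'   `radius`: cells are assigned round-robin to clusters and placed uniformly
#'   inside each cluster disc.
#' @param seed Integer seed.
#' @return A tibble with columns `cell`, `x`, `y`, `cluster`, one intensity
#'   column per marker and one `<marker>_positive` truth column; the
#'   ground-truth manifest is attached as attribute `"manifest"`.
#' @export
make_cell_field <- function(n_cells, marker_model, field_size = c(500, 500),
                            cluster_centers = NULL, seed = 1L) {
  if (!is.numeric(n_cells) || n_cells < 0) abort("`n_cells` must be >= 0.")
  n_cells <- as.integer(n_cells)
  for (nm in names(marker_model)) {
    mm <- marker_model[[nm]]
    if (mm$positive_fraction < 0 || mm$positive_fraction > 1) {
      abort(sprintf("positive_fraction for '%s' must be in [0, 1].", nm))
    }
    if (mm$pos_mean <= mm$neg_mean) {
      abort(sprintf("pos_mean must exceed neg_mean for marker '%s'.", nm))
    }
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 0L))
  if (is.null(cluster_centers)) {
    x <- runif(n_cells, 0, field_size[1])
    y <- runif(n_cells, 0, field_size[2])
    cl <- rep(1L, n_cells)
  } else {
    cc <- as.data.frame(cluster_centers)
    cl <- rep(seq_len(nrow(cc)), length.out = n_cells)
    theta <- runif(n_cells, 0, 2 * pi)
    rad <- cc$radius[cl] * sqrt(runif(n_cells))
    x <- cc$x[cl] + rad * cos(theta)
    y <- cc$y[cl] + rad * sin(theta)
  }
  out <- tibble(cell = seq_len(n_cells), x = x, y = y, cluster = cl)
  truth_counts <- list()
  for (k in seq_along(marker_model)) {
    nm <- names(marker_model)[k]
    mm <- marker_model[[nm]]
    set.seed(derive_seed(seed, k))
    pos <- runif(n_cells) < mm$positive_fraction
    mu <- ifelse(pos, mm$pos_mean, mm$neg_mean)
    out[[nm]] <- pmax(0, rnorm(n_cells, mean = mu, sd = mm$sd))
    out[[paste0(nm, "_positive")]] <- pos
    truth_counts[[nm]] <- sum(pos)
  }
  manifest <- structure(list(
    type = "cell_field", seed = as.integer(seed), n_cells = n_cells,
    true_positive_counts = truth_counts
  ), class = "ground_truth_manifest")
  attr(out, "manifest") <- manifest
  out
}

#' Generate three gene lists with an exactly controlled overlap design
#'
#' Builds lists `C`, `D`, `E` from a finite universe so that the exclusive
#' overlaps are realized exactly: `|(C intersect D) \ E| = A`,
#' `|(C intersect E) \ D| = B`, and `|C intersect D intersect E| = common`.
#' Remaining slots are filled with genes unique to each list.
#'
#' @param universe_size Number of genes in the universe.
#' @param sizes Named or positional numeric vector `(C, D, E)` of list sizes.
#' @param overlap_design Named or positional numeric vector
#'   `(A, B, common)`; `common` defaults to 0 when length 2.
#' @param seed Integer seed (which symbols are drawn, not the design).
#' @return List with `C`, `D`, `E` (character vectors), `universe`, and
#'   `manifest` recording the realized overlaps.
#' @export
make_gene_lists <- function(universe_size, sizes, overlap_design, seed = 1L) {
  sizes <- as.integer(sizes)
  if (length(overlap_design) == 2) overlap_design <- c(overlap_design, 0)
  od <- as.integer(overlap_design)
  nC <- sizes[1]; nD <- sizes[2]; nE <- sizes[3]
  A <- od[1]; B <- od[2]; common <- od[3]
  if (any(c(nC, nD, nE) <= 0)) abort("list sizes must be positive.")
  if (any(od < 0)) abort("overlap design counts must be >= 0.")
  if (A + B + common > nC) abort("infeasible design: |A| + |B| + |common| exceeds |C|.")
  if (A + common > nD) abort("infeasible design: |A| + |common| exceeds |D|.")
  if (B + common > nE) abort("infeasible design: |B| + |common| exceeds |E|.")
  n_distinct <- nC + nD + nE - A - B - 2L * common
  if (n_distinct > universe_size) {
    abort(sprintf(
      "infeasible design: |C union D union E| = %d exceeds universe_size = %d.",
      n_distinct, universe_size
    ))
  }
  universe <- sprintf("g%05d", seq_len(universe_size))
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 0L))
  pool <- sample(universe, n_distinct)
  take <- function(n) {
    out <- head(pool, n)
    pool <<- tail(pool, length(pool) - n)
    out
  }
  g_common <- take(common)
  g_A <- take(A)              # in C and D, not E
  g_B <- take(B)              # in C and E, not D
  g_C <- take(nC - A - B - common)
  g_D <- take(nD - A - common)
  g_E <- take(nE - B - common)
  C <- c(g_common, g_A, g_B, g_C)
  D <- c(g_common, g_A, g_D)
  E <- c(g_common, g_B, g_E)
  manifest <- structure(list(
    type = "gene_lists", seed = as.integer(seed),
    universe_size = as.integer(universe_size),
    sizes = c(C = nC, D = nD, E = nE),
    realized = c(
      A = length(setdiff(intersect(C, D), E)),
      B = length(setdiff(intersect(C, E), D)),
      common = length(intersect(intersect(C, D), E))
    )
  ), class = "ground_truth_manifest")
  list(C = C, D = D, E = E, universe = universe, manifest = manifest)
}

#' Simulate a cohort of compartments with known axis configurations
#'
#' Generates `n` single-compartment scenes whose CER1/TBXT peak separations
#' are drawn from `separations` (balanced, in order), with the CER1 peak
#' angle uniform on the circle and compartment radii uniform over
#' `radius_range`. The returned truth table records each compartment's true
#' peak angles and the axis class implied by the classification windows —
#' the ground truth for polarity-recovery benchmarking.
#'
#' @param n Number of compartments.
#' @param separations True TBXT-CER1 separations (degrees) cycled over the
#'   cohort.
#' @param amplitude Polar-domain peak amplitude (a.u.; the polarity
#'   threshold is 0.1 on the density-normalized scale).
#' @param noise_sd Additive Gaussian noise SD.
#' @param radius_range Compartment radius range in micrometres.
#' @param scene_size Scene edge length in pixels.
#' @param seed Integer seed.
#' @return List with `scenes` (each a [make_scene()] result) and `truth`
#'   (tibble: `id`, `separation`, `cer1_angle`, `tbxt_angle`, `radius`,
#'   `true_class`).
#' @export
simulate_polarity_cohort <- function(n, separations = c(0, 30, 90, 180),
                                     amplitude = 1, noise_sd = 0.1,
                                     radius_range = c(25, 40),
                                     scene_size = 121, seed = 1L) {
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 0L))
  sep <- rep_len(separations, n)
  cer1 <- runif(n, 0, 360)
  tbxt <- (cer1 + sep) %% 360
  radius <- runif(n, radius_range[1], radius_range[2])
  scenes <- lapply(seq_len(n), function(i) {
    make_scene(scene_spec(
      scene_size, scene_size,
      compartments = list(disc_spec(
        c((scene_size + 1) / 2, (scene_size + 1) / 2), radius[i],
        channel_levels = c("F-actin" = 1, CER1 = 0.2, TBXT = 0.2),
        polar_domains = list(
          list(channel = "CER1", peak_angle_deg = cer1[i],
               angular_width_deg = 25, amplitude = amplitude),
          list(channel = "TBXT", peak_angle_deg = tbxt[i],
               angular_width_deg = 25, amplitude = amplitude)
        )
      )),
      background_level = 0.02, noise_sd = noise_sd,
      seed = derive_seed(seed, i)
    ))
  })
  truth <- tibble(
    id = seq_len(n), separation = sep,
    cer1_angle = cer1 %% 360, tbxt_angle = tbxt,
    radius = radius,
    true_class = classify_axis(cer1, tbxt)
  )
  list(scenes = scenes, truth = truth)
}

#' Write / read a ground-truth manifest as JSON
#'
#' Manifests round-trip losslessly: `read_manifest(write_manifest(m, f))`
#' equals `m`.
#'
#' @param manifest A `ground_truth_manifest`.
#' @param path File path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` returns
#'   the manifest.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(m, class = "ground_truth_manifest")
}
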