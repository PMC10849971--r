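# Independent oracles and fixture builders used across the suite. Oracles
# are deliberately naive (enumeration, brute force) and share no code with
# the implementation paths they check.

# exact upper-tail hypergeometric probability by term-wise enumeration of
# binomial coefficient ratios: P(X >= k), X ~ Hypergeom(N, n_a, n_b)
hyper_tail_oracle <- function(N, n_a, n_b, k) {
  i <- max(0, n_a + n_b - N):min(n_a, n_b)
  terms <- choose(n_a, i) * choose(N - n_a, n_b - i) / choose(N, n_b)
  sum(terms[i >= k])
}

# BH step-up by the definition: sort ascending, q_(i) = min_{j >= i} p_(j) m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# focus classification by a literal reading of the blood-island rules,
# written as an explicit rule table over count summaries
focus_rule_oracle <- function(pos, prog_pos, min_cells = 20) {
  n <- nrow(pos)
  markers <- colnames(pos)
  if (n <= min_cells) return("unclassified")
  uni <- character(0)
  for (m in markers) {
    n_neg <- sum(!pos[, m])
    cd43_only <- any(prog_pos & !pos[, m])
    if (n_neg < 3 && !cd43_only) uni <- c(uni, m)
  }
  multi <- markers[colSums(pos) >= 3]
  if (length(uni) == 1) "uni_lineage"
  else if (length(multi) >= 2) "multi_lineage"
  else "unclassified"
}

# brute-force test of whether the inward segment from a border point stays
# inside the mask: dense sub-pixel stepping, containment checked per point
segment_in_mask_oracle <- function(mask, x0, y0, cx, cy, depth, pixel_size,
                                   step = 0.25) {
  len <- sqrt((cx - x0)^2 + (cy - y0)^2)
  if (len == 0) return(TRUE)
  ux <- (cx - x0) / len
  uy <- (cy - y0) / len
  n_steps <- floor(depth / pixel_size)
  for (t in (0:n_steps) * pixel_size) {
    px <- (x0 + ux * t) / pixel_size
    py <- (y0 + uy * t) / pixel_size
    i <- floor(py) + 1L
    j <- floor(px) + 1L
    if (i < 1 || i > nrow(mask) || j < 1 || j > ncol(mask) || !mask[i, j]) {
      return(FALSE)
    }
  }
  TRUE
}

# one centred disc with CER1/TBXT poles; the standard polarity fixture
polarity_scene_spec <- function(cer1_angle, tbxt_angle, radius = 35,
                                amplitude = 1, noise_sd = 0, seed = 1L,
                                size = 160, width_deg = 25) {
  scene_spec(
    size, size,
    compartments = list(disc_spec(
      c(size / 2, size / 2), radius,
      channel_levels = c("F-actin" = 1, CER1 = 0.2, TBXT = 0.2),
      polar_domains = list(
        list(channel = "CER1", peak_angle_deg = cer1_angle,
             angular_width_deg = width_deg, amplitude = amplitude),
        list(channel = "TBXT", peak_angle_deg = tbxt_angle,
             angular_width_deg = width_deg, amplitude = amplitude)
      )
    )),
    background_level = 0.02, noise_sd = noise_sd, seed = seed
  )
}

# run the whole polarity chain on one synthetic compartment
polarity_call_for <- function(spec, depth = 8, ...) {
  sm <- make_scene(spec)
  comps <- detect_compartments(sm$scene, "F-actin", min_area = 20)
  ps <- sample_inward(sm$scene, comps[1, ], depth = depth)
  classify_polarity(list(ps), ...)
}

expect_manifest_equal <- function(a, b) {
  # JSON round-trips may change integer to double; compare numerically
  norm <- function(x) {
    if (is.list(x)) lapply(x, norm)
    else if (is.numeric(x)) as.numeric(x)
    else x
  }
  testthat::expect_equal(norm(unclass(a)), norm(unclass(b)))
}
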