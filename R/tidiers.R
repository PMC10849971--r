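# broom-style views of fitted result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Jaccard-difference score
#'
#' @param x A `jaccard_diff` object.
#' @param ... Unused.
#' @return One-row tibble: `j1`, `j2`, `delta`, `empirical_p`, `score`,
#'   `n_reps`.
#' @export
tidy.jaccard_diff <- function(x, ...) {
  tibble(
    j1 = x$j1, j2 = x$j2, delta = x$delta,
    empirical_p = x$empirical_p, score = x$score, n_reps = x$n_reps
  )
}

#' Glance at a Jaccard-difference score
#'
#' @param x A `jaccard_diff` object.
#' @param ... Unused.
#' @return One-row tibble with the statistic, its null summary and sizes.
#' @export
glance.jaccard_diff <- function(x, ...) {
  tibble(
    delta = x$delta, empirical_p = x$empirical_p, score = x$score,
    null_mean = mean(x$null_deltas), null_sd = stats::sd(x$null_deltas),
    n_reps = x$n_reps, genome_size = x$genome_size,
    n_query = x$sizes[["C"]], n_ref1 = x$sizes[["D"]], n_ref2 = x$sizes[["E"]]
  )
}
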