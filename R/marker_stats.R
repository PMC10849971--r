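# Marker-gene-list similarity statistics: hypergeometric overrepresentation
# of pairwise list overlap (with Benjamini-Hochberg correction across a
# comparison family) and the Jaccard-difference statistic j2 - j1 with an
# empirical random-sampling null.

dedup_genes <- function(x, name = NULL) {
  x <- as.character(x)
  x <- x[!is.na(x) & x != ""]
  unique(x)
}

#' Upper-tail hypergeometric probability of a list overlap
#'
#' `P(X >= k)` for `X ~ Hypergeometric(universe_size, n_a, n_b)`: the chance
#' of at least `k` shared genes between random lists of `n_a` and `n_b`
#' genes. Evaluated in log space for numerical stability. Vectorized over
#' `k`.
#'
#' @param k Observed overlap(s).
#' @param n_a,n_b List sizes.
#' @param universe_size Universe size.
#' @return Upper-tail probability (same length as `k`).
#' @export
hypergeom_tail <- function(k, n_a, n_b, universe_size) {
  pmin(1, exp(phyper(k - 1, n_a, universe_size - n_a, n_b,
                     lower.tail = FALSE, log.p = TRUE)))
}

#' Hypergeometric overrepresentation test of two gene lists
#'
#' Upper-tail probability of observing at least the seen overlap `k` between
#' two lists drawn from a universe of `universe_size` genes — equivalent to a
#' one-tailed Fisher's exact test. The tail is computed in log space
#' (`stats::phyper(log.p = TRUE)`) for numerical stability.
#'
#' @param list_a,list_b Character vectors of gene symbols (duplicates
#'   removed).
#' @param universe_size Number of genes in the universe; must be at least
#'   `|A union B|`.
#' @param label_a,label_b Labels carried into the result.
#' @return One-row tibble: `label_a`, `label_b`, `n_a`, `n_b`, `overlap`,
#'   `universe_size`, `p_value`.
#' @export
hypergeom_overlap_test <- function(list_a, list_b, universe_size,
                                   label_a = "A", label_b = "B") {
  a <- dedup_genes(list_a, "list_a")
  b <- dedup_genes(list_b, "list_b")
  check_number(universe_size, "universe_size", min = 1)
  n_union <- length(union(a, b))
  if (universe_size < n_union) {
    abort(sprintf(
      "universe_size (%d) is smaller than |A union B| (%d).",
      universe_size, n_union
    ))
  }
  k <- length(intersect(a, b))
  tibble(
    label_a = label_a, label_b = label_b,
    n_a = length(a), n_b = length(b), overlap = k,
    universe_size = as.integer(universe_size),
    p_value = hypergeom_tail(k, length(a), length(b), universe_size)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, returned in input
#' order and clipped at 1.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

# j1/j2 and delta on index sets; genome positions 1..G
jaccard_delta <- function(inC, inD, inE, overlap = c("unique", "plain")) {
  overlap <- match.arg(overlap)
  if (overlap == "unique") {
    nA <- sum(inC & inD & !inE)
    nB <- sum(inC & inE & !inD)
  } else {
    nA <- sum(inC & inD)
    nB <- sum(inC & inE)
  }
  j1 <- nA / sum(inC | inD)
  j2 <- nB / sum(inC | inE)
  c(j1 = j1, j2 = j2, delta = j2 - j1)
}

#' Jaccard-difference score with an empirical sampling null
#'
#' For a query marker list `C` and two reference lists `D` and `E`, the
#' exclusive overlaps are `A = (C intersect D) \ E` and
#' `B = (C intersect E) \ D`; the Jaccard similarity indices are
#' `j1 = |A| / |C union D|` and `j2 = |B| / |C union E|`, and the statistic
#' is `delta = j2 - j1`. Significance comes from an empirical null: `n_reps`
#' random draws of three size-matched gene sets from the genome, recomputing
#' `delta` each time. The empirical p-value uses the add-one estimator
#' `(1 + #{delta_null >= delta_obs}) / (n_reps + 1)` (ties count toward the
#' tail), so it is never zero and the reported score `-log10(p)` is finite.
#'
#' @param C,D,E Character vectors of gene symbols (query, reference 1,
#'   reference 2); all must be subsets of `genome`.
#' @param genome Character vector: the universe sampled for the null.
#' @param n_reps Number of null replicates (>= 1).
#' @param seed Optional integer seed for the null draws.
#' @param overlap `"unique"` (exclusive overlaps, the default) or
#'   `"plain"` (`A = C intersect D`, `B = C intersect E`) for sensitivity
#'   analysis.
#' @return An object of class `jaccard_diff` with fields `j1`, `j2`,
#'   `delta`, `empirical_p`, `score` (`-log10(p)`), `null_deltas`,
#'   `n_reps`, `seed`, `sizes`, `overlap`. Use [tidy()] / [glance()] for a
#'   tibble view.
#' @export
jaccard_diff_score <- function(C, D, E, genome, n_reps = 999, seed = NULL,
                               overlap = c("unique", "plain")) {
  overlap <- match.arg(overlap)
  C <- dedup_genes(C); D <- dedup_genes(D); E <- dedup_genes(E)
  genome <- dedup_genes(genome)
  G <- length(genome)
  for (nm in c("C", "D", "E")) {
    s <- get(nm)
    if (length(s) == 0) abort(sprintf("list %s is empty.", nm))
    if (length(s) > G) abort(sprintf("list %s is larger than the genome.", nm))
    if (!all(s %in% genome)) abort(sprintf("list %s contains genes outside the genome.", nm))
  }
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  inC <- genome %in% C
  inD <- genome %in% D
  inE <- genome %in% E
  obs <- jaccard_delta(inC, inD, inE, overlap)

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nC <- length(C); nD <- length(D); nE <- length(E)
  null_deltas <- vapply(seq_len(n_reps), function(r) {
    iC <- iD <- iE <- logical(G)
    iC[sample.int(G, nC)] <- TRUE
    iD[sample.int(G, nD)] <- TRUE
    iE[sample.int(G, nE)] <- TRUE
    jaccard_delta(iC, iD, iE, overlap)[["delta"]]
  }, numeric(1))
  p <- (1 + sum(null_deltas >= obs[["delta"]])) / (n_reps + 1)
  structure(list(
    j1 = obs[["j1"]], j2 = obs[["j2"]], delta = obs[["delta"]],
    empirical_p = p, score = -log10(p),
    null_deltas = null_deltas, n_reps = as.integer(n_reps),
    seed = seed, sizes = c(C = nC, D = nD, E = nE),
    genome_size = G, overlap = overlap
  ), class = "jaccard_diff")
}

#' @export
print.jaccard_diff <- function(x, ...) {
  cat(sprintf(
    "<jaccard_diff> j1 = %.4f, j2 = %.4f, delta = %.4f\n  empirical p = %.4g (R = %d), score = -log10(p) = %.3f\n",
    x$j1, x$j2, x$delta, x$empirical_p, x$n_reps, x$score
  ))
  invisible(x)
}

#' Pairwise hypergeometric comparison of marker-list collections
#'
#' Tests every query list against every reference list and applies one
#' Benjamini-Hochberg family across the whole matrix. The `-log10(q)`
#' column feeds heatmap rendering directly.
#'
#' @param query_lists,reference_lists Named lists of character vectors.
#' @param universe_size Universe size shared by all tests.
#' @return A tibble of class `overlap_matrix`: `query`, `reference`,
#'   `n_query`, `n_reference`, `overlap`, `p_value`, `q_value`,
#'   `neg_log10_q`.
#' @export
pairwise_comparison_matrix <- function(query_lists, reference_lists,
                                       universe_size) {
  if (length(query_lists) == 0 || length(reference_lists) == 0) {
    abort("`query_lists` and `reference_lists` must be non-empty.")
  }
  if (is.null(names(query_lists))) names(query_lists) <- paste0("Q", seq_along(query_lists))
  if (is.null(names(reference_lists))) names(reference_lists) <- paste0("R", seq_along(reference_lists))
  grid <- expand.grid(query = names(query_lists),
                      reference = names(reference_lists),
                      stringsAsFactors = FALSE)
  res <- bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    q <- grid$query[i]; r <- grid$reference[i]
    t <- hypergeom_overlap_test(query_lists[[q]], reference_lists[[r]],
                                universe_size, label_a = q, label_b = r)
    tibble(query = q, reference = r, n_query = t$n_a, n_reference = t$n_b,
           overlap = t$overlap, p_value = t$p_value)
  }))
  res$q_value <- bh_adjust(res$p_value)
  res$neg_log10_q <- -log10(res$q_value)
  class(res) <- c("overlap_matrix", class(res))
  res
}
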