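#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric test of the overlap between two gene sets
#' drawn from a common universe: p = P(X >= observed overlap) for
#' X ~ Hypergeometric(N = |universe|, K = |set_a|, n = |set_b|). The tail
#' is evaluated in log space (via `phyper(log.p = TRUE)`), so p-values at
#' the 1e-30 scale typical of transcriptome-sized universes are exact to
#' double precision. Fold enrichment is observed / expected overlap,
#' expected = |set_a| * |set_b| / |universe|.
#'
#' @param set_a,set_b [gene_set()] objects; must be subsets of `universe`.
#' @param universe [gene_set()] defining the sampling frame.
#' @return Object of class `overlap_result`: list with `universe_size`,
#'   `set_a_size`, `set_b_size`, `overlap`, `expected`,
#'   `fold_enrichment`, `p_upper`, `log_p_upper` (natural log).
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  stopifnot(inherits(set_a, "gene_set"), inherits(set_b, "gene_set"),
            inherits(universe, "gene_set"))
  offenders <- c(setdiff(set_a$members, universe$members),
                 setdiff(set_b$members, universe$members))
  if (length(offenders))
    input_error("sets not subsets of universe; offenders: %s",
                paste(utils::head(unique(offenders), 10), collapse = ", "))
  N <- length(universe$members)
  K <- length(set_a$members)
  n <- length(set_b$members)
  k <- length(intersect(set_a$members, set_b$members))
  log_p <- stats::phyper(k - 1L, K, N - K, n,
                         lower.tail = FALSE, log.p = TRUE)
  expected <- K * n / N
  structure(list(universe_size = N, set_a_size = K, set_b_size = n,
                 overlap = k, expected = expected,
                 fold_enrichment = if (expected > 0) k / expected else NA_real_,
                 p_upper = exp(log_p), log_p_upper = log_p,
                 set_a = set_a$name, set_b = set_b$name),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Hypergeometric overlap: '%s' (n=%d) x '%s' (n=%d) in universe of %d\n",
              x$set_a, x$set_a_size, x$set_b, x$set_b_size, x$universe_size))
  cat(sprintf("  overlap = %d (expected %.2f, fold enrichment %.2f)\n",
              x$overlap, x$expected, x$fold_enrichment))
  cat(sprintf("  upper-tail p = %.4g\n", x$p_upper))
  invisible(x)
}
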