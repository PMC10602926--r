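#' Predicted per-mRNA binding score
#'
#' Aggregates a transcript's retained sites into one predicted binding
#' score: the sum over sites of site score times the model's UTR-location
#' weight. The aggregate is additive over disjoint site sets and is 0 iff
#' the profile has no sites.
#'
#' @param profile an `lre_profile` from [scan_transcript()].
#' @param model the [lre_scoring_model()] the profile was built under.
#' @return One-row data frame: `transcript_id`, `value`.
#' @export
predicted_binding_score <- function(profile, model = lre_scoring_model()) {
  s <- profile$sites
  v <- if (nrow(s) == 0L) 0 else
    sum(s$score * unname(model$utr_weights[s$utr_kind]))
  data.frame(transcript_id = profile$transcript_id, value = v)
}

#' Binding scores for a list of profiles
#'
#' @param profiles list of `lre_profile` objects.
#' @inheritParams predicted_binding_score
#' @return Data frame with one row per transcript: `transcript_id`,
#'   `value`.
#' @export
binding_scores <- function(profiles, model = lre_scoring_model()) {
  out <- do.call(rbind, lapply(profiles, predicted_binding_score, model = model))
  rownames(out) <- NULL
  out
}

#' Relate binding scores to RIP-seq enrichment
#'
#' Joins per-mRNA predicted binding scores with RIP-seq log2 enrichment,
#' restricts to transcripts enriched at least `min_fold`-fold
#' (`log2_enrichment >= log2(min_fold)`), and reports both Pearson and
#' Spearman correlations with two-sided p-values. The returned table is
#' plotting-ready (one point per retained transcript).
#'
#' @param scores data frame (`transcript_id`, `value`) from
#'   [binding_scores()].
#' @param rip data frame (`transcript_id`, `log2_enrichment`), one row per
#'   transcript.
#' @param min_fold minimum RIP enrichment in linear fold units (default 4,
#'   i.e. log2 enrichment >= 2).
#' @return Object of class `rip_scatter`: list with `table` (columns
#'   `transcript_id`, `binding_score`, `log2_enrichment`), `pearson` and
#'   `spearman` (each `list(estimate, p.value)`), `min_fold`, `n`.
#' @export
rip_scatter <- function(scores, rip, min_fold = 4) {
  if (min_fold <= 0) input_error("min_fold must be positive")
  if (anyDuplicated(rip$transcript_id))
    input_error("duplicate transcript ids in RIP table")
  tab <- merge(
    data.frame(transcript_id = scores$transcript_id,
               binding_score = scores$value),
    rip[, c("transcript_id", "log2_enrichment")],
    by = "transcript_id")
  tab <- tab[tab$log2_enrichment >= log2(min_fold), , drop = FALSE]
  if (nrow(tab) == 0L)
    input_error("no transcripts pass the %g-fold enrichment filter", min_fold)
  tab <- tab[order(tab$transcript_id), ]
  rownames(tab) <- NULL
  ct <- function(method) {
    if (nrow(tab) < 3L || stats::sd(tab$binding_score) == 0 ||
        stats::sd(tab$log2_enrichment) == 0)
      return(list(estimate = NA_real_, p.value = NA_real_))
    h <- suppressWarnings(
      stats::cor.test(tab$binding_score, tab$log2_enrichment,
                      method = method, exact = FALSE))
    list(estimate = unname(h$estimate), p.value = h$p.value)
  }
  structure(list(table = tab,
                 pearson = ct("pearson"), spearman = ct("spearman"),
                 min_fold = min_fold, n = nrow(tab)),
            class = "rip_scatter")
}

#' @export
print.rip_scatter <- function(x, ...) {
  cat(sprintf("Binding score vs RIP enrichment (>= %g-fold): n = %d\n",
              x$min_fold, x$n))
  cat(sprintf("  Pearson r  = %+.3f (p = %.3g)\n",
              x$pearson$estimate, x$pearson$p.value))
  cat(sprintf("  Spearman rho = %+.3f (p = %.3g)\n",
              x$spearman$estimate, x$spearman$p.value))
  invisible(x)
}

#' @export
plot.rip_scatter <- function(x, ...) {
  plot(x$table$binding_score, x$table$log2_enrichment,
       xlab = "predicted binding score",
       ylab = "RIP-seq enrichment (log2)",
       pch = 16, col = grDevices::adjustcolor("grey30", 0.6), ...)
  invisible(x)
}
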