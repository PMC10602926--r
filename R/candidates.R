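#' Gene set
#'
#' A named set of gene/transcript identifiers in the same namespace as the
#' scan. Duplicates are dropped.
#'
#' @param name label for reports.
#' @param members character vector of identifiers.
#' @return Object of class `gene_set` (list with `name`, `members`).
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' Discovery-pipeline configuration
#'
#' @param min_rip_fold minimum RIP enrichment (linear fold; default 4).
#' @param min_lre_count minimum number of counted sites across both UTRs
#'   (default 2, matching the requirement that repression needs at least
#'   two elements).
#' @param counted_categories which site categories count toward
#'   `min_lre_count` (default all four).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_rip_fold = 4, min_lre_count = 2L,
                            counted_categories = c("minimal", "weak",
                                                   "medium", "strong")) {
  if (min_rip_fold <= 0) input_error("min_rip_fold must be positive")
  min_lre_count <- as.integer(min_lre_count)
  if (min_lre_count < 1L) input_error("min_lre_count must be >= 1")
  counted_categories <- match.arg(counted_categories,
                                  c("minimal", "weak", "medium", "strong"),
                                  several.ok = TRUE)
  structure(list(min_rip_fold = min_rip_fold,
                 min_lre_count = min_lre_count,
                 counted_categories = counted_categories),
            class = "pipeline_config")
}

#' Discover candidate target mRNAs
#'
#' Applies the discovery funnel to every transcript with a scanned
#' profile, in order: (1) RIP enrichment of at least `min_rip_fold`;
#' (2) membership in the germline-expressed set; (3) at least
#' `min_lre_count` counted sites across both UTRs; (4) absence from the
#' OMA-RIP-enriched set (to exclude indirect, OMA-dependent binding).
#' Every input transcript keeps a per-filter pass/fail flag, so the full
#' funnel is auditable; a transcript is a candidate iff all four flags are
#' true.
#'
#' @param profiles named list of `lre_profile` objects (see
#'   [scan_utrs()]).
#' @param rip data frame (`transcript_id`, `log2_enrichment`). Transcripts
#'   without a RIP record fail filter 1.
#' @param germline [gene_set()] of germline-expressed transcripts.
#' @param oma_enriched [gene_set()] of OMA-RIP-enriched transcripts
#'   (excluded).
#' @param cfg a [pipeline_config()].
#' @param model the scoring model used for the profiles (for binding
#'   scores).
#' @return Object of class `candidate_table`: data frame with one row per
#'   input transcript -- `transcript_id`, `n_lre_5utr`, `n_lre_3utr`,
#'   `binding_score`, `log2_enrichment`, flags `pass_rip`,
#'   `pass_germline`, `pass_lre_count`, `pass_not_oma`, and `candidate` --
#'   with a funnel-count attribute `funnel`.
#' @export
discover_candidates <- function(profiles, rip, germline, oma_enriched,
                                cfg = pipeline_config(),
                                model = lre_scoring_model()) {
  stopifnot(inherits(germline, "gene_set"), inherits(oma_enriched, "gene_set"))
  if (length(germline$members) == 0L)
    input_error("germline gene set is empty")
  ids <- vapply(profiles, function(p) p$transcript_id, character(1))
  if (anyDuplicated(ids))
    input_error("duplicate transcript ids in profiles: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(rip$transcript_id))
    input_error("duplicate transcript ids in RIP table")

  counted <- vapply(profiles, function(p) {
    s <- p$sites
    sum(as.character(s$category) %in% cfg$counted_categories)
  }, integer(1))
  n5 <- vapply(profiles, function(p)
    sum(p$sites$utr_kind == "five_prime"), integer(1))
  n3 <- vapply(profiles, function(p)
    sum(p$sites$utr_kind == "three_prime"), integer(1))
  bs <- binding_scores(profiles, model)

  le <- rip$log2_enrichment[match(ids, rip$transcript_id)]
  tab <- data.frame(
    transcript_id = ids,
    n_lre_5utr = n5, n_lre_3utr = n3,
    binding_score = bs$value[match(ids, bs$transcript_id)],
    log2_enrichment = le,
    pass_rip = !is.na(le) & le >= log2(cfg$min_rip_fold),
    pass_germline = ids %in% germline$members,
    pass_lre_count = counted >= cfg$min_lre_count,
    pass_not_oma = !(ids %in% oma_enriched$members))
  tab$candidate <- tab$pass_rip & tab$pass_germline &
    tab$pass_lre_count & tab$pass_not_oma
  rownames(tab) <- NULL
  funnel <- c(input = nrow(tab),
              rip = sum(tab$pass_rip),
              germline = sum(tab$pass_rip & tab$pass_germline),
              lre_count = sum(tab$pass_rip & tab$pass_germline &
                                tab$pass_lre_count),
              not_oma = sum(tab$candidate))
  structure(tab, funnel = funnel, config = cfg,
            class = c("candidate_table", "data.frame"))
}

#' @export
print.candidate_table <- function(x, ...) {
  f <- attr(x, "funnel")
  cat("Candidate discovery funnel:\n")
  cat(sprintf("  input transcripts        %d\n", f[["input"]]))
  cat(sprintf("  >= RIP fold filter       %d\n", f[["rip"]]))
  cat(sprintf("  & germline-expressed     %d\n", f[["germline"]]))
  cat(sprintf("  & >= min LRE count       %d\n", f[["lre_count"]]))
  cat(sprintf("  & not OMA-enriched       %d candidate(s)\n", f[["not_oma"]]))
  cand <- x[x$candidate, , drop = FALSE]
  if (nrow(cand)) print.data.frame(cand, row.names = FALSE)
  invisible(x)
}

#' Candidates only
#'
#' @param table a `candidate_table`.
#' @return The candidate rows as a plain data frame.
#' @export
candidates <- function(table) {
  out <- as.data.frame(table)[table$candidate, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' UTR localization of candidate sites
#'
#' Reports, per candidate, whether its sites lie only in the 3' UTR, only
#' in the 5' UTR, or in both, plus a cohort summary (fraction of
#' candidates with 3'-only sites).
#'
#' @param table a `candidate_table` from [discover_candidates()].
#' @return List with `per_candidate` (data frame: `transcript_id`,
#'   `n_lre_5utr`, `n_lre_3utr`, `localization`) and `fraction_3utr_only`.
#' @export
utr_localization_report <- function(table) {
  cand <- candidates(table)
  loc <- ifelse(cand$n_lre_3utr > 0 & cand$n_lre_5utr == 0, "3utr_only",
         ifelse(cand$n_lre_5utr > 0 & cand$n_lre_3utr == 0, "5utr_only",
         ifelse(cand$n_lre_5utr > 0 & cand$n_lre_3utr > 0, "both", "none")))
  per <- data.frame(transcript_id = cand$transcript_id,
                    n_lre_5utr = cand$n_lre_5utr,
                    n_lre_3utr = cand$n_lre_3utr,
                    localization = loc)
  list(per_candidate = per,
       fraction_3utr_only =
         if (nrow(per)) mean(loc == "3utr_only") else NA_real_)
}
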