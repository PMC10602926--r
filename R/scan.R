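#' RNA UTR sequence record
#'
#' Normalizes and validates one UTR sequence: uppercased, DNA `T`
#' transliterated to `U`, alphabet restricted to A/C/G/U. Invalid
#' characters raise an input error naming the record and 1-based offset.
#'
#' @param id transcript identifier.
#' @param seq character sequence (RNA or DNA alphabet, any case).
#' @param utr_kind `"five_prime"` or `"three_prime"`.
#' @return An object of class `rna_sequence` (list with `id`, `utr_kind`,
#'   `seq`).
#' @export
rna_sequence <- function(id, seq, utr_kind = c("three_prime", "five_prime")) {
  utr_kind <- match.arg(utr_kind)
  if (!nzchar(id)) input_error("empty sequence id")
  seq <- chartr("T", "U", toupper(as.character(seq)))
  if (!nzchar(seq)) input_error("record '%s': empty sequence", id)
  bad <- regexpr("[^ACGU]", seq)
  if (bad > 0L)
    input_error("record '%s': invalid character '%s' at offset %d",
                id, substr(seq, bad, bad), as.integer(bad))
  structure(list(id = id, utr_kind = utr_kind, seq = seq),
            class = "rna_sequence")
}

RNA_BASES <- c("A", "C", "G", "U")

# Pairing lookup matrices: canonical Watson-Crick, and canonical + G-U wobble.
pair_matrix <- function(wobble) {
  m <- matrix(FALSE, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["A", "U"] <- m["U", "A"] <- m["G", "C"] <- m["C", "G"] <- TRUE
  if (wobble) m["G", "U"] <- m["U", "G"] <- TRUE
  m
}

#' Enumerate tri-loop hairpins in a sequence
#'
#' Finds every maximal-stem hairpin with an exactly 3-nt loop. The stem is
#' grown outward from the loop-closing pair while consecutive pairs
#' satisfy the pairing policy: canonical A-U/U-A/G-C/C-G always; G-U/U-G
#' only in non-closing positions and only if the model allows wobble.
#' At most one hairpin is reported per loop position -- the one with the
#' longest valid stem, capped at `model$max_stem` -- and only if that stem
#' reaches `model$min_stem`. Sequences too short to host any hairpin yield
#' an empty table (not an error).
#'
#' @param seq an [rna_sequence()] (or a plain character string, coerced
#'   with `id = "seq"`, 3' UTR).
#' @param model an [lre_scoring_model()].
#' @return Data frame, one row per hairpin, sorted by `stem5_start`
#'   (0-based): `seq_id`, `utr_kind`, `stem5_start`, `stem_len`,
#'   `loop_start`, `loop`, `arm5`, `arm3` (both written 5' to 3'),
#'   `start`, `end` (0-based half-open span).
#' @examples
#' enumerate_triloop_hairpins(rna_sequence("x", "GCUAAGAGC"),
#'                            lre_scoring_model())
#' @export
enumerate_triloop_hairpins <- function(seq, model = lre_scoring_model()) {
  if (is.character(seq)) seq <- rna_sequence("seq", seq)
  stopifnot(inherits(seq, "rna_sequence"))
  s <- seq$seq
  n <- nchar(s)
  empty <- data.frame(seq_id = character(), utr_kind = character(),
                      stem5_start = integer(), stem_len = integer(),
                      loop_start = integer(), loop = character(),
                      arm5 = character(), arm3 = character(),
                      start = integer(), end = integer())
  if (n < 2L * model$min_stem + 3L) return(empty)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  P_canon <- pair_matrix(FALSE)
  P_stem  <- pair_matrix(model$allow_wobble)
  # 0-based loop starts; alive[i] = stem of length L so far is fully paired
  i0 <- 0:(n - 3L)
  alive <- rep(TRUE, length(i0))
  maxlen <- integer(length(i0))
  for (L in seq_len(model$max_stem)) {
    p5 <- i0 - L        # 0-based index of 5' base of pair L
    p3 <- i0 + 2L + L
    inb <- p5 >= 0L & p3 <= n - 1L
    alive <- alive & inb
    if (!any(alive)) break
    P <- if (L == 1L) P_canon else P_stem
    ok <- alive
    ok[alive] <- P[cbind(ch[p5[alive] + 1L], ch[p3[alive] + 1L])]
    alive <- ok
    maxlen[alive] <- L
  }
  keep <- which(maxlen >= model$min_stem)
  if (!length(keep)) return(empty)
  i0 <- i0[keep]; L <- maxlen[keep]
  data.frame(
    seq_id = seq$id, utr_kind = seq$utr_kind,
    stem5_start = i0 - L, stem_len = L, loop_start = i0,
    loop = substring(s, i0 + 1L, i0 + 3L),
    arm5 = substring(s, i0 - L + 1L, i0),
    arm3 = substring(s, i0 + 4L, i0 + 3L + L),
    start = i0 - L, end = i0 + 3L + L)
}

# reverse each string in a character vector
str_rev <- function(x)
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))

#' Score hairpins under a position-weight model
#'
#' The score is the sum of the model's weight-table entries over the three
#' loop positions, the loop-closing pair, and every non-closing stem pair
#' (up to `max_stem`); keys absent from the table contribute 0.
#'
#' @param h hairpin table from [enumerate_triloop_hairpins()].
#' @param model an [lre_scoring_model()].
#' @return Numeric vector of scores, one per hairpin.
#' @export
score_lre <- function(h, model = lre_scoring_model()) {
  if (nrow(h) == 0L) return(numeric(0))
  w <- model$position_weights
  wt <- function(keys) { v <- unname(w[keys]); v[is.na(v)] <- 0; v }
  L <- h$stem_len
  sc <- wt(paste0("loop1.", substr(h$loop, 1, 1))) +
        wt(paste0("loop2.", substr(h$loop, 2, 2))) +
        wt(paste0("loop3.", substr(h$loop, 3, 3))) +
        wt(paste0("closing.", substr(h$arm5, L, L), substr(h$arm3, 1, 1)))
  for (j in 2:max(c(2L, L))) {
    sel <- L >= j
    if (!any(sel)) break
    b5 <- substr(h$arm5[sel], L[sel] - j + 1L, L[sel] - j + 1L)
    b3 <- substr(h$arm3[sel], j, j)
    sc[sel] <- sc[sel] + wt(paste0("stem.", b5, b3))
  }
  sc
}

#' Classify hairpins as response-element sites
#'
#' A hairpin qualifies as a site iff (a) the third loop nucleotide is a
#' purine (A or G), (b) the loop-closing stem pair, read with the 5'
#' strand base first, is U-A or C-G, and (c) its score reaches the minimal
#' category threshold. Qualifying hairpins are returned with `score` and
#' `category` columns appended; the rest are dropped.
#'
#' @inheritParams score_lre
#' @return Site table (possibly 0 rows): hairpin columns plus `score` and
#'   ordered-factor `category`.
#' @export
classify_lre <- function(h, model = lre_scoring_model()) {
  score <- score_lre(h, model)
  if (nrow(h) == 0L) {
    h$score <- numeric(0)
    h$category <- categorize(numeric(0), model)
    return(h)
  }
  closing <- paste0(substr(h$arm5, h$stem_len, h$stem_len),
                    substr(h$arm3, 1, 1))
  ok <- substr(h$loop, 3, 3) %in% c("A", "G") &
        closing %in% c("UA", "CG") &
        score >= model$thresholds[1]
  out <- h[ok, , drop = FALSE]
  out$score <- score[ok]
  out$category <- categorize(out$score, model)
  rownames(out) <- NULL
  out
}

# Greedy de-overlap: highest score first, ties by leftmost start; a site is
# kept iff it does not overlap an already-kept site (within one UTR).
resolve_overlaps <- function(sites) {
  if (nrow(sites) <= 1L) return(sites)
  ord <- order(-sites$score, sites$start)
  sites <- sites[ord, , drop = FALSE]
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    k <- which(keep)
    keep[i] <- !any(sites$start[i] < sites$end[k] &
                    sites$end[i] > sites$start[k])
  }
  out <- sites[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan the UTRs of one transcript for response elements
#'
#' Runs enumerate -> classify -> score -> categorize on each supplied UTR,
#' then resolves overlapping sites greedily (highest score first, ties by
#' leftmost start, discarding any site that overlaps an accepted one).
#'
#' @param utr5,utr3 [rna_sequence()] objects or `NULL`; at least one must
#'   be present, and both must share the transcript id.
#' @param model an [lre_scoring_model()].
#' @param transcript_id optional override for the profile id.
#' @return An object of class `lre_profile`: list with `transcript_id`,
#'   `sites` (retained site table) and `counts` (category x UTR-kind
#'   integer matrix).
#' @export
scan_transcript <- function(utr5 = NULL, utr3 = NULL,
                            model = lre_scoring_model(),
                            transcript_id = NULL) {
  if (is.null(utr5) && is.null(utr3))
    input_error("at least one UTR must be supplied")
  if (!is.null(utr5) && !is.null(utr3) && utr5$id != utr3$id)
    input_error("UTR id mismatch: '%s' vs '%s'", utr5$id, utr3$id)
  id <- transcript_id %||% (if (!is.null(utr3)) utr3$id else utr5$id)
  scan1 <- function(u) {
    if (is.null(u)) return(NULL)
    resolve_overlaps(classify_lre(enumerate_triloop_hairpins(u, model), model))
  }
  sites <- do.call(rbind, Filter(Negate(is.null), list(scan1(utr5), scan1(utr3))))
  if (is.null(sites))
    sites <- classify_lre(
      enumerate_triloop_hairpins(rna_sequence(id, "A"), model)[0, ], model)
  rownames(sites) <- NULL
  counts <- table(
    factor(sites$category, levels = model$category_names),
    factor(sites$utr_kind, levels = c("five_prime", "three_prime")))
  structure(list(transcript_id = id, sites = sites,
                 counts = unclass(counts)),
            class = "lre_profile")
}

#' @export
print.lre_profile <- function(x, ...) {
  cat(sprintf("Response-element profile for '%s': %d site(s)\n",
              x$transcript_id, nrow(x$sites)))
  print(x$counts)
  invisible(x)
}

#' Scan a whole set of UTR sequences
#'
#' @param utrs data frame with columns `id`, `utr_kind`, `seq`, e.g. from
#'   [read_utr_fasta()]; at most one row per (id, utr_kind).
#' @param model an [lre_scoring_model()].
#' @return Named list of [scan_transcript()] profiles, one per transcript.
#' @export
scan_utrs <- function(utrs, model = lre_scoring_model()) {
  stopifnot(all(c("id", "utr_kind", "seq") %in% names(utrs)))
  if (anyDuplicated(utrs[c("id", "utr_kind")]))
    input_error("duplicate (id, utr_kind) records: %s",
                paste(unique(utrs$id[duplicated(utrs[c("id", "utr_kind")])]),
                      collapse = ", "))
  ids <- unique(utrs$id)
  out <- lapply(ids, function(tid) {
    rows <- utrs[utrs$id == tid, ]
    pick <- function(kind) {
      r <- rows[rows$utr_kind == kind, ]
      if (nrow(r)) rna_sequence(tid, r$seq[1], kind) else NULL
    }
    scan_transcript(pick("five_prime"), pick("three_prime"), model)
  })
  names(out) <- ids
  out
}

#' Combine profiles into one site table
#'
#' @param profiles list of `lre_profile` objects.
#' @return Data frame with one row per retained site across all
#'   transcripts (columns as in [classify_lre()]).
#' @export
site_table <- function(profiles) {
  tabs <- lapply(profiles, function(p) p$sites)
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
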