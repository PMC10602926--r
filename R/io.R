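#' Read UTR sequences from FASTA
#'
#' Reads one FASTA of UTR records whose ids follow the
#' `transcript|5utr` / `transcript|3utr` convention, or two separate
#' files (one per UTR kind). Sequences are uppercased and DNA `T` is
#' transliterated to `U`; duplicate (transcript, kind) records and
#' invalid characters are input errors.
#'
#' @param path FASTA path (combined convention), or the 5'-UTR file when
#'   `path3` is given.
#' @param path3 optional separate 3'-UTR FASTA.
#' @return Data frame with columns `id`, `utr_kind`, `seq`.
#' @export
read_utr_fasta <- function(path, path3 = NULL) {
  read_one <- function(p, forced_kind = NULL) {
    if (!file.exists(p)) input_error("FASTA file not found: %s", p)
    ss <- Biostrings::readBStringSet(p)
    if (!length(ss)) input_error("%s: no FASTA records", p)
    full_ids <- sub("\\s.*$", "", names(ss))
    if (is.null(forced_kind)) {
      kinds <- ifelse(grepl("\\|5utr$", full_ids), "five_prime",
               ifelse(grepl("\\|3utr$", full_ids), "three_prime", NA))
      if (anyNA(kinds))
        input_error("%s: record '%s' lacks a |5utr / |3utr suffix",
                    p, full_ids[which(is.na(kinds))[1]])
      ids <- sub("\\|[35]utr$", "", full_ids)
    } else {
      kinds <- forced_kind
      ids <- full_ids
    }
    data.frame(id = ids, utr_kind = kinds,
               seq = chartr("T", "U", toupper(as.character(ss))))
  }
  utrs <- if (is.null(path3)) read_one(path) else
    rbind(read_one(path, "five_prime"), read_one(path3, "three_prime"))
  dup <- duplicated(utrs[c("id", "utr_kind")])
  if (any(dup))
    input_error("duplicate FASTA record id: %s",
                paste(unique(utrs$id[dup]), collapse = ", "))
  bad <- regexpr("[^ACGU]", utrs$seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    input_error("record '%s': invalid character '%s' at offset %d",
                utrs$id[i], substr(utrs$seq[i], bad[i], bad[i]),
                as.integer(bad[i]))
  }
  rownames(utrs) <- NULL
  utrs
}

#' Write a site table as BED6
#'
#' Coordinates are 0-based half-open; the BED name is the category and the
#' BED score is the model score times 1000, rounded; strand is `+`.
#'
#' @param sites site table from [site_table()] or [classify_lre()] (needs
#'   `seq_id`, `start`, `end`, `category`, `score`).
#' @param path output path.
#' @export
write_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$seq_id,
                    start = sites$start, end = sites$end,
                    name = as.character(sites$category),
                    score = round(sites$score * 1000),
                    strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 site table
#'
#' @param path BED path.
#' @return Data frame: `seq_id`, `start`, `end`, `category`, `score`
#'   (model units), `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) input_error("BED file not found: %s", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "name", "score", "strand"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "numeric", "character"))
  data.frame(seq_id = bed$chrom, start = bed$start, end = bed$end,
             category = bed$name, score = bed$score / 1000,
             strand = bed$strand)
}

#' Tab-separated I/O with header row
#'
#' Thin wrappers with the package's conventions (no quoting, no row
#' names, CRLF tolerated on read); parse errors name the file.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_tsv_file` returns a data frame.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) input_error("TSV file not found: %s", path)
  tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) input_error("%s: %s", path, conditionMessage(e)))
}

#' Read a RIP enrichment table
#'
#' @param path TSV with columns `transcript_id` and `log2_enrichment`.
#' @return Validated data frame (finite enrichment, unique ids).
#' @export
read_rip_table <- function(path) {
  rip <- read_tsv_file(path)
  if (!all(c("transcript_id", "log2_enrichment") %in% names(rip)))
    input_error("%s: need columns transcript_id, log2_enrichment", path)
  if (anyDuplicated(rip$transcript_id))
    input_error("%s: duplicate transcript ids", path)
  if (any(!is.finite(rip$log2_enrichment)))
    input_error("%s: non-finite enrichment values", path)
  rip
}

#' Read a gene list (one id per line, '#' comments)
#'
#' @param path text file path.
#' @param name set name (defaults to the file stem).
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) input_error("gene list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- trimws(sub("#.*$", "", lines))
  gene_set(name %||% tools::file_path_sans_ext(basename(path)),
           lines[nzchar(lines)])
}

#' Read a qPCR Cq table
#'
#' @param path TSV with columns `gene`, `condition`, `replicate`, `cq`
#'   and optionally `priming`.
#' @return Validated data frame.
#' @export
read_cq_table <- function(path) {
  cq <- read_tsv_file(path)
  need <- c("gene", "condition", "replicate", "cq")
  if (!all(need %in% names(cq)))
    input_error("%s: need columns %s", path, paste(need, collapse = ", "))
  if (any(!is.finite(cq$cq)) || any(cq$cq <= 0))
    input_error("%s: Cq values must be finite and positive", path)
  key <- cq[intersect(c("gene", "condition", "replicate", "priming"),
                      names(cq))]
  if (anyDuplicated(key))
    input_error("%s: duplicate (gene, condition, replicate) rows", path)
  cq
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the formats the pipeline reads: two UTR FASTA files,
#' a RIP TSV, two gene lists, the planted-truth tables, and a JSON run
#' manifest recording seed and parameters.
#'
#' @param cohort an `lre_cohort` from [make_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lre_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(utr5 = file.path(dir, "utr5.fasta"),
             utr3 = file.path(dir, "utr3.fasta"),
             rip = file.path(dir, "rip.tsv"),
             germline = file.path(dir, "germline.txt"),
             oma = file.path(dir, "oma_enriched.txt"),
             truth_transcripts = file.path(dir, "truth_transcripts.tsv"),
             truth_sites = file.path(dir, "truth_sites.tsv"),
             manifest = file.path(dir, "manifest.json"))
  for (kind in c("five_prime", "three_prime")) {
    u <- cohort$utrs[cohort$utrs$utr_kind == kind, ]
    ss <- Biostrings::BStringSet(stats::setNames(u$seq, u$id))
    Biostrings::writeXStringSet(
      ss, if (kind == "five_prime") paths[["utr5"]] else paths[["utr3"]])
  }
  write_tsv_file(cohort$rip, paths[["rip"]])
  writeLines(cohort$germline$members, paths[["germline"]])
  writeLines(cohort$oma_enriched$members, paths[["oma"]])
  write_tsv_file(cohort$truth$transcripts, paths[["truth_transcripts"]])
  write_tsv_file(cohort$truth$sites, paths[["truth_sites"]])
  jsonlite::write_json(
    list(seed = cohort$seed, params = cohort$params,
         package = "lrescan",
         version = as.character(utils::packageVersion("lrescan"))),
    paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
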