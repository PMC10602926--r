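# Synthetic-data generators. All generators are pure functions of their
# `seed` argument (they save and restore the caller's RNG state), so two
# runs with the same seed and parameters produce identical output.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

# Per-slot scoring options for a hairpin of stem length L under `model`:
# closing pair, three loop positions, and L-1 inner stem pairs.
slot_options <- function(model, L) {
  w <- model$position_weights
  wt <- function(keys) { v <- unname(w[keys]); v[is.na(v)] <- 0; v }
  stem_pool <- c("GC", "CG", "AU", "UA", if (model$allow_wobble) c("GU", "UG"))
  slots <- list(
    closing = data.frame(label = c("UA", "CG"),
                         value = wt(c("closing.UA", "closing.CG"))),
    loop1 = data.frame(label = RNA_BASES, value = wt(paste0("loop1.", RNA_BASES))),
    loop2 = data.frame(label = RNA_BASES, value = wt(paste0("loop2.", RNA_BASES))),
    loop3 = data.frame(label = c("A", "G"), value = wt(c("loop3.A", "loop3.G"))))
  for (j in seq_len(L - 1L))
    slots[[paste0("stem", j + 1L)]] <-
      data.frame(label = stem_pool, value = wt(paste0("stem.", stem_pool)))
  slots
}

# Greedy randomized search for per-slot choices whose total score lands in
# [lo, hi). Starts from the minimum-value configuration and applies
# smallest-step upgrades in random slots until the total reaches lo.
pick_slots <- function(slots, lo, hi) {
  pick_label <- function(s, v) sample(rep(s$label[s$value == v], 2), 1)
  cur_val <- vapply(slots, function(s) min(s$value), numeric(1))
  cur_lab <- mapply(pick_label, slots, cur_val)
  total <- sum(cur_val)
  if (total >= hi) return(NULL)
  while (total < lo) {
    up <- which(vapply(seq_along(slots), function(i)
      any(slots[[i]]$value > cur_val[i]), logical(1)))
    if (!length(up)) return(NULL)
    i <- if (length(up) == 1L) up else sample(up, 1)
    nv <- min(slots[[i]]$value[slots[[i]]$value > cur_val[i]])
    total <- total + nv - cur_val[i]
    cur_val[i] <- nv
    cur_lab[i] <- pick_label(slots[[i]], nv)
    if (total >= hi) return(NULL)
  }
  list(labels = cur_lab, score = total)
}

#' Generate a sequence fragment containing one planted response element
#'
#' Constructs a hairpin-forming fragment whose single retained site, when
#' re-scanned with the same model, scores inside the requested category's
#' interval. The flanking bases are chosen to be non-pairing so the stem
#' cannot extend beyond the planted length.
#'
#' @param category target category (`"minimal"`, `"weak"`, `"medium"`,
#'   `"strong"`).
#' @param model an [lre_scoring_model()].
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return List with `fragment` (character), `expected_score`,
#'   `category`, `stem_len`, `site_offset` (0-based start of the hairpin
#'   span within the fragment).
#' @export
make_lre_sequence <- function(category, model = lre_scoring_model(),
                              seed = NULL) {
  category <- match.arg(category, model$category_names)
  ci <- match(category, model$category_names)
  lo <- model$thresholds[ci]
  hi <- if (ci < 4L) model$thresholds[ci + 1L] else Inf
  with_seed(seed, {
    for (attempt in 1:200) {
      L <- sample(rep(model$min_stem:model$max_stem, 2), 1)
      sel <- pick_slots(slot_options(model, L), lo, hi)
      if (is.null(sel)) next
      lab <- sel$labels
      closing <- strsplit(lab[["closing"]], "")[[1]]
      inner <- if (L > 1L)
        strsplit(unname(lab[paste0("stem", 2:L)]), "") else list()
      # arm5: outermost..closing 5' bases; arm3: closing..outermost 3' bases
      b5 <- c(closing[1], vapply(inner, `[`, "", 1))
      b3 <- c(closing[2], vapply(inner, `[`, "", 2))
      arm5 <- paste(rev(b5), collapse = "")
      arm3 <- paste(b3, collapse = "")
      loop <- paste0(lab[["loop1"]], lab[["loop2"]], lab[["loop3"]])
      frag <- paste0("A", arm5, loop, arm3, "G")  # A..G cannot pair
      # closed loop: the fragment's single retained site must match
      p <- scan_transcript(utr3 = rna_sequence("frag", frag), model = model)
      if (nrow(p$sites) == 1L && p$sites$stem_len == L &&
          p$sites$start == 1L &&
          p$sites$score >= lo && p$sites$score < hi)
        return(list(fragment = frag, expected_score = p$sites$score,
                    category = category, stem_len = L, site_offset = 1L))
    }
    input_error("category '%s' unreachable under the supplied weight table",
                category)
  })
}

random_rna <- function(len, base_freqs) {
  paste(sample(RNA_BASES, len, replace = TRUE, prob = base_freqs),
        collapse = "")
}

#' Generate a synthetic UTR cohort with planted truth
#'
#' Emulates the inputs of the discovery pipeline: background UTRs drawn
#' i.i.d. from `base_freqs`; a designated target subset receives planted
#' 3'-UTR response elements (non-overlapping, >= 5 nt from record edges);
#' RIP log2 enrichment is Normal(`rip_mu`, `rip_sd`) for targets and
#' Normal(0, `rip_sd`) otherwise; the germline set contains all targets
#' plus a background fraction, and the OMA-enriched set contains only
#' background transcripts. In the noiseless configuration (`rip_sd = 0`)
#' the planted targets are therefore the unique pipeline survivors.
#'
#' @param n_transcripts,n_targets cohort and target-set sizes.
#' @param seed integer seed; the single source of randomness.
#' @param utr3_len_range,utr5_len_range UTR length ranges (nt).
#' @param n_planted_range range of planted 3'-UTR sites per target
#'   (default exactly 2, the minimum required for repression).
#' @param planted_categories categories to sample planted sites from.
#' @param rip_mu mean log2 enrichment of the enriched subset (default 3,
#'   i.e. 8-fold).
#' @param rip_sd log2 enrichment noise SD (0 = noiseless).
#' @param frac_germline_bg,frac_oma_bg fractions of background
#'   transcripts put in the germline / OMA-enriched sets.
#' @param targets_in_oma must be `FALSE`; forcing planted targets into the
#'   exclusion list contradicts the planted truth and raises a
#'   configuration error (modify the returned gene set instead to study
#'   that regime).
#' @param model scoring model used to plant and verify sites.
#' @param base_freqs background base probabilities (A, C, G, U).
#' @return List of class `lre_cohort`: `utrs` (data frame `id`,
#'   `utr_kind`, `seq`), `truth` (list with `transcripts` and `sites`
#'   data frames), `rip`, `germline`, `oma_enriched` ([gene_set()]s),
#'   `params`, `seed`.
#' @export
make_cohort <- function(n_transcripts = 500L, n_targets = 20L, seed = 1L,
                        utr3_len_range = c(150L, 250L),
                        utr5_len_range = c(40L, 80L),
                        n_planted_range = c(2L, 2L),
                        planted_categories = "strong",
                        rip_mu = 3, rip_sd = 0,
                        frac_germline_bg = 0.5, frac_oma_bg = 0.2,
                        targets_in_oma = FALSE,
                        model = lre_scoring_model(),
                        base_freqs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  if (n_targets > n_transcripts)
    input_error("n_targets (%d) exceeds n_transcripts (%d)",
                n_targets, n_transcripts)
  if (isTRUE(targets_in_oma))
    input_error(paste("contradictory configuration: planted targets cannot",
                      "be OMA-enriched (they would never be recoverable)"))
  frag_max <- 2L * model$max_stem + 5L
  need <- max(n_planted_range) * (frag_max + 2L) + 10L
  if (utr3_len_range[1] < need)
    input_error("3' UTRs too short (%d nt) for up to %d planted sites",
                utr3_len_range[1], max(n_planted_range))
  with_seed(seed, {
    ids <- sprintf("T%04d", seq_len(n_transcripts))
    targets <- sort(sample(ids, n_targets))
    seqs5 <- vapply(ids, function(i)
      random_rna(sample(utr5_len_range[1]:utr5_len_range[2], 1), base_freqs),
      character(1))
    seqs3 <- vapply(ids, function(i)
      random_rna(sample(utr3_len_range[1]:utr3_len_range[2], 1), base_freqs),
      character(1))
    site_rows <- list()
    for (tid in targets) {
      s <- seqs3[[tid]]
      n <- nchar(s)
      k <- if (n_planted_range[1] == n_planted_range[2]) n_planted_range[1]
           else sample(n_planted_range[1]:n_planted_range[2], 1)
      if (k == 0L) next
      # one planted site per equal-width block, respecting 5-nt edge margins
      bounds <- floor(seq(5L, n - 5L, length.out = k + 1L))
      for (b in seq_len(k)) {
        frag <- make_lre_sequence(sample(rep(planted_categories, 2), 1), model)
        fl <- nchar(frag$fragment)
        lo_pos <- bounds[b] + 1L                 # 1-based insert start
        hi_pos <- bounds[b + 1L] - fl
        if (hi_pos < lo_pos)
          input_error("planting block too small; lengthen the 3' UTRs")
        at <- sample(lo_pos:hi_pos, 1)
        substr(s, at, at + fl - 1L) <- frag$fragment
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          transcript_id = tid, utr_kind = "three_prime",
          start = at - 1L + frag$site_offset,
          end = at - 1L + frag$site_offset + 2L * frag$stem_len + 3L,
          stem_len = frag$stem_len, category = frag$category,
          expected_score = frag$expected_score)
      }
      seqs3[[tid]] <- s
    }
    bg <- setdiff(ids, targets)
    germline <- gene_set("germline_expressed",
                         c(targets, sample(bg, round(frac_germline_bg * length(bg)))))
    oma <- gene_set("oma_enriched",
                    sample(bg, round(frac_oma_bg * length(bg))))
    is_target <- ids %in% targets
    rip <- data.frame(
      transcript_id = ids,
      log2_enrichment = ifelse(is_target, rip_mu, 0) +
        (if (rip_sd > 0) stats::rnorm(n_transcripts, 0, rip_sd) else 0))
    utrs <- rbind(
      data.frame(id = ids, utr_kind = "five_prime", seq = unname(seqs5)),
      data.frame(id = ids, utr_kind = "three_prime", seq = unname(seqs3)))
    truth_sites <- if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame(transcript_id = character(), utr_kind = character(),
                 start = integer(), end = integer(), stem_len = integer(),
                 category = character(), expected_score = numeric())
    structure(list(
      utrs = utrs,
      truth = list(
        transcripts = data.frame(
          transcript_id = ids, is_target = is_target,
          is_germline = ids %in% germline$members,
          is_oma_enriched = ids %in% oma$members,
          true_log2_enrichment = rip$log2_enrichment),
        sites = truth_sites),
      rip = rip, germline = germline, oma_enriched = oma,
      params = list(n_transcripts = n_transcripts, n_targets = n_targets,
                    utr3_len_range = utr3_len_range,
                    utr5_len_range = utr5_len_range,
                    n_planted_range = n_planted_range,
                    planted_categories = planted_categories,
                    rip_mu = rip_mu, rip_sd = rip_sd,
                    frac_germline_bg = frac_germline_bg,
                    frac_oma_bg = frac_oma_bg),
      seed = seed), class = "lre_cohort")
  })
}

#' @export
print.lre_cohort <- function(x, ...) {
  cat(sprintf("Synthetic UTR cohort: %d transcripts, %d planted targets (seed %s)\n",
              x$params$n_transcripts, x$params$n_targets, x$seed))
  invisible(x)
}

#' Simulate a qPCR Cq table with known fold changes
#'
#' Cq values follow baseline - log2(true abundance) + Normal(0, sd); the
#' control condition has abundance 1 for every gene and the reference
#' gene is held at fold change 1 in both conditions, so noiseless tables
#' invert exactly under [ddcq_fold_change()].
#'
#' @param genes character vector of target gene names.
#' @param fold_changes named numeric vector: test-condition abundance of
#'   each gene relative to control (names must cover `genes`).
#' @param ref_gene reference gene name (appended, fold change 1).
#' @param conditions length-2 character vector, control first.
#' @param sd Cq replicate noise SD (cycles).
#' @param replicates replicates per gene x condition.
#' @param seed integer seed.
#' @param priming priming label stored in the table.
#' @param baseline mean Cq of an abundance-1 transcript.
#' @return Data frame with columns `gene`, `condition`, `replicate`,
#'   `priming`, `cq`.
#' @export
make_cq_table <- function(genes, fold_changes, ref_gene = "act-1",
                          conditions = c("control", "test"),
                          sd = 0.2, replicates = 3L, seed = 1L,
                          priming = "total", baseline = 20) {
  if (sd < 0) input_error("sd must be >= 0")
  if (replicates < 2L) input_error("need >= 2 replicates")
  if (!all(genes %in% names(fold_changes)))
    input_error("fold_changes must name every gene")
  fold_changes <- c(fold_changes, stats::setNames(1, ref_gene))
  all_genes <- c(genes, ref_gene)
  with_seed(seed, {
    offs <- stats::setNames(stats::runif(length(all_genes), -2, 2), all_genes)
    grid <- expand.grid(gene = all_genes, condition = conditions,
                        replicate = seq_len(replicates),
                        stringsAsFactors = FALSE)
    abundance <- ifelse(grid$condition == conditions[2],
                        fold_changes[grid$gene], 1)
    grid$priming <- priming
    grid$cq <- baseline + offs[grid$gene] - log2(abundance) +
      (if (sd > 0) stats::rnorm(nrow(grid), 0, sd) else 0)
    grid[order(grid$gene, grid$condition, grid$replicate), ]
  })
}

#' Simulate overlapping gene sets with a configured enrichment
#'
#' Draws two subsets of a universe whose expected overlap is
#' `fold_enrichment * a_size * b_size / universe_size` (stochastic
#' rounding keeps the expectation exact across seeds).
#'
#' @param universe_size,a_size,b_size set sizes.
#' @param fold_enrichment target overlap enrichment (1 = independence).
#' @param seed integer seed.
#' @return List with [gene_set()]s `universe`, `set_a`, `set_b` and the
#'   realized `overlap`.
#' @export
make_overlap_sets <- function(universe_size, a_size, b_size,
                              fold_enrichment = 1, seed = 1L) {
  t <- fold_enrichment * a_size * b_size / universe_size
  if (fold_enrichment < 0 || t > min(a_size, b_size) ||
      b_size - floor(t) > universe_size - a_size)
    input_error("infeasible fold_enrichment %g for sizes %d/%d/%d",
                fold_enrichment, universe_size, a_size, b_size)
  with_seed(seed, {
    ids <- sprintf("g%05d", seq_len(universe_size))
    a <- sample(ids, a_size)
    k <- floor(t) + stats::rbinom(1, 1, t - floor(t))
    k <- min(k, a_size, b_size)
    b <- c(sample(a, k), sample(setdiff(ids, a), b_size - k))
    list(universe = gene_set("universe", ids),
         set_a = gene_set("set_a", a),
         set_b = gene_set("set_b", b),
         overlap = k)
  })
}
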