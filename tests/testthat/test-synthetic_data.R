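test_that("planted fragments scan back into their requested category", {
  m <- lre_scoring_model()
  lo <- c(m$thresholds, Inf)
  for (ci in 1:4) {
    cat_name <- m$category_names[ci]
    for (seed in 1:5) {
      f <- make_lre_sequence(cat_name, m, seed = seed)
      p <- scan_transcript(utr3 = rna_sequence("f", f$fragment), model = m)
      expect_equal(nrow(p$sites), 1L)
      expect_gte(p$sites$score, lo[ci])
      expect_lt(p$sites$score, lo[ci + 1])
      expect_equal(as.character(p$sites$category), cat_name)
      expect_equal(p$sites$score, f$expected_score)
      # the flanks must not extend the stem
      expect_equal(p$sites$start, f$site_offset)
      expect_equal(p$sites$stem_len, f$stem_len)
    }
  }
})

test_that("T-transliterated fragments yield the identical site", {
  m <- lre_scoring_model()
  f <- make_lre_sequence("medium", m, seed = 9)
  dna <- chartr("U", "T", f$fragment)
  expect_identical(
    scan_transcript(utr3 = rna_sequence("f", f$fragment), model = m)$sites,
    scan_transcript(utr3 = rna_sequence("f", dna), model = m)$sites)
})

test_that("unreachable categories raise a generation error", {
  weak_table <- lre_scoring_model(
    position_weights = c(closing.UA = 0.01, closing.CG = 0.01,
                         loop3.A = 0.01, loop3.G = 0.01, stem.GC = 0.01))
  expect_error(make_lre_sequence("strong", weak_table, seed = 1),
               class = "lrescan_input_error")
})

test_that("cohorts are pure functions of their seed", {
  c1 <- make_cohort(n_transcripts = 30, n_targets = 3, seed = 101)
  c2 <- make_cohort(n_transcripts = 30, n_targets = 3, seed = 101)
  c3 <- make_cohort(n_transcripts = 30, n_targets = 3, seed = 102)
  expect_identical(c1$utrs, c2$utrs)
  expect_identical(c1$rip, c2$rip)
  expect_identical(c1$germline$members, c2$germline$members)
  expect_false(identical(c1$utrs$seq, c3$utrs$seq))
  # generators restore the caller's RNG state
  set.seed(77); before <- .Random.seed
  invisible(make_cohort(n_transcripts = 10, n_targets = 1, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("cohort truth predicts the pipeline outcome", {
  co <- make_cohort(n_transcripts = 60, n_targets = 6, seed = 55)
  truth <- co$truth
  targets <- truth$transcripts$transcript_id[truth$transcripts$is_target]
  # planted sites land where the truth table says, with the stated scores
  profiles <- scan_utrs(co$utrs)
  for (i in seq_len(nrow(truth$sites))) {
    row <- truth$sites[i, ]
    s <- profiles[[row$transcript_id]]$sites
    hit <- s[s$utr_kind == row$utr_kind & s$start == row$start, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$score, row$expected_score)
  }
  # every target carries >= 2 planted, pairwise non-overlapping 3' sites
  for (tid in targets) {
    ts <- truth$sites[truth$sites$transcript_id == tid, ]
    expect_gte(nrow(ts), 2L)
    ts <- ts[order(ts$start), ]
    if (nrow(ts) > 1L) expect_true(all(ts$start[-1] >= ts$end[-nrow(ts)]))
  }
})

test_that("a background-only cohort produces zero candidates", {
  co <- make_cohort(n_transcripts = 50, n_targets = 0, seed = 61)
  tab <- discover_candidates(scan_utrs(co$utrs), co$rip,
                             co$germline, co$oma_enriched)
  expect_equal(nrow(candidates(tab)), 0L)
})

test_that("contradictory cohort options are rejected", {
  expect_error(make_cohort(n_transcripts = 10, n_targets = 20, seed = 1),
               class = "lrescan_input_error")
  expect_error(make_cohort(n_transcripts = 10, n_targets = 2, seed = 1,
                           targets_in_oma = TRUE),
               class = "lrescan_input_error")
  expect_error(make_cohort(n_transcripts = 10, n_targets = 2, seed = 1,
                           utr3_len_range = c(40L, 50L)),
               class = "lrescan_input_error")
})

test_that("noiseless Cq tables invert exactly and noisy ones on average", {
  cq <- make_cq_table("g1", c(g1 = 4), sd = 0, replicates = 3, seed = 3)
  r <- ddcq_fold_change(cq, "g1", "act-1", "control", "test")
  expect_equal(r$fold_change, 4)
  # mean recovered fold change within 10% of truth at sd = 0.2
  fc <- vapply(1:200, function(s) {
    cq <- make_cq_table("g1", c(g1 = 3), sd = 0.2, replicates = 3, seed = s)
    ddcq_fold_change(cq, "g1", "act-1", "control", "test")$fold_change
  }, numeric(1))
  expect_lt(abs(mean(fc) - 3) / 3, 0.1)
})

test_that("null Cq simulations keep the t-test type-I error near nominal", {
  # both conditions have equal variance by construction, so the pooled
  # t-test is exact and its rejection rate should be binomial at alpha
  p <- vapply(1:1000, function(s) {
    cq <- make_cq_table("g1", c(g1 = 1), sd = 0.2, replicates = 3, seed = s)
    ddcq_fold_change(cq, "g1", "act-1", "control", "test",
                     var_equal = TRUE)$p_value
  }, numeric(1))
  hits <- sum(p < 0.05)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("overlap-set generator hits its configured enrichment", {
  # independence (fold 1): rarely significant
  p <- vapply(1:300, function(s) {
    sets <- make_overlap_sets(1000, 80, 80, fold_enrichment = 1, seed = s)
    hypergeometric_overlap(sets$set_a, sets$set_b, sets$universe)$p_upper
  }, numeric(1))
  expect_gte(mean(p >= 0.05), 0.9)
  # realized overlap averages to fold * expected-under-independence
  ov <- vapply(1:300, function(s)
    make_overlap_sets(1000, 80, 80, fold_enrichment = 5, seed = s)$overlap,
    numeric(1))
  expect_equal(mean(ov), 5 * 80 * 80 / 1000, tolerance = 0.05)
  # nested boundary: maximal enrichment gives the minimal attainable p
  fe_max <- 50 * 1000 / (50 * 200)
  sets <- make_overlap_sets(1000, 50, 200, fold_enrichment = fe_max, seed = 2)
  expect_equal(sets$overlap, 50)
  res <- hypergeometric_overlap(sets$set_a, sets$set_b, sets$universe)
  expect_equal(res$p_upper,
               exp(phyper(49, 50, 950, 200, lower.tail = FALSE, log.p = TRUE)))
  # infeasible configurations are rejected
  expect_error(make_overlap_sets(100, 10, 10, fold_enrichment = 50, seed = 1),
               class = "lrescan_input_error")
})
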