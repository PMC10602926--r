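cq_row <- function(gene, condition, replicate, cq)
  data.frame(gene = gene, condition = condition, replicate = replicate,
             priming = "total", cq = cq)

test_that("ddCq fold change: identities and a hand-computed fixture", {
  # identical conditions -> fold change exactly 1
  cq <- rbind(cq_row("tgt", "ctl", 1:3, c(22, 22.3, 21.9)),
              cq_row("tgt", "tst", 1:3, c(22, 22.3, 21.9)),
              cq_row("ref", "ctl", 1:3, c(18, 18.1, 17.8)),
              cq_row("ref", "tst", 1:3, c(18, 18.1, 17.8)))
  r <- ddcq_fold_change(cq, "tgt", "ref", "ctl", "tst")
  expect_equal(r$fold_change, 1)
  # ddCq = -1 exactly -> fold change 2
  cq2 <- rbind(cq_row("tgt", "ctl", 1:2, c(22, 23)),
               cq_row("tgt", "tst", 1:2, c(21, 22)),
               cq_row("ref", "ctl", 1:2, c(18, 18)),
               cq_row("ref", "tst", 1:2, c(18, 18)))
  expect_equal(ddcq_fold_change(cq2, "tgt", "ref", "ctl", "tst")$fold_change, 2)
  # hand-computed fixture: dCq_ctl = (4.0, 4.2, 4.4); dCq_tst = (2.6, 2.7, 2.8)
  # ddCq = 2.7 - 4.2 = -1.5 -> fold change 2^1.5
  cq3 <- rbind(cq_row("tgt", "ctl", 1:3, c(24.0, 24.2, 24.4)),
               cq_row("tgt", "tst", 1:3, c(22.6, 22.7, 22.8)),
               cq_row("ref", "ctl", 1:3, c(20, 20, 20)),
               cq_row("ref", "tst", 1:3, c(20, 20, 20)))
  r3 <- ddcq_fold_change(cq3, "tgt", "ref", "ctl", "tst")
  expect_equal(r3$ddcq, -1.5)
  expect_equal(r3$fold_change, 2^1.5)
  hand <- oracle_welch(c(2.6, 2.7, 2.8), c(4.0, 4.2, 4.4))
  expect_equal(r3$t_statistic, hand$t)
  expect_equal(r3$p_value, hand$p)
})

test_that("ddCq is invariant to a constant shift of every Cq", {
  set.seed(19)
  cq <- make_cq_table("g1", c(g1 = 3), sd = 0.3, replicates = 4, seed = 4)
  r1 <- ddcq_fold_change(cq, "g1", "act-1", "control", "test")
  cq$cq <- cq$cq + 5
  r2 <- ddcq_fold_change(cq, "g1", "act-1", "control", "test")
  expect_equal(r1$fold_change, r2$fold_change)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("ddCq validates reference wells and replicate counts", {
  cq <- rbind(cq_row("tgt", "ctl", 1:3, 22), cq_row("tgt", "tst", 1:3, 21))
  expect_error(ddcq_fold_change(cq, "tgt", "ref", "ctl", "tst"),
               class = "lrescan_input_error")
  cq4 <- rbind(cq_row("tgt", "ctl", 1, 22), cq_row("ref", "ctl", 1, 20),
               cq_row("tgt", "tst", 1:2, 21), cq_row("ref", "tst", 1:2, 20))
  expect_error(ddcq_fold_change(cq4, "tgt", "ref", "ctl", "tst"),
               class = "lrescan_input_error")
})

test_that("standard curve: ideal doubling series and inversion identities", {
  # perfect 2-fold dilutions at 100% efficiency: slope = -1/log10(2)
  conc <- c(1, 0.5, 0.25, 0.125, 0.0625)
  slope_true <- -1 / log10(2)
  pts <- data.frame(log10_conc = log10(conc),
                    cq = 20 + slope_true * log10(conc))
  sc <- standard_curve_quantify(pts, sample_cq = pts$cq)
  expect_equal(sc$slope, slope_true, tolerance = 1e-10)
  expect_equal(sc$efficiency, 1, tolerance = 1e-10)
  expect_equal(sc$r_squared, 1)
  # a sample at a curve point's Cq recovers that point's concentration
  expect_equal(sc$relative_abundance, conc, tolerance = 1e-10)
  # forward model inversion on arbitrary noiseless abundances
  ab <- c(0.3, 0.07, 2.5)
  cqs <- unname(20 + slope_true * log10(ab))
  expect_equal(standard_curve_quantify(pts, cqs)$relative_abundance, ab,
               tolerance = 1e-10)
})

test_that("standard curve rejects degenerate fits", {
  flat <- data.frame(log10_conc = c(0, -1, -2), cq = c(20, 20, 20))
  expect_error(standard_curve_quantify(flat, 20),
               class = "lrescan_input_error")
  rising <- data.frame(log10_conc = c(0, -1, -2), cq = c(24, 22, 20))
  expect_error(standard_curve_quantify(rising, 20),
               class = "lrescan_input_error")
  expect_error(standard_curve_quantify(flat[1:2, ], 20),
               class = "lrescan_input_error")
})

test_that("condition ratios: identities and a hand-checked fixture", {
  expect_equal(condition_ratio(c(2, 2, 2), c(2, 2, 2))$ratio, 1)
  a <- c(1.1, 0.9, 1.0)
  expect_equal(condition_ratio(a, 2 * a)$ratio, 0.5)
  b <- c(1.9, 2.1, 2.0)
  r <- condition_ratio(a, b)
  expect_equal(r$ratio, mean(a) / mean(b))
  expect_equal(r$sd, (mean(a) / mean(b)) *
                 sqrt((sd(a) / mean(a))^2 + (sd(b) / mean(b))^2))
  # one-sample t of per-replicate ratios against 1
  rr <- a / mean(b)
  t_hand <- (mean(rr) - 1) / (sd(rr) / sqrt(3))
  expect_equal(r$t_statistic, t_hand)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), 2))
  expect_error(condition_ratio(a, c(0, 1, 2)), class = "lrescan_input_error")
  expect_error(condition_ratio(a, numeric(1)), class = "lrescan_input_error")
})

test_that("hypergeometric overlap matches full enumeration", {
  mk <- function(n, pre = "g") sprintf("%s%03d", pre, seq_len(n))
  # 10-element universe, |A| = 4, |B| = 5, overlap 4: p = 6/252
  u <- gene_set("u", mk(10))
  a <- gene_set("a", mk(4))
  b <- gene_set("b", c(mk(4), "g010"))
  res <- hypergeometric_overlap(a, b, u)
  expect_equal(res$overlap, 4L)
  expect_equal(res$p_upper, 6 / 252)
  expect_equal(res$fold_enrichment, 4 / (4 * 5 / 10))
  # zero overlap -> p = 1 boundary
  res0 <- hypergeometric_overlap(gene_set("a", mk(2)),
                                 gene_set("b", c("g009", "g010")), u)
  expect_equal(res0$p_upper, 1)
  # log-space tail equals naive factorial arithmetic for all N <= 20
  set.seed(23)
  for (i in 1:300) {
    N <- sample(2:20, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k_lo <- max(0L, K + n - N)
    k <- sample(k_lo:min(K, n), 1)
    expect_equal(
      exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)),
      oracle_hyper_p(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("hypergeometric p is monotone decreasing in overlap and validates subsets", {
  mk <- function(n) sprintf("g%03d", seq_len(n))
  u <- gene_set("u", mk(40))
  p_prev <- 1.01
  for (k in 0:10) {
    a <- gene_set("a", mk(10))
    # |B| = 10 with overlap exactly k
    b <- gene_set("b", c(mk(10)[seq_len(k)], mk(40)[seq(11, length.out = 10 - k)]))
    p <- hypergeometric_overlap(a, b, u)$p_upper
    expect_lt(p, p_prev + 1e-15)
    p_prev <- p
  }
  err <- expect_error(
    hypergeometric_overlap(gene_set("a", "zzz"), gene_set("b", mk(2)), u),
    class = "lrescan_input_error")
  expect_match(conditionMessage(err), "zzz")
})

test_that("extreme tails are handled in log space at transcriptome scale", {
  mk <- function(n) sprintf("g%05d", seq_len(n))
  u <- gene_set("u", mk(20000))
  a <- gene_set("a", mk(600))
  b <- gene_set("b", c(mk(200), mk(20000)[10001:10400]))  # overlap 200
  res <- hypergeometric_overlap(a, b, u)
  expect_true(is.finite(res$log_p_upper))
  expect_lt(res$p_upper, 1e-100)
  expect_gt(res$p_upper, 0)
})

test_that("fluorescence ratios normalize per animal and compare groups", {
  # oocyte == distal -> ratio 1; oocyte = 2x distal -> ratio 2
  d1 <- data.frame(animal = "a1",
                   compartment = c("oocyte", "oocyte", "distal", "distal"),
                   value = c(5, 5, 5, 5))
  expect_equal(fluorescence_ratio(d1)$per_animal$ratio, 1)
  d2 <- transform(d1, value = c(10, 10, 5, 5))
  expect_equal(fluorescence_ratio(d2)$per_animal$ratio, 2)
  # excluding the -1 oocyte drops the last oocyte entry
  d3 <- data.frame(animal = "a1",
                   compartment = c("oocyte", "oocyte", "oocyte", "distal"),
                   value = c(4, 6, 100, 5))
  expect_equal(fluorescence_ratio(d3, exclude_last = TRUE)$per_animal$ratio, 1)
  # 7-animal two-group fixture: hand-computed ratios, enumeration-path p
  set.seed(31)
  mk_animal <- function(a, g, mu) data.frame(
    animal = a, group = g,
    compartment = c("oocyte", "oocyte", "distal", "distal"),
    value = c(mu, mu * 1.1, 10, 10))
  tab <- rbind(mk_animal("w1", "wt", 4), mk_animal("w2", "wt", 5),
               mk_animal("w3", "wt", 4.5), mk_animal("w4", "wt", 5.5),
               mk_animal("m1", "mut", 14), mk_animal("m2", "mut", 16),
               mk_animal("m3", "mut", 15))
  fr <- fluorescence_ratio(tab)
  hand <- c(4, 5, 4.5, 5.5, 14, 16, 15) * 2.1 / 2 / 10
  expect_equal(fr$per_animal$ratio,
               hand[match(fr$per_animal$animal,
                          c("w1", "w2", "w3", "w4", "m1", "m2", "m3"))])
  expect_equal(fr$comparison$method, "exact enumeration")
  g <- split(fr$per_animal$ratio, fr$per_animal$group)
  expect_equal(fr$comparison$p_value, oracle_ranksum_p(g[[1]], g[[2]]))
  # validation
  expect_error(fluorescence_ratio(
    data.frame(animal = "x", compartment = "oocyte", value = 1)),
    class = "lrescan_input_error")
  expect_error(fluorescence_ratio(
    data.frame(animal = "x", compartment = c("oocyte", "distal"),
               value = c(1, 0))),
    class = "lrescan_input_error")
})
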