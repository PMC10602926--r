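# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the hairpin oracle does a full re-check of
# every (loop position, stem length) combination; the statistics oracles
# use textbook formulas or exhaustive enumeration.

# Exhaustive tri-loop hairpin enumerator: for every loop position and
# every stem length up to max_stem, re-checks all pairs from scratch.
oracle_hairpins <- function(seq, min_stem = 3L, max_stem = 8L,
                            wobble = TRUE) {
  seq <- chartr("T", "U", toupper(seq))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  canon <- c("AU", "UA", "GC", "CG")
  stem_ok <- c(canon, if (wobble) c("GU", "UG"))
  rows <- list()
  if (n >= 2L * min_stem + 3L) {
    for (i0 in 0:(n - 3L)) {          # 0-based loop start
      best <- 0L
      for (L in 1:max_stem) {
        if (i0 - L < 0L || i0 + 2L + L > n - 1L) next
        valid <- TRUE
        for (j in 1:L) {
          p <- paste0(ch[i0 - j + 1L], ch[i0 + 3L + j])
          allowed <- if (j == 1L) canon else stem_ok
          if (!(p %in% allowed)) { valid <- FALSE; break }
        }
        if (valid) best <- max(best, L)
      }
      if (best >= min_stem)
        rows[[length(rows) + 1L]] <-
          data.frame(stem5_start = i0 - best, stem_len = best,
                     loop_start = i0)
    }
  }
  if (!length(rows))
    return(data.frame(stem5_start = integer(), stem_len = integer(),
                      loop_start = integer()))
  do.call(rbind, rows)
}

random_seq <- function(len, alphabet = c("A", "C", "G", "U"))
  paste(sample(alphabet, len, replace = TRUE), collapse = "")

# Upper-tail hypergeometric p by naive factorial arithmetic.
oracle_hyper_p <- function(N, K, n, k) {
  lo <- max(0L, K + n - N)
  hi <- min(K, n)
  if (k <= lo) return(1)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# Two-sided exact rank-sum p by enumeration of all group labelings.
oracle_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ws <- apply(utils::combn(n + m, n), 2,
              function(idx) sum(r[idx]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Textbook correlation formulas.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# Welch t statistic and p for two samples.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
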