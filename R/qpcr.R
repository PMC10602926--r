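#' qPCR fold change by the 2^-ddCq method
#'
#' Per replicate, dCq = Cq(target) - Cq(reference); ddCq is the mean dCq
#' of the test condition minus the mean dCq of the control condition; the
#' fold change is 2^-ddCq. Significance is an unpaired t-test on the
#' per-replicate dCq values of the two conditions (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance variant). Adding a constant
#' to every Cq leaves the result unchanged.
#'
#' @param cq data frame with columns `gene`, `condition`, `replicate`,
#'   `cq` (and optionally `priming`, filtered by `priming` if given).
#' @param target_gene,ref_gene gene names of target and internal
#'   reference.
#' @param control_cond,test_cond the two condition labels.
#' @param priming optional priming chemistry to select (`"total"` or
#'   `"polyA"`).
#' @param var_equal use the pooled-variance t-test instead of Welch's.
#' @return Object of class `ddcq_result`: list with `fold_change`,
#'   `ddcq`, `dcq_control`, `dcq_test` (per-replicate values),
#'   `t_statistic`, `df`, `p_value`, `method`.
#' @export
ddcq_fold_change <- function(cq, target_gene, ref_gene,
                             control_cond, test_cond,
                             priming = NULL, var_equal = FALSE) {
  if (!is.null(priming)) {
    if (!"priming" %in% names(cq))
      input_error("cq table has no 'priming' column")
    cq <- cq[cq$priming == priming, , drop = FALSE]
  }
  dcq <- function(cond) {
    tg <- cq[cq$gene == target_gene & cq$condition == cond, ]
    rf <- cq[cq$gene == ref_gene & cq$condition == cond, ]
    if (nrow(rf) == 0L)
      input_error("no reference-gene ('%s') wells for condition '%s'",
                  ref_gene, cond)
    if (nrow(tg) < 2L)
      input_error("need >= 2 target replicates for condition '%s'", cond)
    m <- merge(tg[, c("replicate", "cq")], rf[, c("replicate", "cq")],
               by = "replicate", suffixes = c("_target", "_ref"))
    if (nrow(m) < 2L)
      input_error("fewer than 2 matched target/reference replicates in '%s'",
                  cond)
    stats::setNames(m$cq_target - m$cq_ref, m$replicate)
  }
  d_ctl <- dcq(control_cond)
  d_tst <- dcq(test_cond)
  ddcq <- mean(d_tst) - mean(d_ctl)
  # noiseless (zero-variance) inputs have no defined t statistic
  tt <- tryCatch(stats::t.test(d_tst, d_ctl, var.equal = var_equal),
                 error = function(e)
                   list(statistic = c(t = NA_real_),
                        parameter = c(df = NA_real_), p.value = NA_real_))
  structure(list(fold_change = 2^(-ddcq), ddcq = ddcq,
                 dcq_control = d_ctl, dcq_test = d_tst,
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 method = if (var_equal) "pooled t-test" else "Welch t-test",
                 target_gene = target_gene, ref_gene = ref_gene,
                 control_cond = control_cond, test_cond = test_cond),
            class = "ddcq_result")
}

#' @export
print.ddcq_result <- function(x, ...) {
  cat(sprintf("2^-ddCq fold change, %s vs %s (ref %s):\n",
              x$test_cond, x$control_cond, x$ref_gene))
  cat(sprintf("  %s: fold change = %.4g (ddCq = %+.4g)\n",
              x$target_gene, x$fold_change, x$ddcq))
  cat(sprintf("  %s: t = %.3f, df = %.2f, p = %.4g\n",
              x$method, x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Standard-curve relative quantification
#'
#' Fits the dilution series cq = intercept + slope * log10(concentration)
#' by least squares and inverts it for sample Cq values. Also reports the
#' amplification efficiency 10^(-1/slope) - 1 (1.0 = perfect doubling,
#' slope -1/log10(2) ~ -3.3219).
#'
#' @param curve_points data frame with columns `log10_conc` and `cq`
#'   (>= 3 points; slope must be negative for a valid dilution series).
#' @param sample_cq numeric vector of sample Cq values to quantify.
#' @return List with `relative_abundance` (one per sample Cq), `slope`,
#'   `intercept`, `r_squared`, `efficiency`.
#' @export
standard_curve_quantify <- function(curve_points, sample_cq) {
  stopifnot(all(c("log10_conc", "cq") %in% names(curve_points)))
  if (nrow(curve_points) < 3L)
    input_error("standard curve needs >= 3 points")
  fit <- stats::lm(cq ~ log10_conc, data = curve_points)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || abs(slope) < 1e-8)
    input_error("degenerate standard curve: |slope| ~ 0")
  if (slope >= 0)
    input_error("standard-curve slope must be negative (got %.3g)", slope)
  # noiseless dilution series are legitimately collinear; lm's
  # perfect-fit warning is not informative here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(relative_abundance = 10^((sample_cq - intercept) / slope),
       slope = slope, intercept = intercept, r_squared = r2,
       efficiency = 10^(-1 / slope) - 1)
}

#' Ratio of expression between two conditions
#'
#' Ratio of group means (a over b) with a standard deviation by
#' first-order error propagation, and significance from comparing the
#' per-replicate ratios `a / mean(b)` against 1 (one-sample t-test, the
#' convention used when mutant/wild-type ratios are plotted against a
#' reference line at 1).
#'
#' @param values_a,values_b numeric vectors (>= 2 replicates each); all
#'   values of `values_b` and its mean must be positive.
#' @return List with `ratio`, `sd` (propagated), `t_statistic`, `df`,
#'   `p_value`, `replicate_ratios`.
#' @export
condition_ratio <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    input_error("need >= 2 replicates per condition")
  if (mean(values_b) <= 0 || any(values_b <= 0))
    input_error("denominator values must be positive")
  ma <- mean(values_a); mb <- mean(values_b)
  ratio <- ma / mb
  sd_prop <- abs(ratio) *
    sqrt((stats::sd(values_a) / ma)^2 + (stats::sd(values_b) / mb)^2)
  rr <- values_a / mb
  # zero-variance replicates have no defined t statistic
  tt <- tryCatch(stats::t.test(rr, mu = 1),
                 error = function(e)
                   list(statistic = c(t = NA_real_),
                        parameter = c(df = NA_real_), p.value = NA_real_))
  list(ratio = ratio, sd = sd_prop,
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, replicate_ratios = rr)
}
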