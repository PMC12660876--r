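#' Two-tailed t-test with effect size
#'
#' Thin wrapper around [stats::t.test()] returning the reporting fields
#' used throughout the package: t, df, two-sided p, 95% CI and Cohen's d.
#' The independent two-sample test uses pooled variance.
#'
#' @param x Numeric vector (first group).
#' @param y Optional second group (two-sample or paired).
#' @param mu Reference value for the one-sample test.
#' @param kind `"one_sample"`, `"two_sample"` (pooled variance) or
#'   `"paired"`.
#' @return One-row data frame: `kind`, `t`, `df`, `p`, `ci_lo`, `ci_hi`,
#'   `cohens_d`.
#' @export
ttest_summary <- function(x, y = NULL, mu = 0,
                          kind = c("one_sample", "two_sample",
                                   "paired")) {
  kind <- match.arg(kind)
  check_var <- function(v) {
    if (length(v) < 2L) {
      stop("ttest_summary: need at least 2 observations per group",
           call. = FALSE)
    }
  }
  check_var(x)
  if (kind == "one_sample") {
    if (stats::sd(x) == 0) {
      stop("ttest_summary: zero variance", call. = FALSE)
    }
    res <- stats::t.test(x, mu = mu)
    d <- (mean(x) - mu) / stats::sd(x)
  } else if (kind == "two_sample") {
    check_var(y)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      stop("ttest_summary: zero variance", call. = FALSE)
    }
    res <- stats::t.test(x, y, var.equal = TRUE)
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    d <- (mean(x) - mean(y)) / sp
  } else {
    check_var(y)
    diffs <- x - y
    if (stats::sd(diffs) == 0 && mean(diffs) != 0) {
      stop("ttest_summary: zero variance of paired differences",
           call. = FALSE)
    }
    if (stats::sd(diffs) == 0) {
      # identical pairs: t = 0 by convention
      return(data.frame(kind = kind, t = 0, df = length(x) - 1, p = 1,
                        ci_lo = 0, ci_hi = 0, cohens_d = 0))
    }
    res <- stats::t.test(x, y, paired = TRUE)
    d <- mean(diffs) / stats::sd(diffs)
  }
  data.frame(kind = kind, t = unname(res$statistic),
             df = unname(res$parameter), p = res$p.value,
             ci_lo = res$conf.int[1], ci_hi = res$conf.int[2],
             cohens_d = d)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `q`; adjusted p-values via
#' [stats::p.adjust()] (monotone in the raw-p rank).
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with logical `reject` and numeric `p_adj`, both in the
#'   input order.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0L) {
    return(list(reject = logical(0), p_adj = numeric(0)))
  }
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("fdr_bh: p-values must lie in [0, 1]", call. = FALSE)
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  list(reject = p_adj <= q, p_adj = p_adj)
}
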