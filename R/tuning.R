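#' Reconstruct a tuning curve from fitted versatile-model weights
#'
#' The tuning curve is the weighted sum of the basis functions,
#' `f(x) = sum_i w_i f_i(x)`, evaluated on a regular grid over the
#' estimate domain. Only the interest weights are used.
#'
#' @param fit An `encoding_fit`, or a numeric vector of interest weights.
#' @param basis The [make_basis()] set the weights refer to.
#' @param n_grid Grid resolution (default 201 points).
#' @param unit Column of the fit to use when it holds several units.
#' @return An object of class `tuning_curve` with `grid`, `values`,
#'   `domain`.
#' @export
tuning_curve <- function(fit, basis, n_grid = 201L, unit = 1L) {
  w <- if (inherits(fit, "encoding_fit")) {
    fit$weights[fit$interest_mask, unit]
  } else {
    as.numeric(fit)
  }
  if (length(w) != basis$K) {
    stop("tuning_curve: weight length does not match basis K",
         call. = FALSE)
  }
  grid <- seq(basis$domain[1], basis$domain[2], length.out = n_grid)
  values <- drop(eval_basis(basis, grid) %*% w)
  structure(list(grid = grid, values = values, domain = basis$domain,
                 weights = w),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("tuning curve on [%g, %g] (%d grid points), range [%.3g, %.3g]\n",
              x$domain[1], x$domain[2], length(x$grid),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  plot(x$grid, x$values, type = "l", xlab = "estimate value",
       ylab = "response", ...)
  invisible(x)
}

# Interior local maxima of a numeric vector, plateau-aware (a flat top
# counts once, located at its middle sample). Endpoints are never peaks.
local_maxima <- function(v) {
  n <- length(v)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) {
        peaks <- c(peaks, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# Topographic prominence of a peak: its height above the higher of the two
# key saddles, where each saddle is the minimum between the peak and the
# nearest point that exceeds it on that side (or the signal end).
peak_prominence <- function(v, p) {
  n <- length(v)
  left_min <- v[p]
  i <- p
  while (i > 1L && v[i - 1L] <= v[p]) {
    i <- i - 1L
    left_min <- min(left_min, v[i])
  }
  right_min <- v[p]
  i <- p
  while (i < n && v[i + 1L] <= v[p]) {
    i <- i + 1L
    right_min <- min(right_min, v[i])
  }
  v[p] - max(left_min, right_min)
}

#' Count peaks of a min-max-normalized curve
#'
#' After normalizing the curve to `[0, 1]`, interior local maxima are
#' counted as peaks when their normalized height is at least `height` and
#' their topographic prominence at least `prominence` (the conservative
#' thresholds used for tuning-curve characterization).
#'
#' @param values Numeric curve samples.
#' @param height Minimum normalized height (default 0.7).
#' @param prominence Minimum prominence (default 0.125).
#' @return Integer peak count.
#' @export
count_peaks <- function(values, height = 0.7, prominence = 0.125) {
  rng <- range(values)
  if (diff(rng) == 0) return(0L)
  v <- (values - rng[1]) / diff(rng)
  cand <- local_maxima(v)
  cand <- cand[v[cand] >= height]
  sum(vapply(cand, function(p) peak_prominence(v, p), numeric(1)) >=
        prominence)
}

#' Shape characterization of a tuning curve
#'
#' Computes the curve's argmax (ties broken toward lower x), whether the
#' argmax is non-extreme (at least a 20% margin from the domain bounds,
#' relative to the span), the non-monotonicity index
#' `n(f) = 1 - |f(b) - f(a)| / (f_max - f_min)` (with monotonicity
#' `m(f) = 1 - n(f)`), the nonlinearity index `nu(f) = 1 - R2_lin` of an
#' ordinary least-squares line fitted to the curve, and the
#' prominence-filtered peak count. Constant curves are flagged degenerate
#' with `n = nu = 0` by convention.
#'
#' @param curve A [tuning_curve()] (or list with `grid`, `values`,
#'   `domain`).
#' @param margin Non-extremeness margin as a fraction of the span.
#' @return A one-row data frame with columns `argmax_x`, `non_extreme`,
#'   `nonmono`, `mono`, `nonlin`, `r2_lin`, `n_peaks`, `degenerate`.
#' @export
characterize_curve <- function(curve, margin = 0.2) {
  v <- curve$values
  g <- curve$grid
  a <- curve$domain[1]
  b <- curve$domain[2]
  if (length(v) == 0L) stop("characterize_curve: empty grid", call. = FALSE)
  rng <- range(v)
  degenerate <- diff(rng) == 0
  argmax_x <- g[which.max(v)]
  span <- b - a
  non_extreme <- argmax_x >= a + margin * span &&
    argmax_x <= b - margin * span
  if (degenerate) {
    nonmono <- 0
    nonlin <- 0
    r2_lin <- 1
    n_peaks <- 0L
  } else {
    nonmono <- 1 - abs(v[length(v)] - v[1]) / diff(rng)
    lin <- stats::lm(v ~ g)
    ss_res <- sum(stats::residuals(lin)^2)
    ss_tot <- sum((v - mean(v))^2)
    r2_lin <- 1 - ss_res / ss_tot
    nonlin <- 1 - r2_lin
    n_peaks <- count_peaks(v)
  }
  data.frame(argmax_x = argmax_x, non_extreme = non_extreme,
             nonmono = nonmono, mono = 1 - nonmono, nonlin = nonlin,
             r2_lin = r2_lin, n_peaks = n_peaks, degenerate = degenerate)
}

#' Characterize all units of a cross-validated fit
#'
#' Refits the versatile model on all sessions jointly and characterizes
#' the reconstructed tuning curve of each unit.
#'
#' @param weights Interest-weight matrix (K x units).
#' @param basis The basis set.
#' @param n_grid Curve grid resolution.
#' @return Data frame with one row per unit (`unit` column first).
#' @export
characterize_units <- function(weights, basis, n_grid = 201L) {
  out <- lapply(seq_len(ncol(weights)), function(v) {
    ch <- characterize_curve(tuning_curve(weights[, v], basis, n_grid))
    cbind(unit = v, ch)
  })
  do.call(rbind, out)
}

#' Select units of interest from an empirical R2 null
#'
#' Converts each unit's cross-validated R2 into an empirical p-value
#' against a null distribution of R2 scores obtained with white-noise
#' data, `p = (1 + #(null >= observed)) / (1 + n_null)`, and selects units
#' by Benjamini-Hochberg FDR at level `alpha`.
#'
#' @param r2 Observed fold-averaged R2 per unit.
#' @param null_r2 Null R2 samples (white-noise pipeline runs).
#' @param alpha FDR level.
#' @return List with `selected` (indices), `p`, `p_adj`.
#' @export
select_units <- function(r2, null_r2, alpha = 0.05) {
  if (length(null_r2) == 0L) {
    stop("select_units: empty null distribution", call. = FALSE)
  }
  null_sorted <- sort(null_r2)
  n_null <- length(null_sorted)
  # #(null >= observed) via binary search on the sorted null
  p <- vapply(r2, function(x)
    (1 + n_null - findInterval(x, null_sorted, left.open = TRUE)) /
      (1 + n_null), numeric(1))
  adj <- fdr_bh(p, alpha)
  list(selected = which(adj$reject), p = p, p_adj = adj$p_adj)
}

#' Empirical null distribution of cross-validated R2 under white noise
#'
#' Runs the leave-one-session-out evaluation with the data replaced by
#' white-noise series and returns the fold-averaged R2 of each noise unit.
#'
#' @param X_list Preprocessed per-session design matrices.
#' @param interest_mask Logical mask of interest columns.
#' @param n_samples Number of white-noise units (default 10000).
#' @param lambda Ridge penalty.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_samples` null R2 values.
#' @export
empirical_null_r2 <- function(X_list, interest_mask, n_samples = 10000L,
                              lambda = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- 2
  Y <- lapply(X_list, function(X)
    matrix(stats::rnorm(nrow(X) * n_samples), nrow(X), n_samples))
  Yp <- preprocess_sessions(Y, tr = tr)
  res <- cv_core(X_list, interest_mask, Yp, list(), lambda)
  colMeans(res$r2)
}

#' Split-half reliability of versatile-model weights
#'
#' Fits the interest weights on two independent halves of the data
#' (sessions 1-2 vs 3-4 by default) and returns the Pearson correlation of
#' the concatenated interest weights over the selected units.
#'
#' @param X_list Preprocessed per-session design matrices (4 sessions).
#' @param Y_list Preprocessed per-session data matrices.
#' @param interest_mask Logical mask of interest columns.
#' @param units Unit indices entering the correlation (default all).
#' @param lambda Ridge penalty.
#' @param halves List of two session-index vectors.
#' @return Pearson correlation coefficient.
#' @export
split_half_reliability <- function(X_list, Y_list, interest_mask,
                                   units = NULL, lambda = 1,
                                   halves = list(c(1, 2), c(3, 4))) {
  if (any(lengths(halves) < 1L) ||
      max(unlist(halves)) > length(X_list)) {
    stop("split_half_reliability: invalid session halves", call. = FALSE)
  }
  if (is.null(units)) units <- seq_len(ncol(Y_list[[1]]))
  fit_half <- function(idx) {
    f <- fit_encoding(do.call(rbind, X_list[idx]),
                      do.call(rbind, Y_list[idx]), lambda, interest_mask)
    f$weights[interest_mask, units, drop = FALSE]
  }
  w1 <- fit_half(halves[[1]])
  w2 <- fit_half(halves[[2]])
  stats::cor(as.vector(w1), as.vector(w2))
}

#' Group comparison of tuning-curve characteristics
#'
#' Summarizes per-participant characterization tables (proportion of
#' non-extreme argmax, mean non-monotonicity, mean nonlinearity,
#' proportion of multi-peaked curves; degenerate units excluded) and
#' compares the probability and confidence groups by two-sample two-tailed
#' t-tests.
#'
#' @param prob_tables,conf_tables Lists (one element per participant) of
#'   data frames from [characterize_units()].
#' @return List with `per_participant` (data frame) and `tests` (one
#'   [ttest_summary()] row per measure).
#' @export
group_characterization <- function(prob_tables, conf_tables) {
  if (length(prob_tables) < 2L || length(conf_tables) < 2L) {
    stop("group_characterization: need at least 2 participants per group",
         call. = FALSE)
  }
  summarize <- function(tab, grp, id) {
    tab <- tab[!tab$degenerate, , drop = FALSE]
    data.frame(group = grp, participant = id,
               prop_non_extreme = mean(tab$non_extreme),
               mean_nonmono = mean(tab$nonmono),
               mean_nonlin = mean(tab$nonlin),
               prop_multipeak = mean(tab$n_peaks > 1))
  }
  pp <- rbind(
    do.call(rbind, lapply(seq_along(prob_tables), function(i)
      summarize(prob_tables[[i]], "probability", i))),
    do.call(rbind, lapply(seq_along(conf_tables), function(i)
      summarize(conf_tables[[i]], "confidence", i))))
  measures <- c("prop_non_extreme", "mean_nonmono", "mean_nonlin",
                "prop_multipeak")
  tests <- do.call(rbind, lapply(measures, function(m) {
    res <- ttest_summary(pp[pp$group == "probability", m],
                         pp[pp$group == "confidence", m],
                         kind = "two_sample")
    cbind(measure = m, res)
  }))
  list(per_participant = pp, tests = tests)
}

#' Write a per-unit characterization table as TSV
#'
#' @param tab Data frame from [characterize_units()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_characterization_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
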