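#' Per-bin response patterns for correlation-distance decoding
#'
#' For each leave-one-session-out fold, a 5-basis versatile encoding model
#' is ridge-fitted jointly on the three training sessions and separately
#' on the held-out session; the interest weights form the per-bin response
#' patterns (units x bins). Units are selected by the training-only z-R2
#' (inner leave-one-session-out among the 3 training sessions), taking the
#' `n_top` largest; when fewer units are available than `n_top`, all units
#' are used with a warning.
#'
#' @param seqs List of `stim_sequence` sessions.
#' @param Y List of raw data matrices (scans x units).
#' @param estimate `"probability"` or `"confidence"`.
#' @param n_bins Number of basis functions / bins (default 5).
#' @param n_top Number of units retained (default 100).
#' @param lambda Ridge penalty.
#' @param n_null Null sequences for the inner z-R2 (default 100).
#' @param seed Optional integer seed (null draws).
#' @param obs,hrf Observer and HRF configurations.
#' @param reports Optional per-session report data frames.
#' @return An object of class `bin_patterns`: per-fold list with `train`
#'   and `test` pattern matrices (selected units x bins) and
#'   `selected` unit indices, plus the basis, the per-session estimate
#'   values `x_values` and the fold structure.
#' @export
estimate_bin_patterns <- function(seqs, Y, estimate = "probability",
                                  n_bins = 5L, n_top = 100L, lambda = 1,
                                  n_null = 100L, seed = NULL,
                                  obs = observer_config(),
                                  hrf = hrf_spec(), reports = NULL) {
  n_sess <- length(seqs)
  if (n_sess < 3L) {
    stop("estimate_bin_patterns: need at least 3 sessions", call. = FALSE)
  }
  spec <- encoding_spec("versatile", estimate, K = n_bins)
  traces <- lapply(seqs, function(sq) run_ideal_observer(sq$values, obs))
  designs <- lapply(seq_len(n_sess), function(s)
    build_design(seqs[[s]], traces[[s]], spec, hrf,
                 reports = if (is.null(reports)) NULL else reports[[s]]))
  mask <- designs[[1]]$interest_mask
  tr <- seqs[[1]]$config$tr
  X_list <- preprocess_sessions(lapply(designs, `[[`, "X"), tr = tr)
  Y_list <- preprocess_sessions(Y, tr = tr)
  n_units <- ncol(Y_list[[1]])

  need_selection <- n_units > n_top
  if (!need_selection && n_units < n_top) {
    warning(sprintf("estimate_bin_patterns: only %d units available (< n_top = %d); using all",
                    n_units, n_top), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  null_int <- NULL
  if (need_selection && n_null > 0L) {
    null_mods <- null_interest_modulators(n_null, n_sess,
                                          seqs[[1]]$config, obs, spec)
    null_int <- lapply(null_mods, function(draw) {
      raw <- lapply(seq_len(n_sess), function(s)
        designs[[s]]$H_stim %*% draw[[s]])
      preprocess_sessions(raw, tr = tr)
    })
  }

  folds <- lapply(seq_len(n_sess), function(s) {
    train <- setdiff(seq_len(n_sess), s)
    if (need_selection) {
      inner_null <- lapply(null_int, function(draw) draw[train])
      inner <- cv_core(X_list[train], mask, Y_list[train], inner_null,
                       lambda)
      score <- colMeans(inner$z_r2)
      score[is.na(score)] <- -Inf
      selected <- order(score, decreasing = TRUE)[seq_len(n_top)]
    } else {
      selected <- seq_len(n_units)
    }
    fit_tr <- fit_encoding(do.call(rbind, X_list[train]),
                           do.call(rbind, Y_list[train]), lambda, mask)
    fit_te <- fit_encoding(X_list[[s]], Y_list[[s]], lambda, mask)
    list(fold = s,
         train = t(fit_tr$weights[mask, selected, drop = FALSE]),
         test = t(fit_te$weights[mask, selected, drop = FALSE]),
         selected = selected)
  })

  structure(list(folds = folds, basis = spec$basis, spec = spec,
                 x_values = lapply(traces, function(t2)
                   switch(estimate,
                          probability = t2$estimates$p_hat,
                          confidence = t2$estimates$confidence)),
                 n_bins = as.integer(n_bins), n_top = n_top),
            class = "bin_patterns")
}

#' Correlation-distance RDM between test and train bin patterns
#'
#' `D(j, k) = 1 - Pearson r(test pattern of bin j, train pattern of bin
#' k)`. Because train and test come from different data, the matrix is not
#' symmetric and its diagonal is not 0. Cells involving a zero-variance
#' pattern are `NA` and flagged.
#'
#' @param train,test Pattern matrices (units x bins); alternatively pass
#'   one fold of a `bin_patterns` object as `train`.
#' @return An object of class `rdm`: matrix `D` (rows = test bins, cols =
#'   train bins) with attribute `flagged` marking undefined cells.
#' @export
compute_rdm <- function(train, test = NULL) {
  if (is.list(train) && !is.null(train$train)) {
    test <- train$test
    train <- train$train
  }
  if (nrow(train) < 2L) {
    stop("compute_rdm: need at least 2 units", call. = FALSE)
  }
  n_bins <- ncol(train)
  D <- matrix(NA_real_, n_bins, n_bins)
  sd_tr <- apply(train, 2, stats::sd)
  sd_te <- apply(test, 2, stats::sd)
  ok <- outer(sd_te > 0, sd_tr > 0, "&")
  if (any(ok)) {
    C <- suppressWarnings(stats::cor(test, train))
    D[ok] <- 1 - C[ok]
  }
  structure(D, flagged = !ok, class = c("rdm", "matrix"))
}

# Bin validity: a stimulus falls in bin j when its estimate value elicits
# more than `frac_max` of the basis function's maximum; the bin is valid
# when at least `min_frac` of the session's stimuli fall in it.
bin_validity <- function(x, basis, frac_max = 0.1, min_frac = 0.05) {
  Fx <- eval_basis(basis, pmin(pmax(x, basis$domain[1]),
                               basis$domain[2]))
  fmax <- apply(eval_basis(basis, seq(basis$domain[1], basis$domain[2],
                                      length.out = 1001L)), 2, max)
  counts <- colSums(sweep(Fx, 2, fmax, "/") > frac_max)
  counts / length(x) >= min_frac
}

#' Nearest-pattern bin decoding from RDMs
#'
#' For every valid test bin `j` the decoded bin is
#' `argmin_k D(j, k)` (ties toward the lowest bin index); accuracy is the
#' fraction of valid bins decoded correctly, averaged across folds. A bin
#' is valid in a fold when at least 5% of that test session's stimuli fall
#' in it (a stimulus falls in a bin when its estimate value elicits more
#' than 10% of the maximum of the bin's basis function). Folds without
#' valid bins are omitted with a warning.
#'
#' @param patterns A `bin_patterns` object.
#' @param frac_max,min_frac Validity thresholds (defaults 0.1 and 0.05).
#' @return An object of class `bin_decoding`: per-fold RDMs, assignments,
#'   validity, per-fold and mean accuracy.
#' @export
decode_bins <- function(patterns, frac_max = 0.1, min_frac = 0.05) {
  basis <- patterns$basis
  n_bins <- patterns$n_bins
  folds <- lapply(patterns$folds, function(f) {
    D <- compute_rdm(f)
    valid <- bin_validity(patterns$x_values[[f$fold]], basis,
                          frac_max, min_frac)
    assigned <- rep(NA_integer_, n_bins)
    for (j in which(valid)) {
      row <- D[j, ]
      if (all(is.na(row))) next
      assigned[j] <- which.min(row)  # ties -> lowest k
    }
    acc <- if (any(valid & !is.na(assigned))) {
      mean(assigned[valid] == seq_len(n_bins)[valid], na.rm = TRUE)
    } else NA_real_
    list(fold = f$fold, rdm = D, valid = valid, assigned = assigned,
         accuracy = acc)
  })
  accs <- vapply(folds, `[[`, numeric(1), "accuracy")
  if (anyNA(accs)) {
    warning("decode_bins: fold(s) without valid bins omitted from the accuracy average",
            call. = FALSE)
  }
  structure(list(folds = folds, accuracy_by_fold = accs,
                 accuracy = mean(accs, na.rm = TRUE),
                 n_bins = n_bins),
            class = "bin_decoding")
}

#' @export
print.bin_decoding <- function(x, ...) {
  cat(sprintf("correlation-distance bin decoding: %d bins, %d folds\n",
              x$n_bins, length(x$folds)))
  cat(sprintf("  mean accuracy over valid bins: %.3f (chance %.2f)\n",
              x$accuracy, 1 / x$n_bins))
  invisible(x)
}

#' Fold-averaged RDM
#'
#' Averages per-fold RDMs cell-wise, ignoring rows corresponding to
#' invalid bins in each fold.
#'
#' @param decoding A `bin_decoding` object.
#' @return Matrix (bins x bins) with attribute `valid_rows` (rows with at
#'   least one contributing fold).
#' @export
average_rdm <- function(decoding) {
  n <- decoding$n_bins
  acc <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (f in decoding$folds) {
    rows <- which(f$valid)
    D <- f$rdm
    ok <- !is.na(D)
    use <- matrix(FALSE, n, n)
    use[rows, ] <- TRUE
    use <- use & ok
    acc[use] <- acc[use] + D[use]
    cnt[use] <- cnt[use] + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  attr(out, "valid_rows") <- rowSums(cnt) > 0
  out
}

#' Regress an empirical RDM on identity and graded model RDMs
#'
#' Vectorizes all valid cells of the fold-averaged RDM (diagonal included)
#' and regresses them, with an intercept, on two theoretical
#' dissimilarity structures: the identity model (0 on the diagonal, 1 off
#' it, the signature of a highly non-monotonic code) and the graded model
#' (`|j - k|`, or `(j - k)^2`, the signature of a monotonic code).
#' Model predictors are z-scored over the included cells so the
#' coefficients are commensurable; the winning geometry is the model with
#' the larger coefficient.
#'
#' @param D Fold-averaged RDM matrix (e.g. from [average_rdm()]).
#' @param graded `"linear"` for `|j - k|` or `"quadratic"` for
#'   `(j - k)^2`.
#' @return An object of class `rdm_regression`: `coef_identity`,
#'   `coef_graded`, `intercept`, `winner`.
#' @export
regress_rdm <- function(D, graded = c("linear", "quadratic")) {
  graded <- match.arg(graded)
  n <- nrow(D)
  valid_rows <- attr(D, "valid_rows")
  if (is.null(valid_rows)) valid_rows <- rep(TRUE, n)
  if (sum(valid_rows) < 2L) {
    stop("regress_rdm: need at least 2 valid RDM rows", call. = FALSE)
  }
  jk <- expand.grid(j = seq_len(n), k = seq_len(n))
  keep <- valid_rows[jk$j] & !is.na(D[cbind(jk$j, jk$k)])
  y <- D[cbind(jk$j, jk$k)][keep]
  identity_m <- as.numeric(jk$j != jk$k)[keep]
  graded_m <- switch(graded,
                     linear = abs(jk$j - jk$k)[keep],
                     quadratic = (jk$j - jk$k)[keep]^2)
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  Xi <- zs(identity_m)
  Xg <- zs(graded_m)
  if (abs(stats::cor(Xi, Xg)) > 1 - 1e-10) {
    stop("regress_rdm: identity and graded predictors are collinear ",
         "after row exclusion", call. = FALSE)
  }
  fit <- stats::lm(y ~ Xi + Xg)
  co <- stats::coef(fit)
  structure(list(coef_identity = unname(co["Xi"]),
                 coef_graded = unname(co["Xg"]),
                 intercept = unname(co["(Intercept)"]),
                 winner = if (co["Xi"] >= co["Xg"]) "identity" else
                   "graded"),
            class = "rdm_regression")
}

#' @export
print.rdm_regression <- function(x, ...) {
  cat(sprintf("RDM regression: identity = %.3f, graded = %.3f -> winner: %s\n",
              x$coef_identity, x$coef_graded, x$winner))
  invisible(x)
}

#' Group-level decoding and RDM-geometry statistics
#'
#' Per region: two-sided one-sample t-test of the cohort's decoding
#' accuracies against chance, BH-FDR corrected across regions. Per
#' participant: the fraction of regions whose RDM is won by the graded
#' model, tested two-sided against 0.5 at the group level; when both
#' estimate types are supplied, their graded fractions are compared with a
#' paired two-sided t-test.
#'
#' @param accuracy Participants x regions matrix of mean accuracies.
#' @param winners Participants x regions character matrix
#'   (`"identity"`/`"graded"`), or `NULL`.
#' @param winners2 Optional second winners matrix (e.g. confidence vs
#'   probability) for the paired comparison.
#' @param chance Chance accuracy (default 0.2).
#' @param q FDR level.
#' @return List with `regions` (data frame: region, mean_accuracy, t, p,
#'   p_fdr, significant), `graded_fraction` test(s).
#' @export
group_decoding_stats <- function(accuracy, winners = NULL,
                                 winners2 = NULL, chance = 0.2,
                                 q = 0.05) {
  if (nrow(accuracy) < 2L) {
    stop("group_decoding_stats: need at least 2 participants",
         call. = FALSE)
  }
  region_tests <- do.call(rbind, lapply(seq_len(ncol(accuracy)),
                                        function(r) {
    res <- ttest_summary(accuracy[, r], mu = chance, kind = "one_sample")
    data.frame(region = r, mean_accuracy = mean(accuracy[, r]),
               t = res$t, p = res$p)
  }))
  adj <- fdr_bh(region_tests$p, q)
  region_tests$p_fdr <- adj$p_adj
  region_tests$significant <- adj$reject

  out <- list(regions = region_tests)
  if (!is.null(winners)) {
    frac <- rowMeans(winners == "graded")
    out$graded_fraction <- frac
    out$graded_vs_half <- ttest_summary(frac, mu = 0.5,
                                        kind = "one_sample")
    if (!is.null(winners2)) {
      frac2 <- rowMeans(winners2 == "graded")
      out$graded_fraction2 <- frac2
      out$paired_graded <- ttest_summary(frac, frac2, kind = "paired")
    }
  }
  out
}
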