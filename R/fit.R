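#' Fit an encoding model by ridge regression
#'
#' Closed-form ridge solve `w = (X'X + lambda I)^{-1} X'y`, no intercept
#' (data and regressors are expected to be session-demeaned by
#' [preprocess_sessions()]). The same penalty is shared across units; `y`
#' may be a matrix with one column per unit.
#'
#' @param X A numeric matrix (scans x regressors) or a `design_matrix`.
#' @param y Numeric vector or matrix (scans x units).
#' @param lambda Ridge penalty, `>= 0`.
#' @param interest_mask Logical per column marking regressors of interest;
#'   taken from `X` when it is a `design_matrix`.
#'
#' @return An object of class `encoding_fit` with components `weights`
#'   (regressors x units), `lambda`, `labels`, `interest_mask`.
#' @export
fit_encoding <- function(X, y, lambda = 1, interest_mask = NULL) {
  if (inherits(X, "design_matrix")) {
    if (is.null(interest_mask)) interest_mask <- X$interest_mask
    X <- X$X
  }
  y <- as.matrix(y)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("fit_encoding: non-finite values in X or y", call. = FALSE)
  }
  if (lambda < 0) stop("fit_encoding: `lambda` must be >= 0", call. = FALSE)
  p <- ncol(X)
  if (is.null(interest_mask)) interest_mask <- rep(TRUE, p)
  W <- solve(crossprod(X) + lambda * diag(p), crossprod(X, y))
  rownames(W) <- colnames(X)
  structure(list(weights = W, lambda = lambda,
                 labels = colnames(X), interest_mask = interest_mask),
            class = "encoding_fit")
}

#' @export
coef.encoding_fit <- function(object, interest_only = FALSE, ...) {
  W <- object$weights
  if (interest_only) W <- W[object$interest_mask, , drop = FALSE]
  if (ncol(W) == 1L) drop(W) else W
}

#' Predict from a fitted encoding model
#'
#' @param object An `encoding_fit`.
#' @param newdata Design matrix (or `design_matrix`) to predict from.
#' @param interest_only If `TRUE`, use only the regressors of interest
#'   (equivalent, after session demeaning, to setting the no-interest
#'   regressors to their session mean).
#' @param ... Unused.
#' @return Matrix of predictions (scans x units).
#' @export
predict.encoding_fit <- function(object, newdata,
                                 interest_only = FALSE, ...) {
  X <- if (inherits(newdata, "design_matrix")) newdata$X else newdata
  if (interest_only) {
    X[, object$interest_mask, drop = FALSE] %*%
      object$weights[object$interest_mask, , drop = FALSE]
  } else {
    X %*% object$weights
  }
}

#' @export
residuals.encoding_fit <- function(object, X, y, ...) {
  as.matrix(y) - predict(object, X)
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("ridge encoding fit: %d regressors (%d of interest), %d unit(s), lambda = %g\n",
              nrow(x$weights), sum(x$interest_mask), ncol(x$weights),
              x$lambda))
  invisible(x)
}

# Sums-of-squares R2 of predictions against data, per column (unit).
# May be negative on held-out data.
r2_score <- function(y, yhat) {
  y <- as.matrix(y)
  yhat <- as.matrix(yhat)
  ss_tot <- colSums(sweep(y, 2, colMeans(y), "-")^2)
  ss_res <- colSums((y - yhat)^2)
  1 - ss_res / ss_tot
}

# Core leave-one-session-out evaluation. X_list / Y_list: preprocessed
# per-session design and data matrices; null_int: list over null draws of
# per-session preprocessed interest-column matrices. Returns per-fold R2,
# null moments and z-R2 per unit.
cv_core <- function(X_list, interest_mask, Y_list, null_int, lambda) {
  n_sess <- length(X_list)
  n_units <- ncol(Y_list[[1]])
  n_null <- length(null_int)
  r2 <- matrix(NA_real_, n_sess, n_units)
  mu0 <- matrix(NA_real_, n_sess, n_units)
  sd0 <- matrix(NA_real_, n_sess, n_units)
  weights <- vector("list", n_sess)

  for (s in seq_len(n_sess)) {
    train <- setdiff(seq_len(n_sess), s)
    Xtr <- do.call(rbind, X_list[train])
    Ytr <- do.call(rbind, Y_list[train])
    fit <- fit_encoding(Xtr, Ytr, lambda, interest_mask)
    weights[[s]] <- fit$weights
    W_int <- fit$weights[interest_mask, , drop = FALSE]

    Yte <- Y_list[[s]]
    yhat <- X_list[[s]][, interest_mask, drop = FALSE] %*% W_int
    r2[s, ] <- r2_score(Yte, yhat)

    if (n_null > 0L) {
      null_r2 <- matrix(NA_real_, n_null, n_units)
      for (i in seq_len(n_null)) {
        yhat0 <- null_int[[i]][[s]] %*% W_int
        null_r2[i, ] <- r2_score(Yte, yhat0)
      }
      mu0[s, ] <- colMeans(null_r2)
      sd0[s, ] <- apply(null_r2, 2, stats::sd)
    }
  }
  z <- (r2 - mu0) / sd0
  z[!is.finite(z)] <- NA_real_
  list(r2 = r2, null_mean = mu0, null_sd = sd0, z_r2 = z,
       weights = weights)
}

# Generate null stimulus sequences (values + observer estimates) from the
# task process, shared across units and folds. Returns a list over draws,
# each a list over sessions of interest-modulator matrices (trials x K).
null_interest_modulators <- function(n_null, n_sess, task_cfg, obs, spec,
                                     timing = "prior") {
  lapply(seq_len(n_null), function(i) {
    lapply(seq_len(n_sess), function(s) {
      sq <- generate_sequence(task_cfg, seed = NULL, session_id = "null")
      tr <- run_ideal_observer(sq$values, obs, timing = timing)
      interest_modulators(tr, spec)
    })
  })
}

#' Evaluate an encoding model by cross-validated z-R2
#'
#' Leave-one-session-out cross-validation: the model is ridge-fitted on all
#' but one session and tested on the held-out session using the regressors
#' of interest only (sums-of-squares R2, which may be negative). A null
#' distribution of R2 is obtained by rebuilding the interest regressors
#' from `n_null` freshly generated task sequences (same generative process
#' and report timeline, the fitted weights kept) and scoring them against
#' the same held-out data; the z-R2 is `(R2 - mu0) / sd0`, averaged across
#' folds. Null sequences are drawn once and shared across units and folds.
#'
#' @param seqs List of `stim_sequence` objects (one per session).
#' @param Y List of raw data matrices (scans x units), one per session.
#' @param spec An [encoding_spec()].
#' @param lambda Ridge penalty.
#' @param n_null Number of null sequences (default 100).
#' @param seed Optional integer seed controlling the null draws.
#' @param obs Observer configuration used for the normative estimates.
#' @param hrf HRF specification.
#' @param reports Optional list of per-session report data frames (see
#'   [build_design()]).
#' @param motion Optional list of per-session motion confound matrices.
#' @param timing Estimate timing convention, `"prior"` or `"posterior"`.
#'
#' @return An object of class `encoding_cv`: per-fold `r2`, `null_mean`,
#'   `null_sd`, `z_r2` matrices (folds x units), the fold-averaged
#'   `z_r2_mean` and `r2_mean` per unit, per-fold training `weights`, and
#'   the spec.
#' @export
evaluate_encoding <- function(seqs, Y, spec, lambda = 1, n_null = 100L,
                              seed = NULL, obs = observer_config(),
                              hrf = hrf_spec(), reports = NULL,
                              motion = NULL,
                              timing = c("prior", "posterior")) {
  timing <- match.arg(timing)
  n_sess <- length(seqs)
  if (n_sess < 2L) {
    stop("evaluate_encoding: at least 2 sessions are required",
         call. = FALSE)
  }
  traces <- lapply(seqs, function(sq)
    run_ideal_observer(sq$values, obs, timing = timing))
  designs <- lapply(seq_len(n_sess), function(s)
    build_design(seqs[[s]], traces[[s]], spec, hrf,
                 reports = if (is.null(reports)) NULL else reports[[s]],
                 motion = if (is.null(motion)) NULL else motion[[s]]))
  interest_mask <- designs[[1]]$interest_mask
  tr <- seqs[[1]]$config$tr

  X_list <- preprocess_sessions(lapply(designs, `[[`, "X"), tr = tr)
  Y_list <- preprocess_sessions(Y, tr = tr)

  if (!is.null(seed)) set.seed(as.integer(seed))
  null_mods <- null_interest_modulators(n_null, n_sess,
                                        seqs[[1]]$config, obs, spec,
                                        timing)
  null_int <- lapply(null_mods, function(draw) {
    raw <- lapply(seq_len(n_sess), function(s)
      designs[[s]]$H_stim %*% draw[[s]])
    preprocess_sessions(raw, tr = tr)
  })

  res <- cv_core(X_list, interest_mask, Y_list, null_int, lambda)
  n_dropped <- sum(colSums(is.na(res$z_r2)) > 0)
  if (n_dropped > 0L) {
    warning(sprintf("evaluate_encoding: %d unit(s) with zero-variance null excluded from z-R2",
                    n_dropped), call. = FALSE)
  }
  structure(c(res,
              list(z_r2_mean = colMeans(res$z_r2),
                   r2_mean = colMeans(res$r2),
                   spec = spec, lambda = lambda, n_null = n_null)),
            class = "encoding_cv")
}

#' @export
print.encoding_cv <- function(x, ...) {
  cat(sprintf("cross-validated encoding evaluation (%s model of %s)\n",
              x$spec$model, x$spec$estimate))
  cat(sprintf("  %d folds x %d unit(s), %d null sequences, lambda = %g\n",
              nrow(x$r2), ncol(x$r2), x$n_null, x$lambda))
  cat(sprintf("  mean z-R2 across units: %.3f\n",
              mean(x$z_r2_mean, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.encoding_cv <- function(object, ...) {
  data.frame(unit = seq_along(object$z_r2_mean),
             r2 = object$r2_mean,
             z_r2 = object$z_r2_mean)
}

#' Simulation-based grid search for the ridge penalty
#'
#' Simulates voxels under a generative spec at the study's noise ratio and
#' returns the penalty maximizing the mean cross-validated z-R2 of the
#' matched model, mirroring how the penalty is calibrated in practice.
#'
#' @param seqs List of `stim_sequence` sessions.
#' @param spec Generative and fitted [encoding_spec()].
#' @param lambdas Candidate penalties.
#' @param n_voxels Simulated voxels per candidate evaluation.
#' @param noise_ratio Noise-to-signal power ratio.
#' @param n_null Null sequences per evaluation (kept small here).
#' @param seed Integer seed.
#' @return A list with `best` (the selected penalty) and `scores`.
#' @export
tune_ridge_lambda <- function(seqs, spec, lambdas = 10^seq(-2, 2),
                              n_voxels = 10L, noise_ratio = 9,
                              n_null = 30L, seed = 1L) {
  sim <- simulate_experiment(seqs[[1]]$config, spec,
                             n_voxels = n_voxels,
                             noise_ratio = noise_ratio, seed = seed,
                             seqs = seqs)
  scores <- vapply(lambdas, function(l) {
    cv <- evaluate_encoding(sim$seqs, sim$Y, spec, lambda = l,
                            n_null = n_null, seed = seed)
    mean(cv$z_r2_mean, na.rm = TRUE)
  }, numeric(1))
  list(best = lambdas[which.max(scores)],
       scores = data.frame(lambda = lambdas, mean_z_r2 = scores))
}
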