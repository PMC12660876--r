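#' Linear operator mapping event amplitudes to HRF-convolved scan samples
#'
#' Each event contributes a shifted copy of the canonical HRF scaled by its
#' amplitude; the operator evaluates those copies at the scan times, so
#' `H %*% amplitudes` is the convolved, TR-sampled regressor. This is the
#' exact limit of convolving an impulse train on an oversampled grid.
#'
#' @param scan_times Volume acquisition times (s).
#' @param onsets Event onsets (s).
#' @param hrf An [hrf_spec()].
#' @return A `length(scan_times) x length(onsets)` matrix.
#' @export
event_operator <- function(scan_times, onsets, hrf = hrf_spec()) {
  if (length(onsets) == 0L) {
    return(matrix(0, length(scan_times), 0L))
  }
  lags <- outer(scan_times, onsets, "-")
  matrix(hrf_at(lags, hrf), nrow = length(scan_times))
}

scan_times <- function(duration, tr) {
  n <- ceiling(duration / tr)
  (seq_len(n) - 1L) * tr
}

# Per-trial modulator values for the interest part of an encoding spec.
# Returns an n_trials x K matrix (K = 1 for the linear class). Estimate
# values outside the basis domain are clamped to the boundary (the count of
# clamped trials is attached as an attribute).
interest_modulators <- function(trace, spec) {
  est <- trace$estimates
  x <- switch(spec$estimate,
              probability = est$p_hat,
              confidence = est$confidence,
              entropy = est$entropy)
  n_clamped <- 0L
  if (!is.null(spec$basis)) {
    lo <- spec$basis$domain[1]
    hi <- spec$basis$domain[2]
    n_clamped <- sum(x < lo | x > hi)
    x <- pmin(pmax(x, lo), hi)
  }
  m <- switch(spec$model,
    linear = matrix(x, ncol = 1L, dimnames = list(NULL, "x")),
    versatile = eval_basis(spec$basis, x),
    posterior_expectation = posterior_expectation_modulators(trace, spec)
  )
  attr(m, "n_clamped") <- n_clamped
  m
}

# Posterior-expectation variant: the modulator for basis function f_i at
# trial t is the grid quadrature of f_i against the trial's posterior,
# sum_g f_i(grid_g) * posterior[t, g].
posterior_expectation_modulators <- function(trace, spec) {
  if (spec$estimate != "probability") {
    stop("posterior_expectation model requires the probability estimate ",
         "(the posterior is over the hidden probability)", call. = FALSE)
  }
  P <- if (identical(trace$timing, "prior")) trace$prior_pred else
    trace$posterior
  Fg <- eval_basis(spec$basis, trace$grid)        # G x K
  M <- P %*% Fg                                   # T x K
  colnames(M) <- colnames(Fg)
  M
}

#' Build the scan-resolution design matrix for one session
#'
#' Places the interest modulators (basis activations `f_i(x_t)` for the
#' versatile class, the estimate `x_t` itself for the linear class) as
#' impulses at stimulus onsets, convolves with the canonical HRF and
#' samples at the TR grid. No-interest regressors are added: stimulus-onset
#' constant, Shannon surprise, outcome entropy (omitted when entropy is the
#' estimate of interest), report-screen constant, report-screen normative
#' estimate, report-screen reported estimate, and optional motion columns.
#' Columns are returned *raw*; apply [preprocess_sessions()] before
#' fitting, identically to the data.
#'
#' @param seq A `stim_sequence`.
#' @param trace The matching `observer_trace` from [run_ideal_observer()].
#' @param spec An [encoding_spec()].
#' @param hrf An [hrf_spec()].
#' @param reports Optional data frame of simulated/behavioral reports with
#'   columns `p_norm`, `c_norm`, `p_report`, `c_report` (one row per report
#'   period); defaults to the normative values at the report trials.
#' @param motion Optional matrix of confound columns (n_scans x 6).
#' @param tr Repetition time (s); defaults to the task configuration.
#'
#' @return An object of class `design_matrix`: list with `X` (n_scans x p),
#'   `labels`, `interest_mask`, `scan_times`, `tr`, `spec`, and
#'   `n_clamped` (count of estimate values clamped into the basis domain).
#' @export
build_design <- function(seq, trace, spec, hrf = hrf_spec(),
                         reports = NULL, motion = NULL,
                         tr = seq$config$tr) {
  times <- scan_times(seq$duration, tr)
  H_stim <- event_operator(times, seq$onsets, hrf)

  mods <- interest_modulators(trace, spec)
  n_clamped <- attr(mods, "n_clamped")
  if (n_clamped > 0L) {
    warning(sprintf("build_design: %d estimate value(s) clamped to the basis domain",
                    n_clamped), call. = FALSE)
  }
  X_int <- H_stim %*% mods
  int_labels <- paste0("interest_", colnames(mods))

  ev <- trace$estimates
  no_int <- cbind(const = rep(1, length(seq$onsets)),
                  surprise = ev$surprise)
  if (spec$estimate != "entropy") {
    no_int <- cbind(no_int, entropy = ev$entropy)
  }
  X_noint <- H_stim %*% no_int

  # report-screen regressors: one probability screen and one confidence
  # screen per report period
  rep_on <- as.vector(t(seq$report_onsets))
  if (length(rep_on) > 0L) {
    if (is.null(reports)) {
      rt <- seq$report_trials
      reports <- data.frame(p_norm = ev$p_hat[rt],
                            c_norm = ev$confidence[rt],
                            p_report = ev$p_hat[rt],
                            c_report = ev$confidence[rt])
    }
    H_rep <- event_operator(times, rep_on, hrf)
    rep_amp <- cbind(
      rep_const = rep(1, length(rep_on)),
      rep_norm = as.vector(t(cbind(reports$p_norm, reports$c_norm))),
      rep_reported = as.vector(t(cbind(reports$p_report,
                                       reports$c_report))))
    X_rep <- H_rep %*% rep_amp
  } else {
    X_rep <- matrix(0, length(times), 0L)
  }

  X <- cbind(X_int, X_noint, X_rep)
  labels <- c(int_labels, colnames(no_int), colnames(X_rep))
  if (!is.null(motion)) {
    if (nrow(motion) != length(times)) {
      stop("build_design: motion confounds must have one row per scan",
           call. = FALSE)
    }
    X <- cbind(X, motion)
    labels <- c(labels, paste0("motion", seq_len(ncol(motion))))
  }
  colnames(X) <- labels
  interest_mask <- seq_along(labels) <= length(int_labels)

  structure(list(X = X, labels = labels, interest_mask = interest_mask,
                 scan_times = times, tr = tr, spec = spec,
                 n_clamped = n_clamped,
                 H_stim = H_stim),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design matrix: %d scans x %d regressors (%d of interest)\n",
              nrow(x$X), ncol(x$X), sum(x$interest_mask)))
  invisible(x)
}

# Residual-maker for the session-level temporal filter: projects out an
# intercept, a linear trend and a discrete-cosine drift basis up to the
# cutoff frequency (the standard drift model for slow scanner trends).
session_filter_matrix <- function(n, tr, cutoff = 1 / 128) {
  if (n < 2L) {
    stop("preprocess: sessions must contain at least 2 scans",
         call. = FALSE)
  }
  k_max <- floor(2 * n * tr * cutoff)
  t_idx <- seq_len(n) - 1L
  B <- cbind(1, t_idx)
  if (k_max >= 1L) {
    for (k in seq_len(k_max)) {
      B <- cbind(B, cos(pi * (2 * t_idx + 1) * k / (2 * n)))
    }
  }
  diag(n) - B %*% solve(crossprod(B), t(B))
}

#' Temporal preprocessing shared by data and regressors
#'
#' Per session: linear detrend and high-pass filtering at the cutoff
#' frequency (realized as removal of a discrete-cosine drift basis); then
#' column-wise z-scoring over the concatenation of all sessions; then
#' per-session demeaning. Constant columns become all-zero rather than
#' dividing by zero. The identical pipeline must be applied to voxel data
#' and to design-matrix columns.
#'
#' @param sessions List of per-session numeric matrices (scans x series),
#'   all with the same number of columns.
#' @param tr Repetition time (s).
#' @param cutoff High-pass cutoff frequency (Hz), default 1/128.
#' @return List of matrices of the same shapes, preprocessed.
#' @export
preprocess_sessions <- function(sessions, tr = 2, cutoff = 1 / 128) {
  sessions <- lapply(sessions, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  filtered <- lapply(sessions, function(m) {
    M <- session_filter_matrix(nrow(m), tr, cutoff)
    M %*% m
  })
  all_rows <- do.call(rbind, filtered)
  mu <- colMeans(all_rows)
  sdv <- apply(all_rows, 2, stats::sd)
  # columns the filter annihilates (constants, pure drift) become zeros
  # instead of amplified round-off
  raw_sd <- apply(do.call(rbind, sessions), 2, stats::sd)
  dead <- !is.finite(sdv) | sdv <= 1e-8 * (raw_sd + 1)
  sdv[dead] <- Inf
  mu[dead] <- 0
  out <- lapply(filtered, function(m) {
    m <- sweep(m, 2, mu, "-")
    m <- sweep(m, 2, sdv, "/")
    sweep(m, 2, colMeans(m), "-")  # session demean
  })
  lapply(out, function(m) {
    colnames(m) <- colnames(sessions[[1]])
    m
  })
}

#' Smooth random-walk motion confounds for synthetic sessions
#'
#' Six cumulative-sum Gaussian random walks, lightly smoothed, standing in
#' for rigid-body motion parameters.
#'
#' @param n_scans Number of volumes.
#' @param n_par Number of motion columns (default 6).
#' @param sd Innovation standard deviation.
#' @return An `n_scans x n_par` matrix.
#' @export
simulate_motion <- function(n_scans, n_par = 6L, sd = 0.02) {
  sapply(seq_len(n_par), function(i) {
    w <- cumsum(stats::rnorm(n_scans, sd = sd))
    stats::filter(w, rep(1 / 5, 5), sides = 2, circular = TRUE)
  })
}
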