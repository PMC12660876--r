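#' Simulate behavioral reports at the report trials
#'
#' Reports exist in the pipeline only as no-interest regressor fodder: the
#' reported value is the normative value plus Gaussian noise (sd 0.1),
#' discretized to the task's report scales (probability: a 3-range or
#' 5-range scale chosen at random per period; confidence: 5 levels spanning
#' the confidence domain).
#'
#' @param trace An `observer_trace` for the session.
#' @param seq The matching `stim_sequence`.
#' @param sd Report noise standard deviation.
#' @param conf_domain Confidence domain used for level discretization.
#' @return Data frame with one row per report period: `p_norm`, `c_norm`,
#'   `p_report`, `c_report`.
#' @export
simulate_reports <- function(trace, seq, sd = 0.1,
                             conf_domain = c(1.1, 2.6)) {
  rt <- seq$report_trials
  if (length(rt) == 0L) {
    return(data.frame(p_norm = numeric(0), c_norm = numeric(0),
                      p_report = numeric(0), c_report = numeric(0)))
  }
  est <- trace$estimates
  p_norm <- est$p_hat[rt]
  c_norm <- est$confidence[rt]
  discretize <- function(x, lo, hi, n_levels) {
    x <- pmin(pmax(x, lo), hi)
    bin <- pmin(floor((x - lo) / (hi - lo) * n_levels), n_levels - 1)
    lo + (bin + 0.5) * (hi - lo) / n_levels
  }
  n_scale <- sample(c(3L, 5L), length(rt), replace = TRUE)
  p_noisy <- p_norm + stats::rnorm(length(rt), sd = sd)
  c_noisy <- c_norm + stats::rnorm(length(rt), sd = sd)
  p_report <- vapply(seq_along(rt), function(i)
    discretize(p_noisy[i], 0, 1, n_scale[i]), numeric(1))
  c_report <- discretize(c_noisy, conf_domain[1], conf_domain[2], 5L)
  data.frame(p_norm = p_norm, c_norm = c_norm,
             p_report = p_report, c_report = c_report)
}

#' Simulate a voxel time series from a generative encoding model
#'
#' The signal is the weighted sum of the (raw, HRF-convolved) regressors of
#' interest; Gaussian white noise is added with power equal to
#' `noise_ratio` times the signal power (computed over the concatenated
#' sessions), i.e. the default 9 gives 10% signal / 90% noise.
#'
#' @param X_int List of per-session raw interest-regressor matrices.
#' @param weights Generative interest weights (length = columns of
#'   `X_int`).
#' @param noise_ratio Noise-to-signal power ratio (`>= 0`).
#' @param seed Optional integer seed.
#' @return List of per-session numeric vectors (the voxel time series).
#' @export
simulate_voxel <- function(X_int, weights, noise_ratio = 9, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  signal <- lapply(X_int, function(X) drop(X %*% weights))
  v <- stats::var(unlist(signal))
  if (v == 0 && noise_ratio > 0) {
    stop("simulate_voxel: zero-variance signal with positive noise ratio",
         call. = FALSE)
  }
  lapply(signal, function(s)
    s + stats::rnorm(length(s), sd = sqrt(noise_ratio * v)))
}

draw_interest_weights <- function(K, n_voxels, range = c(-0.5, 0.5)) {
  matrix(stats::runif(K * n_voxels, range[1], range[2]), K, n_voxels)
}

#' Simulate a complete synthetic experiment
#'
#' Generates `n_sessions` task sequences, runs the ideal observer,
#' simulates reports, builds the generative design, draws per-voxel
#' interest weights uniformly in `[-0.5, 0.5]` and produces noisy voxel
#' time series at the requested noise ratio. Ground truth is stored.
#'
#' @param task A [task_config()].
#' @param gspec Generative [encoding_spec()].
#' @param n_voxels Number of simulated voxels.
#' @param noise_ratio Noise-to-signal power ratio (default 9).
#' @param seed Integer seed (same seed, identical experiment).
#' @param obs Observer configuration.
#' @param hrf HRF specification.
#' @param weights Optional generative weight matrix (K x n_voxels)
#'   overriding the uniform draw.
#' @param seqs Optional pre-generated list of sessions.
#' @param timing Estimate timing convention.
#' @return An object of class `synth_experiment`: `seqs`, `traces`,
#'   `reports`, `designs` (raw, generative spec), `Y` (list of raw
#'   scans-x-voxels matrices), `weights`, `gspec`, `noise_ratio`, `seed`.
#' @export
simulate_experiment <- function(task = task_config(), gspec,
                                n_voxels = 20L, noise_ratio = 9,
                                seed = 1L, obs = observer_config(),
                                hrf = hrf_spec(), weights = NULL,
                                seqs = NULL,
                                timing = c("prior", "posterior")) {
  timing <- match.arg(timing)
  set.seed(as.integer(seed))
  if (is.null(seqs)) {
    seqs <- lapply(seq_len(task$n_sessions), function(s)
      generate_sequence(task, seed = NULL,
                        session_id = paste0("session", s)))
  }
  traces <- lapply(seqs, function(sq)
    run_ideal_observer(sq$values, obs, timing = timing))
  reports <- lapply(seq_along(seqs), function(s)
    simulate_reports(traces[[s]], seqs[[s]]))
  designs <- lapply(seq_along(seqs), function(s)
    build_design(seqs[[s]], traces[[s]], gspec, hrf,
                 reports = reports[[s]]))
  K <- sum(designs[[1]]$interest_mask)
  if (is.null(weights)) weights <- draw_interest_weights(K, n_voxels)
  X_int <- lapply(designs, function(d)
    d$X[, d$interest_mask, drop = FALSE])
  Y <- vector("list", length(seqs))
  series <- lapply(seq_len(n_voxels), function(v)
    simulate_voxel(X_int, weights[, v], noise_ratio))
  for (s in seq_along(seqs)) {
    Y[[s]] <- vapply(series, `[[`, numeric(nrow(X_int[[s]])), s)
  }
  structure(list(seqs = seqs, traces = traces, reports = reports,
                 designs = designs, Y = Y, weights = weights,
                 gspec = gspec, noise_ratio = noise_ratio,
                 seed = as.integer(seed), timing = timing,
                 obs = obs, hrf = hrf),
            class = "synth_experiment")
}

#' @export
print.synth_experiment <- function(x, ...) {
  cat(sprintf("synthetic experiment: %d sessions x %d voxels, %s generative code, noise:signal = %g:1\n",
              length(x$seqs), ncol(x$Y[[1]]), spec_label(x$gspec),
              x$noise_ratio))
  invisible(x)
}

default_model_set <- function() {
  list(`linear-probability` = encoding_spec("linear", "probability"),
       `versatile-probability` = encoding_spec("versatile", "probability"),
       `linear-confidence` = encoding_spec("linear", "confidence"),
       `versatile-confidence` = encoding_spec("versatile", "confidence"))
}

#' Model-recovery simulation (generative x fitted z-R2 matrix)
#'
#' For each simulated experiment, voxels are generated under every
#' generative model, every fitted model is evaluated by cross-validated
#' z-R2, and the scores are averaged over voxels and experiments. Null
#' sequences are drawn once per experiment and shared across fitted
#' models, units and folds. The default desk scale is 10 experiments x 20
#' voxels (the full-scale simulation uses 100 x 100).
#'
#' @param n_experiments,n_voxels Simulation scale.
#' @param gen_specs,fit_specs Named lists of [encoding_spec()]s; default
#'   the 2 x 2 set {linear, versatile} x {probability, confidence}.
#' @param lambda Ridge penalty.
#' @param n_null Null sequences per evaluation.
#' @param noise_ratio Noise-to-signal power ratio.
#' @param seed Integer seed.
#' @param task,obs,hrf Configurations shared by all experiments.
#' @return An object of class `recovery_matrix`: `mean_z_r2` and
#'   `frac_best` (generative x fitted matrices), plus the per-experiment
#'   score array `z_by_experiment`.
#' @export
model_recovery <- function(n_experiments = 10L, n_voxels = 20L,
                           gen_specs = default_model_set(),
                           fit_specs = default_model_set(),
                           lambda = 1, n_null = 100L, noise_ratio = 9,
                           seed = 1L, task = task_config(),
                           obs = observer_config(), hrf = hrf_spec()) {
  n_gen <- length(gen_specs)
  n_fit <- length(fit_specs)
  zarr <- array(NA_real_, c(n_gen, n_fit, n_experiments),
                dimnames = list(names(gen_specs), names(fit_specs), NULL))

  for (e in seq_len(n_experiments)) {
    set.seed(as.integer(seed) + e)
    seqs <- lapply(seq_len(task$n_sessions), function(s)
      generate_sequence(task, seed = NULL,
                        session_id = paste0("session", s)))
    traces <- lapply(seqs, function(sq) run_ideal_observer(sq$values, obs))
    reports <- lapply(seq_along(seqs), function(s)
      simulate_reports(traces[[s]], seqs[[s]]))

    all_specs <- c(gen_specs, fit_specs[setdiff(names(fit_specs),
                                                names(gen_specs))])
    designs <- lapply(all_specs, function(sp)
      lapply(seq_along(seqs), function(s)
        build_design(seqs[[s]], traces[[s]], sp, hrf,
                     reports = reports[[s]])))
    tr <- task$tr
    Xp <- lapply(designs, function(ds)
      preprocess_sessions(lapply(ds, `[[`, "X"), tr = tr))

    # null sequences: drawn once, shared across fitted models
    null_traces <- lapply(seq_len(n_null), function(i)
      lapply(seq_along(seqs), function(s) {
        sq <- generate_sequence(task, seed = NULL)
        run_ideal_observer(sq$values, obs)
      }))
    H_stim <- lapply(designs[[1]], `[[`, "H_stim")
    null_int <- lapply(names(fit_specs), function(f) {
      sp <- fit_specs[[f]]
      lapply(null_traces, function(draw) {
        raw <- lapply(seq_along(seqs), function(s)
          H_stim[[s]] %*% interest_modulators(draw[[s]], sp))
        preprocess_sessions(raw, tr = tr)
      })
    })
    names(null_int) <- names(fit_specs)

    for (g in names(gen_specs)) {
      dg <- designs[[g]]
      X_int <- lapply(dg, function(d) d$X[, d$interest_mask, drop = FALSE])
      K <- ncol(X_int[[1]])
      W <- draw_interest_weights(K, n_voxels)
      series <- lapply(seq_len(n_voxels), function(v)
        simulate_voxel(X_int, W[, v], noise_ratio))
      Y <- lapply(seq_along(seqs), function(s)
        vapply(series, `[[`, numeric(nrow(X_int[[s]])), s))
      Yp <- preprocess_sessions(Y, tr = tr)

      for (f in names(fit_specs)) {
        mask <- designs[[f]][[1]]$interest_mask
        res <- cv_core(Xp[[f]], mask, Yp, null_int[[f]], lambda)
        zarr[g, f, e] <- mean(colMeans(res$z_r2), na.rm = TRUE)
      }
    }
  }

  mean_z <- apply(zarr, c(1, 2), mean)
  winners <- apply(zarr, c(1, 3), which.max)
  frac_best <- t(vapply(seq_len(n_gen), function(g)
    tabulate(winners[g, ], nbins = n_fit) / n_experiments,
    numeric(n_fit)))
  dimnames(frac_best) <- dimnames(mean_z)

  structure(list(mean_z_r2 = mean_z, frac_best = frac_best,
                 z_by_experiment = zarr,
                 n_experiments = n_experiments, n_voxels = n_voxels,
                 noise_ratio = noise_ratio, lambda = lambda,
                 n_null = n_null, seed = as.integer(seed)),
            class = "recovery_matrix")
}

#' @export
print.recovery_matrix <- function(x, ...) {
  cat(sprintf("model recovery: %d experiments x %d voxels, noise:signal = %g:1\n",
              x$n_experiments, x$n_voxels, x$noise_ratio))
  cat("mean z-R2 (rows = generative, cols = fitted):\n")
  print(round(x$mean_z_r2, 3))
  cat("fraction of experiments won by each fitted model:\n")
  print(round(x$frac_best, 3))
  invisible(x)
}
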