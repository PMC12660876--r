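#' Ideal-observer configuration
#'
#' The Bayes-optimal observer of the change-point Bernoulli task tracks a
#' posterior distribution over the hidden probability on a discrete grid.
#' Between observations the posterior is propagated through the change-point
#' transition kernel: with probability `1 - hazard` the hidden probability
#' stays put, with probability `hazard` it is resampled from
#' `resample_prior`.
#'
#' @param grid Strictly increasing probability values; default 100 equally
#'   spaced points spanning `p_support`.
#' @param hazard Per-trial change-point probability assumed by the observer.
#' @param p_support Interval the default grid and prior span.
#' @param resample_prior Weights over the grid used at (assumed) change
#'   points and as the initial prior; default uniform. Normalized
#'   internally.
#'
#' @return An object of class `observer_config`.
#' @export
observer_config <- function(grid = NULL,
                            hazard = 1 / 75,
                            p_support = c(0.1, 0.9),
                            resample_prior = NULL) {
  if (is.null(grid)) {
    grid <- seq(p_support[1], p_support[2], length.out = 100L)
  }
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("observer_config: `grid` must be strictly increasing, length >= 2",
         call. = FALSE)
  }
  if (any(grid <= 0) || any(grid >= 1)) {
    stop("observer_config: `grid` values must lie inside (0, 1)",
         call. = FALSE)
  }
  if (!(hazard >= 0 && hazard < 1)) {
    stop("observer_config: `hazard` must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(resample_prior)) {
    resample_prior <- rep(1, length(grid))
  }
  if (length(resample_prior) != length(grid) || any(resample_prior < 0)) {
    stop("observer_config: `resample_prior` must be nonnegative weights ",
         "matching the grid", call. = FALSE)
  }
  resample_prior <- resample_prior / sum(resample_prior)
  structure(list(grid = grid, hazard = hazard,
                 resample_prior = resample_prior),
            class = "observer_config")
}

posterior_moments <- function(w, grid) {
  m <- sum(w * grid)
  v <- sum(w * (grid - m)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Run the change-point ideal observer on a binary sequence
#'
#' Grid filtering of the hidden Bernoulli parameter: starting from the
#' resampling prior, each observation `s_t` updates the posterior as
#' `posterior_t \eqn{\propto} lik(s_t | h) * [(1 - hazard) * posterior_{t-1}
#' + hazard * prior]`, normalized over the grid.
#'
#' Per trial the observer reports a probability estimate (posterior mean),
#' a confidence (minus the log posterior standard deviation, i.e. the log
#' precision up to a factor of two), the Shannon surprise of the observed
#' stimulus and the Shannon entropy of the predicted outcome. Under the
#' default `timing = "prior"` convention these are computed from the
#' distribution held *before* observing `s_t` (the transition-propagated
#' prior predictive), so that surprise `-log p(s_t)` is defined from the
#' same quantity; `timing = "posterior"` uses the post-update posterior
#' instead (surprise always uses the pre-update prediction).
#'
#' @param x A `stim_sequence` or a 0/1 vector (1 = stimulus A).
#' @param obs An [observer_config()].
#' @param timing `"prior"` (default) or `"posterior"`; see Details.
#'
#' @return An object of class `observer_trace`: list with `grid`,
#'   `posterior` (T x G matrix, row t = p(h_t | s_1:t)), `prior_pred`
#'   (T x G matrix, row t = distribution before observing s_t), and
#'   `estimates`, a data frame with columns `trial`, `p_hat`, `confidence`,
#'   `surprise`, `entropy`.
#' @export
run_ideal_observer <- function(x, obs = observer_config(),
                               timing = c("prior", "posterior")) {
  timing <- match.arg(timing)
  values <- if (inherits(x, "stim_sequence")) x$values else as.integer(x)
  if (any(!values %in% c(0L, 1L))) {
    stop("run_ideal_observer: sequence values must be 0/1", call. = FALSE)
  }
  grid <- obs$grid
  G <- length(grid)
  n <- length(values)
  posterior <- matrix(NA_real_, n, G)
  prior_pred <- matrix(NA_real_, n, G)
  p_hat <- conf <- surprise <- entropy <- numeric(n)

  cur <- obs$resample_prior  # posterior after 0 observations
  for (t in seq_len(n)) {
    pred <- (1 - obs$hazard) * cur + obs$hazard * obs$resample_prior
    pred <- pred / sum(pred)
    prior_pred[t, ] <- pred
    lik <- if (values[t] == 1L) grid else 1 - grid
    post <- pred * lik
    z <- sum(post)
    if (!is.finite(z) || z <= 0) {
      stop("run_ideal_observer: degenerate posterior at trial ", t,
           call. = FALSE)
    }
    post <- post / z
    posterior[t, ] <- post

    w <- if (timing == "prior") pred else post
    mo <- posterior_moments(w, grid)
    p_hat[t] <- mo["mean"]
    conf[t] <- -log(mo["sd"])
    # Surprise is always the prediction error of the observed stimulus.
    p_pred_mean <- sum(pred * grid)
    surprise[t] <- -log(if (values[t] == 1L) p_pred_mean else 1 - p_pred_mean)
    entropy[t] <- binary_entropy(p_hat[t])
    cur <- post
  }

  structure(
    list(grid = grid,
         posterior = posterior,
         prior_pred = prior_pred,
         estimates = data.frame(trial = seq_len(n), p_hat = p_hat,
                                confidence = conf, surprise = surprise,
                                entropy = entropy),
         timing = timing,
         obs = obs),
    class = "observer_trace"
  )
}

#' @export
print.observer_trace <- function(x, ...) {
  n <- nrow(x$estimates)
  cat("Change-point ideal observer trace:", n, "trials,",
      length(x$grid), "grid points\n")
  cat("  p_hat range:      [",
      paste(round(range(x$estimates$p_hat), 3), collapse = ", "), "]\n")
  cat("  confidence range: [",
      paste(round(range(x$estimates$confidence), 3), collapse = ", "), "]\n")
  invisible(x)
}

binary_entropy <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log(p) - (1 - p) * log(1 - p))
}

#' Shannon surprise and outcome entropy of a predicted binary event
#'
#' `surprise = -log p(s)` where `p(s)` is the predicted probability of the
#' observed stimulus value, and `entropy = -p log p - (1-p) log(1-p)`, both
#' in nats.
#'
#' @param p_prev Predicted probability of stimulus A, strictly in (0, 1).
#' @param stimulus 0/1 observed value (1 = A).
#' @return A list with vectors `surprise` and `entropy`.
#' @export
compute_event_quantities <- function(p_prev, stimulus) {
  if (any(p_prev <= 0) || any(p_prev >= 1)) {
    stop("compute_event_quantities: `p_prev` must lie strictly in (0, 1)",
         call. = FALSE)
  }
  p_s <- ifelse(stimulus == 1L, p_prev, 1 - p_prev)
  list(surprise = -log(p_s), entropy = binary_entropy(p_prev))
}

#' Exact change-point posterior by enumeration
#'
#' Reference computation of the posterior over the hidden probability after
#' observing a short binary prefix, by explicit summation over all
#' change-point configurations of the prefix (each weighted by
#' `hazard^changes * (1-hazard)^(non-changes)`, with per-segment Bernoulli
#' likelihoods integrated against the resampling prior on the grid).
#' Exponential in the prefix length; intended as an independent check of
#' [run_ideal_observer()] on short sequences.
#'
#' @param values 0/1 vector, length at most 12.
#' @param obs An [observer_config()].
#' @return Normalized posterior weights over `obs$grid` for the hidden
#'   probability at the final trial.
#' @export
enumerate_posterior <- function(values, obs = observer_config()) {
  values <- as.integer(values)
  n <- length(values)
  if (n > 12L) {
    stop("enumerate_posterior: prefix longer than 12 (combinatorial ",
         "explosion); use run_ideal_observer", call. = FALSE)
  }
  grid <- obs$grid
  prior <- obs$resample_prior
  h <- obs$hazard
  lik1 <- function(s) if (s == 1L) grid else 1 - grid

  post <- rep(0, length(grid))
  n_gaps <- n - 1L
  for (code in 0:(2^n_gaps - 1L)) {
    changes <- if (n_gaps > 0) {
      as.logical(bitwAnd(code, 2^(0:(n_gaps - 1L))))
    } else logical(0)
    # segment boundaries: a new segment starts at t=1 and after each change
    seg_start <- c(1L, which(changes) + 1L)
    seg_end <- c(seg_start[-1L] - 1L, n)
    w_config <- h^sum(changes) * (1 - h)^(n_gaps - sum(changes))
    contrib <- w_config
    n_seg <- length(seg_start)
    for (k in seq_len(n_seg)) {
      seg_lik <- rep(1, length(grid))
      for (t in seg_start[k]:seg_end[k]) {
        seg_lik <- seg_lik * lik1(values[t])
      }
      if (k < n_seg) {
        contrib <- contrib * sum(prior * seg_lik)
      } else {
        contrib <- contrib * prior * seg_lik
      }
    }
    post <- post + contrib
  }
  post / sum(post)
}

#' Export per-trial normative estimates as TSV
#'
#' @param trace An `observer_trace`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_estimates_tsv <- function(trace, path) {
  df <- trace$estimates
  df$trial_index <- df$trial - 1L
  utils::write.table(
    df[, c("trial_index", "p_hat", "confidence", "surprise", "entropy")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
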