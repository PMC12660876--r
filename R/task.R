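#' Task configuration for the change-point probability sequence
#'
#' Parameters of the generative process used in the probability-learning
#' task: a binary stimulus stream whose hidden Bernoulli parameter `h_t`
#' undergoes abrupt change points at a constant per-trial hazard, with
#' occasional report periods interleaved between stimuli.
#'
#' @param n_stimuli Number of stimuli per session.
#' @param n_sessions Number of sessions per simulated participant.
#' @param hazard Per-trial change-point probability of the hidden parameter.
#' @param p_support Closed interval from which the hidden probability is
#'   (re)sampled uniformly.
#' @param min_odds_factor At a change point, the odds `p/(1-p)` must change
#'   by at least this factor (in either direction).
#' @param max_run Maximum number of trials without a change point; a change
#'   is forced when a run reaches this length.
#' @param report_mean_interval Mean number of stimuli between report periods.
#' @param report_jitter Maximum uniform jitter (in trials) of that interval.
#' @param soa Stimulus-onset asynchrony in seconds.
#' @param stimulus_duration Stimulus presentation duration in seconds.
#' @param report_period_duration Duration, in seconds, of one report period
#'   (two response screens).
#' @param report_screen_offsets Onsets of the two response screens relative
#'   to the start of the report period, in seconds.
#' @param tr Scanner repetition time in seconds (volume sampling interval).
#'
#' @return An object of class `task_config` (a validated list).
#' @export
task_config <- function(n_stimuli = 420L,
                        n_sessions = 4L,
                        hazard = 1 / 75,
                        p_support = c(0.1, 0.9),
                        min_odds_factor = 4,
                        max_run = 300L,
                        report_mean_interval = 22L,
                        report_jitter = 3L,
                        soa = 1.3,
                        stimulus_duration = 1.0,
                        report_period_duration = 10,
                        report_screen_offsets = c(0, 5),
                        tr = 2) {
  cfg <- list(
    n_stimuli = as.integer(n_stimuli),
    n_sessions = as.integer(n_sessions),
    hazard = hazard,
    p_support = as.numeric(p_support),
    min_odds_factor = min_odds_factor,
    max_run = as.numeric(max_run),
    report_mean_interval = report_mean_interval,
    report_jitter = report_jitter,
    soa = soa,
    stimulus_duration = stimulus_duration,
    report_period_duration = report_period_duration,
    report_screen_offsets = report_screen_offsets,
    tr = tr
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (!(cfg$hazard >= 0 && cfg$hazard < 1)) {
    stop("task_config: `hazard` must lie in [0, 1)", call. = FALSE)
  }
  if (length(cfg$p_support) != 2L ||
      cfg$p_support[1] >= cfg$p_support[2] ||
      cfg$p_support[1] <= 0 || cfg$p_support[2] >= 1) {
    stop("task_config: `p_support` must be an interval inside (0, 1)",
         call. = FALSE)
  }
  if (cfg$min_odds_factor < 1) {
    stop("task_config: `min_odds_factor` must be >= 1", call. = FALSE)
  }
  if (cfg$max_run < 1) {
    stop("task_config: `max_run` must be >= 1", call. = FALSE)
  }
  if (!(cfg$report_mean_interval > cfg$report_jitter) ||
      cfg$report_jitter < 0) {
    stop("task_config: need `report_mean_interval` > `report_jitter` >= 0",
         call. = FALSE)
  }
  if (cfg$n_stimuli < 1 || cfg$n_sessions < 1) {
    stop("task_config: `n_stimuli` and `n_sessions` must be >= 1",
         call. = FALSE)
  }
  invisible(cfg)
}

odds <- function(p) p / (1 - p)

# Resample the hidden probability uniformly on the support, rejecting draws
# whose odds change by less than the minimum factor relative to `p_old`.
resample_hidden_p <- function(p_old, cfg) {
  lo <- cfg$p_support[1]
  hi <- cfg$p_support[2]
  repeat {
    p_new <- stats::runif(1, lo, hi)
    ratio <- odds(p_new) / odds(p_old)
    if (max(ratio, 1 / ratio) >= cfg$min_odds_factor) {
      return(p_new)
    }
  }
}

#' Generate one session of the change-point Bernoulli task
#'
#' Draws a hidden probability trajectory under the constant-hazard
#' change-point process (forced change at `max_run`, odds-factor constraint
#' at every change), samples the binary stimulus sequence from it, and lays
#' out the session timeline: stimulus onsets every `soa` seconds, with a
#' report period (two response screens) inserted after each report trial.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param session_id Label stored with the sequence.
#'
#' @return An object of class `stim_sequence`: a list with `values` (0/1,
#'   1 = stimulus A), `hidden_p`, `change_points` (trial indices whose
#'   hidden probability differs from the previous trial), `report_trials`
#'   (trial after which a report period occurs), `onsets` (s),
#'   `report_onsets` (s, one row per report period, one column per response
#'   screen), `duration` (s) and the config.
#' @export
generate_sequence <- function(config = task_config(), seed = NULL,
                              session_id = "session1") {
  validate_task_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$n_stimuli

  hidden_p <- numeric(n)
  change_points <- integer(0)
  p <- stats::runif(1, config$p_support[1], config$p_support[2])
  run <- 1
  hidden_p[1] <- p
  if (n > 1) {
    for (t in 2:n) {
      change <- (run >= config$max_run) ||
        (stats::runif(1) < config$hazard)
      if (change) {
        p <- resample_hidden_p(p, config)
        change_points <- c(change_points, t)
        run <- 1
      } else {
        run <- run + 1
      }
      hidden_p[t] <- p
    }
  }
  values <- as.integer(stats::runif(n) < hidden_p)

  report_trials <- report_schedule(n, config)
  timeline <- session_timeline(n, report_trials, config)

  structure(
    list(
      values = values,
      hidden_p = hidden_p,
      change_points = change_points,
      report_trials = report_trials,
      onsets = timeline$onsets,
      report_onsets = timeline$report_onsets,
      duration = timeline$duration,
      session_id = session_id,
      config = config
    ),
    class = "stim_sequence"
  )
}

# Report trials at cumulative intervals of `report_mean_interval` plus a
# uniform integer jitter in [-report_jitter, report_jitter]; first report
# after the first full interval.
report_schedule <- function(n, cfg) {
  trials <- integer(0)
  pos <- 0
  repeat {
    jit <- if (cfg$report_jitter > 0) {
      sample(seq(-cfg$report_jitter, cfg$report_jitter), 1)
    } else 0
    pos <- pos + round(cfg$report_mean_interval + jit)
    if (pos > n) break
    trials <- c(trials, as.integer(pos))
  }
  trials
}

# Stimulus onsets at SOA spacing with a fixed-duration gap inserted after
# every report trial; report screens at fixed offsets inside the gap.
session_timeline <- function(n, report_trials, cfg) {
  onsets <- numeric(n)
  report_onsets <- matrix(numeric(0), ncol = length(cfg$report_screen_offsets))
  t0 <- 0
  for (i in seq_len(n)) {
    onsets[i] <- t0
    t0 <- t0 + cfg$soa
    if (i %in% report_trials) {
      report_onsets <- rbind(report_onsets,
                             t0 + cfg$report_screen_offsets)
      t0 <- t0 + cfg$report_period_duration
    }
  }
  list(onsets = onsets,
       report_onsets = report_onsets,
       duration = t0 + cfg$report_period_duration)
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat("Change-point Bernoulli stimulus sequence (", x$session_id, ")\n",
      sep = "")
  cat("  trials:        ", length(x$values), "\n", sep = "")
  cat("  change points: ", length(x$change_points), "\n", sep = "")
  cat("  report periods:", length(x$report_trials), "\n")
  cat("  duration:      ", round(x$duration, 1), " s\n", sep = "")
  invisible(x)
}

#' Export a stimulus sequence as a BIDS-style events table
#'
#' Writes a tab-separated events table with columns `onset`, `duration`,
#' `trial_index` (0-based), `stimulus` (A/B), `hidden_p`, `is_change_point`
#' and `is_report`.
#'
#' @param seq A `stim_sequence`.
#' @param path File path for the TSV output.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(seq, path) {
  n <- length(seq$values)
  df <- data.frame(
    onset = seq$onsets,
    duration = rep(seq$config$stimulus_duration, n),
    trial_index = seq_len(n) - 1L,
    stimulus = ifelse(seq$values == 1L, "A", "B"),
    hidden_p = seq$hidden_p,
    is_change_point = as.integer(seq_len(n) %in% seq$change_points),
    is_report = as.integer(seq_len(n) %in% seq$report_trials)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a BIDS-style events table back into a stimulus sequence
#'
#' Inverse of [write_events_tsv()]. Report-period timing is reconstructed
#' from the supplied task configuration.
#'
#' @param path Path to an events TSV written by [write_events_tsv()].
#' @param config The [task_config()] describing the session layout.
#' @param session_id Label for the reconstructed sequence.
#' @return A `stim_sequence`.
#' @export
read_events_tsv <- function(path, config = task_config(),
                            session_id = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  n <- nrow(df)
  report_trials <- which(df$is_report == 1L)
  timeline <- session_timeline(n, report_trials, config)
  structure(
    list(
      values = as.integer(df$stimulus == "A"),
      hidden_p = df$hidden_p,
      change_points = which(df$is_change_point == 1L),
      report_trials = as.integer(report_trials),
      onsets = df$onset,
      report_onsets = timeline$report_onsets,
      duration = timeline$duration,
      session_id = session_id,
      config = config
    ),
    class = "stim_sequence"
  )
}
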