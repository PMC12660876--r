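# Independent reference implementations used as oracles, deliberately
# naive and separate from the package's code paths.

# Exhaustive peak detection: every interior strict local maximum of the
# min-max normalized curve, with prominence computed by full traversal
# (minimum of the stretch to the nearest higher point on each side; the
# prominence is the drop to the higher of the two stretch minima).
oracle_count_peaks <- function(values, height = 0.7, prominence = 0.125) {
  rng <- range(values)
  if (diff(rng) == 0) return(0L)
  v <- (values - rng[1]) / diff(rng)
  n <- length(v)
  count <- 0L
  for (p in 2:(n - 1)) {
    if (!(v[p] > v[p - 1] && v[p] > v[p + 1])) next
    if (v[p] < height) next
    left <- p
    while (left > 1 && v[left - 1] <= v[p]) left <- left - 1
    right <- p
    while (right < n && v[right + 1] <= v[p]) right <- right + 1
    left_min <- min(v[left:p])
    right_min <- min(v[p:right])
    if (v[p] - max(left_min, right_min) >= prominence) count <- count + 1L
  }
  count
}

# Small task configuration for fast unit tests (short sessions).
small_task <- function(n_stimuli = 80L, ...) {
  task_config(n_stimuli = n_stimuli, ...)
}

# White-noise session data matching a list of sequences.
noise_sessions <- function(seqs, n_units, tr = 2) {
  lapply(seqs, function(sq)
    matrix(rnorm(ceiling(sq$duration / tr) * n_units), ncol = n_units))
}
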