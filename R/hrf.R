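#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF is the difference of two gamma densities: a positive
#' response peaking around 6 s and a delayed undershoot around 16 s, scaled
#' so the kernel's maximum is 1 (the overall scale is absorbed by the
#' regression weights).
#'
#' @param peak_delay,undershoot_delay Delays (s) of response and undershoot.
#' @param peak_disp,undershoot_disp Dispersions of the two gamma densities.
#' @param ratio Undershoot-to-peak amplitude ratio.
#' @param duration Kernel length in seconds (support of the response).
#' @param oversampling Sub-TR sampling step (s) used by [hrf_kernel()].
#'
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_disp = 1, undershoot_disp = 1,
                     ratio = 1 / 6, duration = 32, oversampling = 0.1) {
  if (duration < 24) {
    stop("hrf_spec: `duration` must be at least 24 s", call. = FALSE)
  }
  spec <- list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
               peak_disp = peak_disp, undershoot_disp = undershoot_disp,
               ratio = ratio, duration = duration,
               oversampling = oversampling)
  # peak value of the un-normalized kernel, for max-1 scaling
  tt <- seq(0, duration, by = oversampling)
  spec$scale <- max(hrf_raw(tt, spec))
  if (spec$scale <= 0) {
    stop("hrf_spec: kernel must integrate to a positive response",
         call. = FALSE)
  }
  class(spec) <- "hrf_spec"
  spec
}

hrf_raw <- function(t, spec) {
  out <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_disp,
                       rate = 1 / spec$peak_disp) -
    spec$ratio * stats::dgamma(t,
                               shape = spec$undershoot_delay /
                                 spec$undershoot_disp,
                               rate = 1 / spec$undershoot_disp)
  out[t < 0 | t > spec$duration] <- 0
  out
}

#' Evaluate the canonical HRF at arbitrary lags
#'
#' @param t Lags in seconds (values outside `[0, duration]` give 0).
#' @param spec An [hrf_spec()].
#' @return Response values, peak-normalized to 1.
#' @export
hrf_at <- function(t, spec = hrf_spec()) {
  hrf_raw(t, spec) / spec$scale
}

#' Sample the HRF kernel on the oversampled grid
#'
#' @param spec An [hrf_spec()].
#' @return Numeric vector of the kernel at `seq(0, duration, oversampling)`.
#' @export
hrf_kernel <- function(spec = hrf_spec()) {
  hrf_at(seq(0, spec$duration, by = spec$oversampling), spec)
}
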