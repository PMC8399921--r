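# PQRST wave offsets (s) / widths (s) / amplitudes (mV) for one beat,
# relative to the R peak.  Offsets compress at short RR so beats never
# collide at high heart rate.
ff_pqrst <- list(
  off = c(P = -0.200, Q = -0.028, R = 0.000, S = 0.028, T = 0.280),
  sig = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.060),
  amp = c(P = 0.15, Q = -0.10, R = 1.00, S = -0.25, T = 0.30)
)

#' Synthesize a single-lead ECG stream
#'
#' Generates a PQRST-like beat train at 250 Hz whose instantaneous rate
#' tracks a supplied heart-rate profile, plus additive sinusoidal baseline
#' wander and white measurement noise so that baseline correction is
#' exercised downstream.
#'
#' @param hr_profile Heart rate in beats/min: a scalar or a vector sampled
#'   at 1 Hz over the duration.  All values must lie in `[40, 210]`.
#' @param duration_s Duration in seconds.
#' @param seed Optional seed; `NULL` consumes the current RNG stream.
#' @param rate_hz Sampling rate, default 250 Hz.
#' @param wander_amp Baseline-wander amplitude in mV (0 disables wander).
#' @param wander_hz Baseline-wander frequency, default 0.25 Hz.
#' @param noise_sd White noise sd in mV.
#' @return Tibble with `time` (s) and `ecg` (mV).
#' @export
#' @examples
#' ecg <- synth_ecg(60, duration_s = 10, seed = 1)
#' range(ecg$ecg)
synth_ecg <- function(hr_profile, duration_s, seed = NULL, rate_hz = 250,
                      wander_amp = 0.1, wander_hz = 0.25, noise_sd = 0.02) {
  if (any(hr_profile < 40 | hr_profile > 210)) {
    abort("`hr_profile` must lie within [40, 210] bpm.",
          class = "ff_validation_error")
  }
  stopifnot(duration_s > 0)
  gen <- function() {
    n <- round(duration_s * rate_hz)
    t <- (seq_len(n) - 1) / rate_hz
    # hr_profile is a 1 Hz series; constant-within-second lookup is O(1)
    hr_t <- if (length(hr_profile) == 1) {
      function(x) hr_profile
    } else {
      function(x) hr_profile[pmin(floor(x) + 1, length(hr_profile))]
    }
    # beat times: step forward one RR interval at the local rate
    beats <- numeric(ceiling(duration_s * max(hr_profile) / 60) + 2)
    beats[1] <- 0
    k <- 1
    while (beats[k] < duration_s) {
      rr <- 60 / hr_t(beats[k])
      beats[k + 1] <- beats[k] + rr * (1 + rnorm(1, 0, 0.02))
      k <- k + 1
    }
    beats <- beats[seq_len(k)]
    rrs <- c(diff(beats), 60 / hr_t(beats[k]))

    idx <- findInterval(t, beats)
    idx[idx < 1] <- 1
    # each sample hears its nearest beat (previous or next, whichever closer)
    d_prev <- t - beats[idx]
    nxt <- pmin(idx + 1, k)
    d_next <- t - beats[nxt]
    use_next <- abs(d_next) < abs(d_prev)
    bi <- ifelse(use_next, nxt, idx)
    dt <- ifelse(use_next, d_next, d_prev)
    squeeze <- pmin(1, rrs[bi] / 0.8)

    ecg <- numeric(n)
    for (w in names(ff_pqrst$amp)) {
      ecg <- ecg + ff_pqrst$amp[[w]] *
        exp(-(dt - ff_pqrst$off[[w]] * squeeze)^2 /
              (2 * (ff_pqrst$sig[[w]] * squeeze)^2))
    }
    if (wander_amp > 0) {
      ecg <- ecg + wander_amp * sin(2 * pi * wander_hz * t + runif(1, 0, 2 * pi))
    }
    tibble::tibble(time = t, ecg = ecg + rnorm(n, 0, noise_sd))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Detect R peaks in an ECG series
#'
#' Simple amplitude-threshold R-peak detector used for generator
#' self-consistency checks: local maxima above a fraction of the global
#' amplitude range, separated by a refractory period.
#'
#' @param ecg Numeric ECG series (mV), baseline-corrected or clean.
#' @param rate_hz Sampling rate, default 250.
#' @param threshold_frac Fraction of the max amplitude a peak must exceed.
#' @param refractory_s Minimum spacing between detected peaks, seconds.
#' @return Integer vector of peak sample indices.
#' @export
detect_r_peaks <- function(ecg, rate_hz = 250, threshold_frac = 0.5,
                           refractory_s = 0.25) {
  thr <- threshold_frac * max(ecg)
  n <- length(ecg)
  cand <- which(ecg > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[ecg[cand] >= ecg[cand - 1] & ecg[cand] > ecg[cand + 1]]
  if (length(cand) == 0) return(integer(0))
  keep <- cand[1]
  gap <- refractory_s * rate_hz
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= gap) keep <- c(keep, i)
  }
  keep
}
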