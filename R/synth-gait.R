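# Per-surface step waveform templates.  Each step is a sum of 2 Gaussian
# lobes in step phase [0, 1); the first (impact) lobe dominates so that the
# mean-removed vertical channel crosses zero upward exactly once per step.
ff_gait_templates <- list(
  tarseal  = list(mu = c(0.22, 0.34), sigma = c(0.050, 0.090), c = c(1.00, 0.45)),
  gravel   = list(mu = c(0.22, 0.36), sigma = c(0.060, 0.100), c = c(0.95, 0.40)),
  dirt     = list(mu = c(0.24, 0.38), sigma = c(0.070, 0.110), c = c(0.90, 0.35)),
  mud      = list(mu = c(0.26, 0.42), sigma = c(0.090, 0.130), c = c(0.75, 0.35)),
  grass    = list(mu = c(0.24, 0.40), sigma = c(0.080, 0.120), c = c(0.85, 0.38)),
  boulders = list(mu = c(0.22, 0.40), sigma = c(0.060, 0.140), c = c(1.00, 0.50))
)

eval_lobes <- function(phase, mu, sigma, cc) {
  out <- numeric(length(phase))
  for (j in seq_along(mu)) {
    out <- out + cc[j] * exp(-(phase - mu[j])^2 / (2 * sigma[j]^2))
  }
  out
}

#' Synthesize tri-axial gait accelerometry
#'
#' Generates a step-periodic chest acceleration signal for one activity on
#' one surface.  The vertical channel oscillates around +1 g (gravity) with
#' one dominant impact lobe per step, so its mean-removed zero crossings
#' recover the cadence; the lateral channel alternates sign with the stance
#' leg and the sagittal channel carries a braking/propulsion couple.
#' Fatigue scales per-step peak amplitude by `1 - 0.3 * f` and inflates
#' per-step timing and amplitude jitter, emulating reduced peak forces and
#' increased gait variability under fatigue.
#'
#' @param activity `"run"` or `"walk"` (gait waveform family).
#' @param surface One of [ff_surfaces].
#' @param cadence_spm Cadence in steps/min, in `[60, 220]`.
#' @param fatigue Fatigue state in `[0, 1]`; either a scalar or a vector of
#'   per-sample values (length `duration_s * rate_hz`).
#' @param duration_s Duration in seconds, `> 0`.
#' @param seed Optional seed; `NULL` uses the current RNG state (the session
#'   generator passes `NULL` so all draws flow from the session seed).
#' @param rate_hz Sampling rate, default 100 Hz.
#' @param noise_sd Additive white noise sd in g.
#' @return A tibble with columns `time` (s), `x` (vertical, g), `y`
#'   (lateral, g), `z` (sagittal, g).
#' @export
#' @examples
#' acc <- synth_gait_accel("run", "dirt", 160, fatigue = 0,
#'                         duration_s = 10, seed = 1)
#' range(acc$x)
synth_gait_accel <- function(activity, surface, cadence_spm, fatigue,
                             duration_s, seed = NULL, rate_hz = 100,
                             noise_sd = 0.05) {
  if (!activity %in% c("run", "walk")) {
    abort(sprintf("Unknown activity '%s'.", activity),
          class = "ff_validation_error")
  }
  if (!surface %in% ff_surfaces) {
    abort(sprintf("Unknown surface '%s'.", surface),
          class = "ff_validation_error")
  }
  stopifnot(duration_s > 0)
  if (cadence_spm < 60 || cadence_spm > 220) {
    abort("`cadence_spm` must lie in [60, 220].",
          class = "ff_validation_error")
  }
  gen <- function() {
    n <- round(duration_s * rate_hz)
    t <- (seq_len(n) - 1) / rate_hz
    f_sample <- if (length(fatigue) == 1) rep(fatigue, n) else fatigue
    stopifnot(length(f_sample) == n, all(f_sample >= 0 & f_sample <= 1))

    period <- 60 / cadence_spm
    n_steps <- ceiling(duration_s / period * 1.3) + 4
    f_step0 <- f_sample[pmin(
      pmax(round(seq(0, by = period, length.out = n_steps) * rate_hz) + 1, 1),
      n
    )]
    jitter_sd <- 0.02 + 0.06 * f_step0
    periods <- period * pmax(1 + rnorm(n_steps, 0, jitter_sd), 0.5)
    starts <- c(0, cumsum(periods))[seq_len(n_steps)]

    amp_scale <- if (activity == "run") 1.8 else 0.9
    sig_scale <- if (activity == "run") 1.0 else 1.3
    amp_sd <- 0.05 + 0.10 * f_step0
    amps <- amp_scale * (1 - 0.3 * f_step0) *
      pmax(1 + rnorm(n_steps, 0, amp_sd), 0.2)

    idx <- findInterval(t, starts)
    phase <- (t - starts[idx]) / periods[idx]
    a <- amps[idx]

    tpl <- ff_gait_templates[[surface]]
    vert <- 1 + a * eval_lobes(phase, tpl$mu, tpl$sigma * sig_scale, tpl$c)
    lat <- 0.3 * a * (-1)^idx * eval_lobes(phase, 0.30, 0.12, 1)
    sag <- 0.6 * a * (eval_lobes(phase, 0.40, 0.08, 0.5) -
                        eval_lobes(phase, 0.18, 0.06, 0.5))
    tibble::tibble(
      time = t,
      x = vert + rnorm(n, 0, noise_sd),
      y = lat + rnorm(n, 0, noise_sd),
      z = sag + rnorm(n, 0, noise_sd)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Synthesize seated (quasi-static) accelerometry
#'
#' Low-amplitude postural sway for the seated test block: a slow (~0.3 Hz)
#' band-limited wobble plus a small white component, so cadence estimated
#' from zero crossings stays far below the walking threshold.
#'
#' @inheritParams synth_gait_accel
#' @param sway_sd Sd of the slow sway component, g.
#' @return Tibble `time`, `x`, `y`, `z`; `x` oscillates around +1 g.
#' @export
synth_sit_accel <- function(duration_s, seed = NULL, rate_hz = 100,
                            sway_sd = 0.02, noise_sd = 0.003) {
  stopifnot(duration_s > 0)
  gen <- function() {
    n <- round(duration_s * rate_hz)
    t <- (seq_len(n) - 1) / rate_hz
    sway <- function() {
      ph <- runif(3, 0, 2 * pi)
      fr <- c(0.22, 0.31, 0.40) * runif(3, 0.8, 1.2)
      amp <- rnorm(3, 0, sway_sd / sqrt(1.5))
      out <- numeric(n)
      for (i in 1:3) out <- out + amp[i] * sin(2 * pi * fr[i] * t + ph[i])
      out
    }
    tibble::tibble(
      time = t,
      x = 1 + sway() + rnorm(n, 0, noise_sd),
      y = sway() + rnorm(n, 0, noise_sd),
      z = sway() + rnorm(n, 0, noise_sd)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Synthesize a one-off obstacle transient
#'
#' Gate obstacles produce short stereotyped non-periodic waveforms clearly
#' distinguishable from gait: `open_gate` is a brief pause with two handling
#' bumps, `climb_gate` a larger mount/dismount couple on all three axes.
#'
#' @param obstacle `"open_gate"` or `"climb_gate"`.
#' @inheritParams synth_gait_accel
#' @return Tibble `time`, `x`, `y`, `z`.
#' @export
synth_obstacle_accel <- function(obstacle, duration_s, seed = NULL,
                                 rate_hz = 100, noise_sd = 0.05) {
  if (!obstacle %in% c("open_gate", "climb_gate")) {
    abort(sprintf("Unknown obstacle '%s'.", obstacle),
          class = "ff_validation_error")
  }
  stopifnot(duration_s > 0)
  gen <- function() {
    n <- round(duration_s * rate_hz)
    t <- (seq_len(n) - 1) / rate_hz
    u <- t / duration_s
    if (obstacle == "open_gate") {
      shape <- eval_lobes(u, c(0.25, 0.70), c(0.06, 0.06), c(0.5, 0.4))
      zsh <- eval_lobes(u, c(0.30, 0.65), c(0.08, 0.08), c(0.3, -0.3))
    } else {
      shape <- eval_lobes(u, c(0.20, 0.50, 0.80), c(0.05, 0.10, 0.05),
                          c(1.2, -0.4, 1.0))
      zsh <- eval_lobes(u, c(0.35, 0.75), c(0.10, 0.08), c(0.6, -0.5))
    }
    tibble::tibble(
      time = t,
      x = 1 + shape + rnorm(n, 0, noise_sd),
      y = 0.3 * zsh + rnorm(n, 0, noise_sd),
      z = zsh + rnorm(n, 0, noise_sd)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
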