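# Default performance-test battery: score = intercept + slope * f(t) + noise.
# Slopes and noise sds are chosen so the regenerated sensitivity pattern
# mirrors the field battery: jump and dominant-hand finger tapping highly
# protocol-sensitive, PVSAT and spatial memory insensitive.
ff_test_battery <- tibble::tribble(
  ~test_name,        ~intercept, ~slope, ~noise_sd,
  "jump",             40.0,      -12.0,   1.2,
  "ftt_dominant",     44.0,      -10.0,   1.1,
  "ftt_nondominant",  40.0,       -8.0,   1.25,
  "stroop",            1.20,       0.35,  0.06,
  "trail_a",          22.0,        6.0,   2.1,
  "trail_b",          48.0,        3.0,   6.0,
  "pvsat",            52.0,       -1.0,   3.5,
  "spatial_memory",    6.5,       -0.1,   1.0
)

# heart-rate model: activity base rate plus a fatigue-driven drift (bpm)
ff_hr_base <- c(run = 155, walk = 120, sit = 85, obstacle = 110)

#' Synthesize performance-test scores
#'
#' Draws a table of performance-test observations from a fatigue trajectory:
#' each test's score is an affine function of the latent fatigue state plus
#' Gaussian test noise, so the downstream sensitivity analysis can recover a
#' configurable R-squared pattern.
#'
#' @param trajectory A [fatigue_trajectory()].
#' @param schedule Tibble with columns `time` (s) and `phase`
#'   (`"post_physical"` or `"post_cognitive"`); one battery per row.
#' @param battery Tibble like `ff_test_battery` (`test_name`, `intercept`,
#'   `slope`, `noise_sd`).
#' @param seed Optional seed (`NULL` = current RNG stream).
#' @return Tibble `time`, `test_name`, `phase`, `score`.
#' @export
synth_test_scores <- function(trajectory, schedule,
                              battery = ff_test_battery, seed = NULL) {
  if (is.null(schedule) || nrow(schedule) == 0) {
    abort("Test schedule is empty.", class = "ff_validation_error")
  }
  gen <- function() {
    tidyr::crossing(schedule, battery) |>
      dplyr::mutate(
        f = fatigue_at(trajectory, .data$time),
        score = .data$intercept + .data$slope * .data$f +
          rnorm(dplyr::n(), 0, .data$noise_sd)
      ) |>
      dplyr::select("time", "test_name", "phase", "score") |>
      dplyr::arrange(.data$test_name, .data$time)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Per-lap traversal plan: one row per section plus the seated block.
lap_plan <- function(config) {
  sec <- config$course
  gait <- ifelse(sec$nominal_activity == "obstacle", "obstacle",
                 sec$nominal_activity)
  speed_key <- ifelse(gait == "obstacle", "obstacle",
                      paste(gait, sec$slope_class, sep = "_"))
  speed_key <- sub("run_flat", "run_flat", speed_key)
  speed <- unname(ff_speeds[speed_key])
  dur <- pmax(round(sec$length_m / speed), 2)
  activity <- ifelse(
    sec$nominal_activity == "obstacle", sec$obstacle,
    ifelse(sec$slope_class == "flat", gait,
           paste(gait, sec$slope_class, sep = "_"))
  )
  cadence <- dplyr::case_when(
    gait == "run" ~ config$cadence_run_spm,
    gait == "walk" ~ config$cadence_walk_spm,
    TRUE ~ 0
  )
  plan <- tibble::tibble(
    section_id = sec$section_id, duration_s = dur, activity = activity,
    gait = gait, surface = sec$surface, slope_class = sec$slope_class,
    cadence_spm = cadence, obstacle = sec$obstacle,
    lat0 = sec$lat, lon0 = sec$lon, alt0 = sec$alt_m,
    lat1 = c(sec$lat[-1], sec$lat[1]), lon1 = c(sec$lon[-1], sec$lon[1]),
    alt1 = c(sec$alt_m[-1], sec$alt_m[1])
  )
  sit <- tibble::tibble(
    section_id = NA_integer_, duration_s = config$sit_s, activity = "sit",
    gait = "sit", surface = NA_character_, slope_class = NA_character_,
    cadence_spm = 0, obstacle = "none",
    lat0 = sec$lat[1], lon0 = sec$lon[1], alt0 = sec$alt_m[1],
    lat1 = sec$lat[1], lon1 = sec$lon[1], alt1 = sec$alt_m[1]
  )
  dplyr::bind_rows(plan, sit)
}

#' Session duration implied by a protocol configuration
#'
#' @param config A [protocol_config()].
#' @return Duration in seconds of the full session (all laps).
#' @export
session_duration <- function(config) {
  config$n_laps * sum(lap_plan(config)$duration_s)
}

#' Generate a complete synthetic protocol session
#'
#' Builds the full multi-stream recording of a protocol run: per-lap
#' traversal of the course at activity-specific speeds (gait accelerometry
#' per section, obstacle transients at the gates), a seated test block per
#' lap, a single ECG stream whose heart rate follows activity load plus a
#' fatigue drift, a 1 Hz GPS track around the loop, hourly performance-test
#' scores, and the per-second ground truth that makes every downstream stage
#' testable.
#'
#' All randomness flows from `config$seed` through one RNG stream consumed
#' in a fixed order, so identical `(config, trajectory)` pairs reproduce the
#' session bit-for-bit.
#'
#' @param config A [protocol_config()].
#' @param trajectory A [fatigue_trajectory()] covering the session; `NULL`
#'   uses the default linear ramp from 0 to 0.6 over the session.
#' @return A `sensor_session` list: tibbles `accel` (100 Hz), `ecg`
#'   (250 Hz), `gps` (1 Hz), `test_scores`, per-second `truth`, plus the
#'   `trajectory`, `config`, rates and `duration_s`.
#' @export
#' @examples
#' cfg <- protocol_config(n_laps = 1, seed = 7)
#' s <- generate_session(cfg)
#' s$duration_s
generate_session <- function(config, trajectory = NULL) {
  stopifnot(inherits(config, "protocol_config"))
  duration <- session_duration(config)
  if (is.null(trajectory)) trajectory <- fatigue_trajectory(duration)
  if (trajectory$duration_s < duration) {
    abort("Trajectory does not cover the session duration.",
          class = "ff_config_error")
  }

  plan1 <- lap_plan(config)
  segs <- purrr::map_dfr(seq_len(config$n_laps), function(lap) {
    dplyr::mutate(plan1, lap = lap)
  })
  segs$start_s <- cumsum(c(0, segs$duration_s[-nrow(segs)]))

  withr::with_seed(config$seed, {
    # --- accelerometer, segment by segment ---------------------------------
    accel <- purrr::pmap(
      list(segs$start_s, segs$duration_s, segs$gait, segs$surface,
           segs$cadence_spm, segs$obstacle, segs$activity),
      function(start, dur, gait, surface, cadence, obstacle, activity) {
        if (gait %in% c("run", "walk")) {
          fvec <- fatigue_at(
            trajectory,
            start + (seq_len(dur * config$accel_rate_hz) - 1) /
              config$accel_rate_hz
          )
          a <- synth_gait_accel(gait, surface, cadence, fvec, dur,
                                rate_hz = config$accel_rate_hz,
                                noise_sd = config$accel_noise_sd)
        } else if (gait == "sit") {
          a <- synth_sit_accel(dur, rate_hz = config$accel_rate_hz)
        } else {
          a <- synth_obstacle_accel(activity, dur,
                                    rate_hz = config$accel_rate_hz,
                                    noise_sd = config$accel_noise_sd)
        }
        a$time <- a$time + start
        a
      }
    ) |> dplyr::bind_rows()

    # --- ECG: one stream, heart rate from activity load + fatigue drift ----
    truth <- segs |>
      dplyr::select("lap", "section_id", "activity", "gait", "surface",
                    "slope_class", "cadence_spm", "obstacle", "duration_s") |>
      tidyr::uncount(.data$duration_s) |>
      dplyr::mutate(t = seq_len(dplyr::n()) - 1, .before = 1)
    truth$fatigue <- fatigue_at(trajectory, truth$t)
    hr_raw <- ff_hr_base[truth$gait] + 25 * truth$fatigue
    hr <- as.numeric(stats::filter(hr_raw, rep(1 / 60, 60), sides = 1))
    hr[seq_len(59)] <- hr[60]
    ecg <- synth_ecg(hr, duration, rate_hz = config$ecg_rate_hz,
                     wander_amp = config$ecg_wander_mv)

    # --- GPS track ---------------------------------------------------------
    gps <- purrr::pmap(
      list(segs$start_s, segs$duration_s, segs$lat0, segs$lon0, segs$alt0,
           segs$lat1, segs$lon1, segs$alt1),
      function(start, dur, lat0, lon0, alt0, lat1, lon1, alt1) {
        u <- (seq_len(dur) - 1) / dur
        tibble::tibble(
          time = start + seq_len(dur) - 1,
          lat = lat0 + u * (lat1 - lat0) +
            rnorm(dur, 0, config$gps_noise_h_m / 111320),
          lon = lon0 + u * (lon1 - lon0) +
            rnorm(dur, 0, config$gps_noise_h_m /
                    (111320 * cos(lat0 * pi / 180))),
          alt = alt0 + u * (alt1 - alt0) + rnorm(dur, 0, config$gps_noise_v_m)
        )
      }
    ) |> dplyr::bind_rows()

    # --- hourly performance tests ------------------------------------------
    lap_len <- sum(plan1$duration_s)
    schedule <- purrr::map_dfr(seq_len(config$n_laps), function(lap) {
      tibble::tibble(
        time = c((lap - 1) * lap_len + lap_len - config$sit_s,
                 lap * lap_len - 1),
        phase = c("post_physical", "post_cognitive")
      )
    })
    scores <- synth_test_scores(trajectory, schedule)

    structure(
      list(
        accel = accel, ecg = ecg, gps = gps, test_scores = scores,
        truth = truth, trajectory = trajectory, config = config,
        accel_rate_hz = config$accel_rate_hz,
        ecg_rate_hz = config$ecg_rate_hz,
        gps_rate_hz = config$gps_rate_hz,
        duration_s = duration
      ),
      class = "sensor_session"
    )
  })
}

#' @export
print.sensor_session <- function(x, ...) {
  cat(sprintf(
    paste0("<sensor_session> %.2f h, %d lap(s)\n",
           "  accel %d x 3 @ %g Hz | ecg %d @ %g Hz | gps %d @ %g Hz\n",
           "  %d test scores, truth fatigue %.2f -> %.2f\n"),
    x$duration_s / 3600, x$config$n_laps,
    nrow(x$accel), x$accel_rate_hz, nrow(x$ecg), x$ecg_rate_hz,
    nrow(x$gps), x$gps_rate_hz, nrow(x$test_scores),
    x$truth$fatigue[1], x$truth$fatigue[nrow(x$truth)]
  ))
  invisible(x)
}
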