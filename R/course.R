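#' Terrain surfaces, slope classes and composite activities
#'
#' Vocabulary constants used throughout the package: the terrain surface
#' types encountered on a mountain trail loop, the three slope classes, and
#' the nine composite activity names (gait class crossed with slope class,
#' plus the seated test block and the two one-off gate obstacles).
#'
#' @name vocabulary
#' @keywords internal
NULL

#' @rdname vocabulary
#' @export
ff_surfaces <- c("tarseal", "gravel", "dirt", "mud", "grass", "boulders")

#' @rdname vocabulary
#' @export
ff_slope_classes <- c("flat", "up", "down")

#' @rdname vocabulary
#' @export
ff_activities <- c("run", "run_up", "run_down", "walk", "walk_up",
                   "walk_down", "sit", "open_gate", "climb_gate")

# ground speeds (m/s) per gait x slope, used to schedule section traversal
ff_speeds <- c(
  run_flat = 2.8, run_up = 2.0, run_down = 3.0,
  walk_flat = 1.35, walk_up = 1.1, walk_down = 1.0,
  obstacle = 0.7
)

#' Default 23-section trail course
#'
#' A closed 3.8 km loop with 200 m of climb, divided into 23 sections
#' separated by waypoints wherever terrain surface, slope or an obstacle
#' changes.  Waypoints are laid out on a circular loop (radius chosen so the
#' circumference matches the lap distance) around a configurable centre, and
#' altitudes accumulate the per-section elevation change.
#'
#' @param centre Numeric length-2 `(lat, lon)` of the loop centre.
#' @param base_alt_m Altitude of the start waypoint in metres.
#' @return A tibble with one row per section: `section_id`, start waypoint
#'   coordinates (`lat`, `lon`, `alt_m`), `length_m`, `dalt_m`, `surface`,
#'   `slope_class`, `nominal_activity` (`run`/`walk`/`obstacle`) and
#'   `obstacle` (`none`, `open_gate`, `climb_gate`).  The end waypoint of
#'   section *i* is the start waypoint of section *i + 1*; the last section
#'   closes the loop onto waypoint 1.
#' @export
#' @examples
#' course <- default_course()
#' nrow(course)          # 23 sections
#' sum(course$length_m)  # 3800 m
default_course <- function(centre = c(-36.85, 174.76), base_alt_m = 20) {
  sec <- tibble::tribble(
    ~length_m, ~dalt_m, ~surface,   ~nominal_activity, ~obstacle,
    200,  0,   "tarseal",  "run",      "none",
    250,  15,  "tarseal",  "run",      "none",
    250,  25,  "gravel",   "run",      "none",
    10,   0,   "gravel",   "obstacle", "open_gate",
    250,  30,  "dirt",     "walk",     "none",
    300,  35,  "dirt",     "walk",     "none",
    250,  30,  "mud",      "walk",     "none",
    12,   2,   "boulders", "obstacle", "climb_gate",
    250,  28,  "boulders", "walk",     "none",
    200,  20,  "grass",    "walk",     "none",
    150,  15,  "dirt",     "run",      "none",
    200,  0,   "grass",    "run",      "none",
    150,  0,   "dirt",     "walk",     "none",
    250, -40,  "dirt",     "run",      "none",
    250, -45,  "gravel",   "run",      "none",
    60,  -10,  "boulders", "walk",     "none",
    250, -35,  "dirt",     "run",      "none",
    200, -25,  "grass",    "run",      "none",
    10,   0,   "grass",    "run",      "open_gate",
    200, -30,  "gravel",   "run",      "none",
    150, -15,  "tarseal",  "run",      "none",
    150,  0,   "tarseal",  "walk",     "none",
    116,  0,   "tarseal",  "run",      "none"
  )
  n <- nrow(sec)
  total <- sum(sec$length_m)
  d0 <- c(0, cumsum(sec$length_m)[-n])       # distance at section start
  radius <- total / (2 * pi)
  bearing <- 360 * d0 / total
  wp <- geosphere::destPoint(cbind(centre[2], centre[1]), bearing, radius)
  sec |>
    dplyr::mutate(
      section_id = dplyr::row_number(),
      lat = wp[, 2],
      lon = wp[, 1],
      alt_m = base_alt_m + c(0, cumsum(.data$dalt_m)[-n]),
      grade = .data$dalt_m / .data$length_m,
      slope_class = dplyr::case_when(
        abs(.data$grade) < 0.02 ~ "flat",
        .data$grade > 0 ~ "up",
        TRUE ~ "down"
      ),
      .before = 1
    ) |>
    dplyr::select("section_id", "lat", "lon", "alt_m", "length_m", "dalt_m",
                  "grade", "slope_class", "surface", "nominal_activity",
                  "obstacle")
}

#' Protocol configuration
#'
#' Bundles everything needed to generate a synthetic protocol session: the
#' course, the number of hourly laps, sensor sampling rates, gait cadences,
#' noise levels and the master seed.  Each lap is one traversal of the course
#' at activity-specific ground speeds followed by a 10-minute seated
#' cognitive test block.
#'
#' @param n_laps Number of laps (one per protocol hour), `>= 1`.
#' @param course Course tibble as returned by [default_course()].
#' @param accel_rate_hz,ecg_rate_hz,gps_rate_hz Sampling rates (Hz).
#' @param sit_s Seated test-block duration per lap, seconds.
#' @param cadence_run_spm,cadence_walk_spm Nominal cadences (steps/min).
#' @param accel_noise_sd Additive accelerometer noise, g.
#' @param gps_noise_h_m,gps_noise_v_m GPS horizontal/vertical noise sd, m.
#' @param ecg_wander_mv ECG baseline-wander amplitude, mV.
#' @param seed Master seed; every stochastic stream of the generator is
#'   drawn from a single RNG seeded here and consumed in a fixed order.
#' @return A `protocol_config` list, validated.
#' @export
protocol_config <- function(n_laps = 4,
                            course = default_course(),
                            accel_rate_hz = 100,
                            ecg_rate_hz = 250,
                            gps_rate_hz = 1,
                            sit_s = 600,
                            cadence_run_spm = 165,
                            cadence_walk_spm = 112,
                            accel_noise_sd = 0.05,
                            gps_noise_h_m = 2.5,
                            gps_noise_v_m = 3,
                            ecg_wander_mv = 0.1,
                            seed = 1L) {
  if (!is.numeric(n_laps) || length(n_laps) != 1 || n_laps < 1) {
    abort("`n_laps` must be a single number >= 1.", class = "ff_config_error")
  }
  rates <- c(accel_rate_hz, ecg_rate_hz, gps_rate_hz)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    abort("Sampling rates must be strictly positive.",
          class = "ff_config_error")
  }
  if (!all(course$surface %in% ff_surfaces)) {
    abort("Unknown surface in course.", class = "ff_config_error")
  }
  # closed loop: the final section must end where section 1 starts, i.e. the
  # implied end waypoint is waypoint 1 -- verified on cumulative altitude
  if (abs(sum(course$dalt_m)) > 1e-9) {
    abort("Course is not a closed loop (net altitude change != 0).",
          class = "ff_config_error")
  }
  structure(
    list(
      n_laps = as.integer(n_laps), course = course,
      lap_distance_m = sum(course$length_m),
      lap_climb_m = sum(pmax(course$dalt_m, 0)),
      accel_rate_hz = accel_rate_hz, ecg_rate_hz = ecg_rate_hz,
      gps_rate_hz = gps_rate_hz, sit_s = sit_s,
      cadence_run_spm = cadence_run_spm, cadence_walk_spm = cadence_walk_spm,
      accel_noise_sd = accel_noise_sd, gps_noise_h_m = gps_noise_h_m,
      gps_noise_v_m = gps_noise_v_m, ecg_wander_mv = ecg_wander_mv,
      seed = as.integer(seed)
    ),
    class = "protocol_config"
  )
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf(
    "<protocol_config> %d lap(s) of %.1f km / +%d m, %d sections, seed %d\n",
    x$n_laps, x$lap_distance_m / 1000, round(x$lap_climb_m),
    nrow(x$course), x$seed
  ))
  invisible(x)
}

#' Ground-truth fatigue trajectory
#'
#' The latent fatigue state driving the synthetic generator: a monotone
#' non-decreasing function of protocol time on `[0, 1]` (0 = fresh), by
#' default linear, with an optional bounded within-hour recovery component
#' (which makes the trajectory non-monotone and is off by default).
#'
#' @param duration_s Session duration in seconds.
#' @param f_start,f_end Fatigue state at the start/end of the session.
#' @param recovery_amp Amplitude of an optional within-hour recovery
#'   oscillation (subtracted as `recovery_amp * (1 - cos(2*pi*t/period))/2`).
#' @param recovery_period_s Period of the recovery component, seconds.
#' @return A `fatigue_trajectory` object; evaluate it with [fatigue_at()].
#' @export
#' @examples
#' tr <- fatigue_trajectory(3600, f_end = 0.6)
#' fatigue_at(tr, c(0, 1800, 3600))
fatigue_trajectory <- function(duration_s, f_start = 0, f_end = 0.6,
                               recovery_amp = 0, recovery_period_s = 3600) {
  stopifnot(duration_s > 0, f_start >= 0, f_end <= 1, f_end >= f_start,
            recovery_amp >= 0)
  structure(
    list(duration_s = duration_s, f_start = f_start, f_end = f_end,
         recovery_amp = recovery_amp, recovery_period_s = recovery_period_s),
    class = "fatigue_trajectory"
  )
}

#' Evaluate a fatigue trajectory
#'
#' @param trajectory A [fatigue_trajectory()].
#' @param t Numeric vector of times (seconds from protocol start).
#' @return Fatigue state in `[0, 1]` at each time.
#' @export
fatigue_at <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "fatigue_trajectory"))
  base <- trajectory$f_start +
    (trajectory$f_end - trajectory$f_start) *
      pmin(pmax(t / trajectory$duration_s, 0), 1)
  if (trajectory$recovery_amp > 0) {
    dip <- trajectory$recovery_amp *
      (1 - cos(2 * pi * t / trajectory$recovery_period_s)) / 2
    base <- base - dip
  }
  pmin(pmax(base, 0), 1)
}
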