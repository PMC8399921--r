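#' Cadence from vertical-axis zero crossings
#'
#' Estimates cadence (steps/min) by counting positive-going zero crossings
#' of the mean-removed vertical acceleration in a sliding window: every
#' step's impact lobe carries the signal above the window mean exactly once.
#' One estimate per second, window centred on that second.
#'
#' @param vertical_accel Numeric vertical acceleration series.
#' @param rate_hz Sampling rate, default 100 Hz.
#' @param window_s Window length in seconds, `>= 2` (default 5).
#' @param smooth_s Low-pass (running-mean) length in seconds applied before
#'   counting, suppressing noise-dithered crossings; gait fundamentals pass
#'   nearly unattenuated.  `0` disables smoothing.
#' @return Tibble `t` (second index, 0-based) and `cadence_spm`.
#' @export
#' @examples
#' x <- sin(2 * pi * 2 * (0:999) / 100)   # 2 Hz -> 120 steps/min
#' cadence_from_zero_crossings(x, 100, 5)$cadence_spm[3]
cadence_from_zero_crossings <- function(vertical_accel, rate_hz = 100,
                                        window_s = 5, smooth_s = 0.15) {
  if (window_s < 2) abort("`window_s` must be >= 2 s.",
                          class = "ff_validation_error")
  n <- length(vertical_accel)
  w <- round(window_s * rate_hz)
  if (w > n) abort("Window longer than the series.",
                   class = "ff_validation_error")
  if (smooth_s > 0) {
    vertical_accel <- runmean_vec(vertical_accel,
                                  odd_window(smooth_s * rate_hz))
  }
  n_sec <- floor(n / rate_hz)
  half <- window_s / 2
  cadence <- vapply(seq_len(n_sec) - 1, function(s) {
    centre <- s + 0.5
    i0 <- max(1, round((centre - half) * rate_hz) + 1)
    i1 <- min(n, i0 + w - 1)
    i0 <- i1 - w + 1
    seg <- vertical_accel[i0:i1]
    count_pos_crossings(seg - mean(seg)) * 60 / window_s
  }, numeric(1))
  tibble::tibble(t = seq_len(n_sec) - 1, cadence_spm = cadence)
}

# positive-going zero crossings: x[i] <= 0 and x[i+1] > 0
count_pos_crossings <- function(x) {
  sum(x[-length(x)] <= 0 & x[-1] > 0)
}

#' Classify gait activity from cadence
#'
#' Applies the cadence thresholds `100 < walk < 150 <= run` steps/min.
#' The boundaries are read strictly: exactly 100 is `other`, exactly 150 is
#' `run`.
#'
#' @param cadence Numeric cadence vector, steps/min, `>= 0`.
#' @return Character vector in `c("other", "walk", "run")`.
#' @export
#' @examples
#' classify_activity(c(80, 110, 160))
classify_activity <- function(cadence) {
  if (any(cadence < 0)) abort("Cadence must be non-negative.",
                              class = "ff_validation_error")
  dplyr::case_when(
    cadence >= 150 ~ "run",
    cadence > 100 ~ "walk",
    TRUE ~ "other"
  )
}

#' Assign waypoint crossing times from a GPS track
#'
#' For each lap and waypoint, the crossing time is the track timestamp of
#' minimal great-circle distance to the waypoint, searched within a per-lap
#' interval inferred from cumulative track distance (so repeated laps do not
#' alias).  A waypoint never approached within `max_dist_m` is flagged.
#'
#' @param gps Tibble `time`, `lat`, `lon` (and optionally `alt`).
#' @param waypoints Tibble `section_id`, `lat`, `lon` (course order).
#' @param n_laps Number of laps to resolve.
#' @param max_dist_m Flag threshold in metres (default 50).
#' @return Tibble `lap`, `section_id`, `time` (crossing), `dist_m`,
#'   `flagged`.
#' @export
assign_sections <- function(gps, waypoints, n_laps = 1, max_dist_m = 50,
                            smooth_s = 21) {
  stopifnot(nrow(gps) > 1, nrow(waypoints) > 0)
  # smooth the track so GPS noise neither inflates cumulative distance nor
  # jitters the closest-approach argmin (smooth_s = 0 disables)
  if (smooth_s > 0) {
    k <- odd_window(min(smooth_s, nrow(gps) / 3))
    lat_s <- runmean_vec(gps$lat, k)
    lon_s <- runmean_vec(gps$lon, k)
  } else {
    lat_s <- gps$lat
    lon_s <- gps$lon
  }
  p <- cbind(lon_s, lat_s)
  cum_d <- c(0, cumsum(geosphere::distHaversine(p[-nrow(p), , drop = FALSE],
                                                p[-1, , drop = FALSE])))
  lap_len <- max(cum_d) / n_laps

  # course-relative position of each waypoint on the closed loop; with a
  # single lap there is no aliasing and the whole track is searched
  wpm <- cbind(waypoints$lon, waypoints$lat)
  if (nrow(wpm) > 1) {
    leg <- geosphere::distHaversine(wpm, wpm[c(2:nrow(wpm), 1), ,
                                             drop = FALSE])
    wp_frac <- cumsum(c(0, leg[-length(leg)])) / max(sum(leg), 1e-9)
  } else {
    wp_frac <- 0
  }

  purrr::map_dfr(seq_len(n_laps), function(lap) {
    purrr::map_dfr(seq_len(nrow(waypoints)), function(kk) {
      target <- (lap - 1) * lap_len + wp_frac[kk] * lap_len
      idx <- if (n_laps == 1) seq_len(nrow(gps)) else {
        which(cum_d >= target - 0.2 * lap_len &
                cum_d <= target + 0.2 * lap_len)
      }
      if (length(idx) == 0) idx <- seq_len(nrow(gps))
      d <- geosphere::distHaversine(p[idx, , drop = FALSE],
                                    c(waypoints$lon[kk], waypoints$lat[kk]))
      j <- idx[which.min(d)]
      tibble::tibble(
        lap = lap, section_id = waypoints$section_id[kk],
        time = gps$time[j], dist_m = min(d), flagged = min(d) > max_dist_m
      )
    })
  })
}

# centred running mean with edge shrinkage, for track smoothing
runmean_vec <- function(x, k) {
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) |>
    (\(y) {
      h <- (k - 1) / 2
      for (i in seq_len(h)) {
        y[i] <- mean(x[1:(i + h)])
        y[length(x) - i + 1] <- mean(x[(length(x) - i + 1 - h):length(x)])
      }
      y
    })()
}

#' Slope class between two waypoints
#'
#' The mean GPS altitude at each waypoint — pooled over every track fix
#' within `radius_m` of it, across all laps — gives the section's rise;
#' divided by its horizontal length this yields a grade classified as flat
#' (|grade| < `flat_threshold`), up or down.
#'
#' @param gps Tibble `time`, `lat`, `lon`, `alt`.
#' @param wp_start,wp_end Numeric `(lat, lon)` of the section's bounding
#'   waypoints.
#' @param length_m Horizontal section length in metres.
#' @param radius_m Pooling radius around each waypoint, metres.
#' @param flat_threshold Absolute grade below which the section is flat
#'   (default 0.02, i.e. 2%).
#' @return One of `"flat"`, `"up"`, `"down"`.
#' @export
slope_class_from_altitude <- function(gps, wp_start, wp_end, length_m,
                                      radius_m = 10,
                                      flat_threshold = 0.02) {
  grade <- (waypoint_altitude(gps, wp_end, radius_m) -
              waypoint_altitude(gps, wp_start, radius_m)) / length_m
  if (abs(grade) < flat_threshold) "flat" else if (grade > 0) "up" else "down"
}

#' Mean GPS altitude at a waypoint
#'
#' @param gps Tibble `lat`, `lon`, `alt`.
#' @param wp Numeric `(lat, lon)`.
#' @param radius_m Pooling radius, metres; at least 3 fixes are required.
#' @return Mean altitude of the pooled fixes, metres.
#' @export
waypoint_altitude <- function(gps, wp, radius_m = 10) {
  d <- geosphere::distHaversine(cbind(gps$lon, gps$lat), c(wp[2], wp[1]))
  a <- gps$alt[d <= radius_m]
  if (length(a) < 3) {
    abort("Fewer than 3 altitude samples near a waypoint.",
          class = "ff_validation_error")
  }
  mean(a)
}

#' Build the per-second activity timeline
#'
#' Combines cadence-based gait classification, GPS-derived section
#' membership and slope, and known event seconds (obstacles and seated test
#' blocks, from course configuration or a supplied event table) into one
#' record per second of the session.
#'
#' @param session A `sensor_session`.
#' @param course Course tibble ([default_course()]); defaults to the
#'   session's own course.
#' @param window_s Cadence window, seconds.
#' @param events Optional tibble `t`, `event` overriding per-second event
#'   labels (`"open_gate"`, `"climb_gate"`, `"sit"`).  Defaults to the
#'   session's scheduled obstacle/seated seconds (known by design, as the
#'   study's were).
#' @return An `activity_timeline` tibble: `t`, `cadence_spm`, `gait`
#'   (cadence class), `section_id`, `surface`, `slope_class`, `event`,
#'   `activity` (composite name).
#' @export
label_session <- function(session, course = NULL, window_s = 5,
                          events = NULL) {
  course <- course %||% session$config$course
  cad <- cadence_from_zero_crossings(session$accel$x,
                                     rate_hz = session$accel_rate_hz,
                                     window_s = window_s)
  cad$gait <- classify_activity(cad$cadence_spm)

  crossings <- assign_sections(session$gps, course,
                               n_laps = session$config$n_laps)
  # section membership: [crossing_i, crossing_{i+1}) within each lap;
  # seconds after the lap's last crossing (the seated block) get NA
  cross <- dplyr::arrange(crossings, .data$time)
  sec_of_t <- rep(NA_integer_, nrow(cad))
  lap_of_t <- rep(NA_integer_, nrow(cad))
  for (i in seq_len(nrow(cross))) {
    t0 <- cross$time[i]
    t1 <- if (i < nrow(cross)) cross$time[i + 1] else session$duration_s
    sel <- cad$t >= t0 & cad$t < t1
    sec_of_t[sel] <- cross$section_id[i]
    lap_of_t[sel] <- cross$lap[i]
  }

  # slope class per section from pooled GPS altitude at its bounding
  # waypoints (the end waypoint of section i is the start of section i + 1)
  nxt <- c(2:nrow(course), 1)
  slope_map <- vapply(seq_len(nrow(course)), function(i) {
    slope_class_from_altitude(
      session$gps,
      wp_start = c(course$lat[i], course$lon[i]),
      wp_end = c(course$lat[nxt[i]], course$lon[nxt[i]]),
      length_m = course$length_m[i]
    )
  }, character(1))
  names(slope_map) <- course$section_id

  if (is.null(events)) {
    events <- session$truth |>
      dplyr::filter(.data$activity %in% c("open_gate", "climb_gate", "sit")) |>
      dplyr::transmute(t = .data$t, event = .data$activity)
  }

  tl <- cad |>
    dplyr::mutate(
      section_id = sec_of_t,
      lap = lap_of_t,
      surface = course$surface[.data$section_id],
      slope_class = unname(slope_map[as.character(.data$section_id)])
    ) |>
    dplyr::left_join(events, by = "t") |>
    dplyr::mutate(event = dplyr::coalesce(.data$event, "none"))
  tl$activity <- composite_activity_name(tl$gait, tl$slope_class, tl$event)
  class(tl) <- c("activity_timeline", class(tl))
  tl
}

#' Composite activity names
#'
#' Crosses the cadence gait class with the slope class into the nine-name
#' composite vocabulary; event seconds (obstacles, seated block) override
#' the gait cross.
#'
#' @param gait `"run"`, `"walk"` or `"other"` per second.
#' @param slope_class `"flat"`, `"up"`, `"down"` or `NA` per second.
#' @param event `"open_gate"`, `"climb_gate"`, `"sit"` or `"none"`.
#' @return Character vector of composite names (`NA` for unlabelled
#'   seconds, e.g. cadence class `other` outside any event).
#' @export
composite_activity_name <- function(gait, slope_class, event) {
  out <- dplyr::case_when(
    event %in% c("open_gate", "climb_gate", "sit") ~ event,
    gait %in% c("run", "walk") & slope_class == "flat" ~ gait,
    gait %in% c("run", "walk") & slope_class %in% c("up", "down") ~
      paste(gait, slope_class, sep = "_"),
    TRUE ~ NA_character_
  )
  out
}

#' Split a timeline into composite activities
#'
#' @param timeline An `activity_timeline` from [label_session()].
#' @return A named list of tibbles, one per composite activity present, the
#'   member seconds concatenated in time order.  Member sets are disjoint.
#' @export
composite_activities <- function(timeline) {
  labelled <- dplyr::filter(timeline, !is.na(.data$activity))
  split(labelled, labelled$activity)
}
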