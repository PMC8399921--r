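test_that("cadence from zero crossings matches first principles", {
  # pure 2 Hz sinusoid: 2 positive crossings/s -> 120 steps/min
  x <- sin(2 * pi * 2 * (0:2999) / 100)
  cad <- cadence_from_zero_crossings(x, 100, 5, smooth_s = 0)
  expect_equal(cad$cadence_spm[10], 120)
  # constant zero signal -> 0
  expect_equal(unique(
    cadence_from_zero_crossings(rep(0, 1000), 100, 5)$cadence_spm), 0)
  expect_error(cadence_from_zero_crossings(rep(0, 100), 100, 5),
               class = "ff_validation_error")
  expect_error(cadence_from_zero_crossings(x, 100, 1),
               class = "ff_validation_error")
})

test_that("crossing counts agree exactly with the brute-force oracle", {
  withr::with_seed(7, {
    for (i in 1:25) {
      x <- rnorm(500) + sin(2 * pi * runif(1, 0.5, 3) * (1:500) / 100)
      w <- x[1:500] - mean(x[1:500])
      expect_identical(fieldfatigue:::count_pos_crossings(w),
                       brute_crossings(w))
    }
  })
})

test_that("activity classification follows the cadence thresholds", {
  expect_equal(classify_activity(c(0, 99, 100)), rep("other", 3))
  expect_equal(classify_activity(c(101, 110, 149)), rep("walk", 3))
  expect_equal(classify_activity(c(150, 160, 220)), rep("run", 3))
  expect_error(classify_activity(-5), class = "ff_validation_error")
})

test_that("waypoint crossings are found at closest approach", {
  # track passing exactly through two waypoints
  wp <- tibble::tibble(section_id = 1:2,
                       lat = c(-36.850, -36.846), lon = c(174.760, 174.760))
  lat_path <- seq(-36.852, -36.842, length.out = 101)
  gps <- tibble::tibble(time = 0:100, lat = lat_path, lon = 174.760)
  cr <- assign_sections(gps, wp, n_laps = 1, smooth_s = 0)
  expect_equal(cr$time[cr$section_id == 1],
               gps$time[which.min(abs(lat_path - wp$lat[1]))])
  expect_equal(cr$dist_m, c(0, 0), tolerance = 1)
  expect_false(any(cr$flagged))
  # constant 6 m lateral offset: still a unique minimum at the same second
  gps_off <- dplyr::mutate(gps, lon = .data$lon + 6 / (111320 * cos(-36.85 * pi / 180)))
  cr_off <- assign_sections(gps_off, wp, n_laps = 1, smooth_s = 0)
  expect_equal(cr_off$time, cr$time)
  expect_true(all(cr_off$dist_m > 4 & cr_off$dist_m < 8))
  # a waypoint far off the track is flagged, not silently assigned
  wp_far <- tibble::tibble(section_id = 1, lat = -36.7, lon = 174.9)
  expect_true(all(assign_sections(gps, wp_far, 1, smooth_s = 0)$flagged))
})

test_that("two-lap crossings are strictly increasing and match a scan", {
  s <- ff_test_session()
  course <- s$config$course
  cr <- assign_sections(s$gps, course, n_laps = 2)
  expect_equal(nrow(cr), 2 * nrow(course))
  for (sid in course$section_id) {
    tt <- cr$time[cr$section_id == sid]
    expect_length(tt, 2)
    expect_true(diff(tt) > 0)
  }
  expect_true(all(diff(cr$time[cr$lap == 1]) > 0))
  # brute-force oracle on a clean constructed 2-lap loop (no seated pause)
  wp <- course[c(1, 6, 12, 18), c("section_id", "lat", "lon")]
  one_lap <- purrr::map_dfr(1:4, function(i) {
    j <- c(2:4, 1)[i]
    tibble::tibble(lat = seq(wp$lat[i], wp$lat[j], length.out = 51)[-51],
                   lon = seq(wp$lon[i], wp$lon[j], length.out = 51)[-51])
  })
  track <- dplyr::bind_rows(one_lap, one_lap)
  track$time <- seq_len(nrow(track)) - 1
  got <- assign_sections(track, wp, n_laps = 2, smooth_s = 0)
  lap_n <- nrow(one_lap)
  for (lap in 1:2) {
    idx <- (lap - 1) * lap_n + seq_len(lap_n)
    for (k in seq_len(nrow(wp))) {
      d <- geosphere::distHaversine(
        cbind(track$lon[idx], track$lat[idx]), c(wp$lon[k], wp$lat[k]))
      expect_equal(got$time[got$lap == lap & got$section_id == wp$section_id[k]],
                   track$time[idx[which.min(d)]])
    }
  }
})

test_that("slope classification from waypoint altitudes is reliable", {
  mk_gps <- function(alt0, alt1, sd, n = 5) {
    tibble::tibble(
      time = seq_len(2 * n) - 1,
      lat = rep(c(-36.8500, -36.8482), each = n),   # ~200 m apart
      lon = 174.76,
      alt = c(alt0 + rnorm(n, 0, sd), alt1 + rnorm(n, 0, sd))
    )
  }
  wp_a <- c(-36.8500, 174.76)
  wp_b <- c(-36.8482, 174.76)
  withr::with_seed(21, {
    g <- mk_gps(100, 150, 0)
    expect_equal(slope_class_from_altitude(g, wp_a, wp_b, 500), "up")
    expect_equal(slope_class_from_altitude(g, wp_b, wp_a, 500), "down")
    g0 <- mk_gps(100, 100, 0)
    expect_equal(slope_class_from_altitude(g0, wp_a, wp_b, 500), "flat")
    # Monte-Carlo oracle: 50 m climb over 200 m, altitude noise sd 3 m,
    # 5 samples per waypoint -> correct in >= 99% of 1000 draws
    hits <- mean(replicate(1000, {
      slope_class_from_altitude(mk_gps(100, 150, 3), wp_a, wp_b, 200) == "up"
    }))
    expect_gte(hits, 0.99)
  })
  few <- tibble::tibble(time = 0:1, lat = c(-36.85, -36.8482), lon = 174.76,
                        alt = c(100, 150))
  expect_error(slope_class_from_altitude(few, wp_a, wp_b, 200),
               class = "ff_validation_error")
})

test_that("composite names cross gait and slope with event override", {
  expect_equal(composite_activity_name("run", "down", "none"), "run_down")
  expect_equal(composite_activity_name("walk", "up", "none"), "walk_up")
  expect_equal(composite_activity_name("run", "flat", "none"), "run")
  expect_equal(composite_activity_name("walk", "flat", "climb_gate"),
               "climb_gate")
  expect_equal(composite_activity_name("other", "flat", "sit"), "sit")
  expect_true(is.na(composite_activity_name("other", "flat", "none")))
})

test_that("composite activities partition the labelled timeline", {
  tl <- ff_test_timeline()
  comp <- composite_activities(tl)
  expect_true(all(names(comp) %in% ff_activities))
  sizes <- vapply(comp, nrow, integer(1))
  expect_equal(sum(sizes), sum(!is.na(tl$activity)))
  # disjoint: member seconds never repeat
  all_t <- unlist(lapply(comp, function(d) d$t), use.names = FALSE)
  expect_equal(anyDuplicated(all_t), 0L)
})

test_that("cadence labelling recovers generated ground truth", {
  s <- ff_test_session()
  tl <- ff_test_timeline()
  truth <- s$truth
  change <- which(c(TRUE, truth$activity[-1] != truth$activity[-nrow(truth)]))
  margin <- rep(FALSE, nrow(truth))
  for (d in -2:2) margin[pmin(pmax(change + d, 1), nrow(truth))] <- TRUE
  ok <- !is.na(tl$activity) & tl$activity == truth$activity
  expect_gte(mean(ok[!margin]), 0.98)
})
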