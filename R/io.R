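#' Write a session to disk as plain-text streams
#'
#' Writes the accelerometer, ECG and test-score streams as CSV (seconds
#' offset timestamps), the GPS track as GPX 1.1, the per-second truth as
#' CSV, and a JSON manifest recording rates, seed and duration.
#'
#' @param session A `sensor_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(session$accel, file.path(dir, "accel.csv"), row.names = FALSE)
  write.csv(session$ecg, file.path(dir, "ecg.csv"), row.names = FALSE)
  write.csv(session$test_scores, file.path(dir, "test_scores.csv"),
            row.names = FALSE)
  write.csv(session$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write_gpx(session$gps, file.path(dir, "track.gpx"))
  manifest <- list(
    accel_rate_hz = session$accel_rate_hz,
    ecg_rate_hz = session$ecg_rate_hz,
    gps_rate_hz = session$gps_rate_hz,
    duration_s = session$duration_s,
    n_laps = session$config$n_laps,
    seed = session$config$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write / read a GPX 1.1 track
#'
#' Minimal GPX 1.1 serialization of a 1 Hz track: one `<trkpt>` per fix
#' with `lat`/`lon` attributes, `<ele>` altitude and the seconds offset in
#' `<time>` (as a plain number; no wall-clock epoch is attached to
#' synthetic sessions).
#'
#' @param gps Tibble `time`, `lat`, `lon`, `alt`.
#' @param path Output file.
#' @return `path` (write) or the track tibble (read).
#' @export
write_gpx <- function(gps, path) {
  doc <- xml2::xml_new_root(
    "gpx", version = "1.1", creator = "fieldfatigue",
    xmlns = "http://www.topografix.com/GPX/1/1"
  )
  trk <- xml2::xml_add_child(doc, "trk")
  seg <- xml2::xml_add_child(trk, "trkseg")
  for (i in seq_len(nrow(gps))) {
    pt <- xml2::xml_add_child(seg, "trkpt",
                              lat = sprintf("%.7f", gps$lat[i]),
                              lon = sprintf("%.7f", gps$lon[i]))
    xml2::xml_add_child(pt, "ele", sprintf("%.2f", gps$alt[i]))
    xml2::xml_add_child(pt, "time", sprintf("%g", gps$time[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_gpx
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  pts <- xml2::xml_find_all(doc, ".//g:trkpt", ns)
  tibble::tibble(
    time = as.numeric(xml2::xml_text(
      xml2::xml_find_first(pts, "./g:time", ns))),
    lat = as.numeric(xml2::xml_attr(pts, "lat")),
    lon = as.numeric(xml2::xml_attr(pts, "lon")),
    alt = as.numeric(xml2::xml_text(
      xml2::xml_find_first(pts, "./g:ele", ns)))
  )
}

#' Read a session back from [write_session()] output
#'
#' @param dir Directory written by [write_session()].
#' @return A `sensor_session`-shaped list (without generator truth
#'   trajectory object; the truth table is reloaded).
#' @export
read_session <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(
    list(
      accel = tibble::as_tibble(read.csv(file.path(dir, "accel.csv"))),
      ecg = tibble::as_tibble(read.csv(file.path(dir, "ecg.csv"))),
      gps = read_gpx(file.path(dir, "track.gpx")),
      test_scores = tibble::as_tibble(
        read.csv(file.path(dir, "test_scores.csv"))),
      truth = tibble::as_tibble(read.csv(file.path(dir, "truth.csv"))),
      accel_rate_hz = manifest$accel_rate_hz,
      ecg_rate_hz = manifest$ecg_rate_hz,
      gps_rate_hz = manifest$gps_rate_hz,
      duration_s = manifest$duration_s,
      n_laps = manifest$n_laps
    ),
    class = "sensor_session"
  )
}
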