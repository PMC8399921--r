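#' Run the full analysis pipeline
#'
#' Synthesize (or load) a session, prepare and label it, build the
#' continuous fatigue label, window one activity, train the network, and
#' evaluate rolled predictions — writing every stage artifact plus a
#' manifest (config hash, seed) into an output directory.  Re-running with
#' an identical configuration reproduces identical outputs.
#'
#' @param out_dir Output directory.
#' @param config A [protocol_config()] (the session source) or a directory
#'   previously written by [write_session()].
#' @param activity Composite activity to model.
#' @param width Window width in samples.
#' @param data_group `"combined"`, `"accel"` or `"ecg"`.
#' @param label_method `"ITI"` or `"LTLF"`.
#' @param spec A [cnn_spec()].
#' @param k Rolling length for evaluation.
#' @param test_fraction,seed Split/training seed parameters.
#' @param write_session_streams Also write the raw stream CSV/GPX files
#'   (large; off by default).
#' @param write_plots Write the prediction-trace and loss-trace figures as
#'   PNG.
#' @return Invisibly, a list with the `session`, `timeline`, `label`,
#'   `model` and `eval` result; artifacts under `out_dir`.
#' @export
run_pipeline <- function(out_dir, config = protocol_config(),
                         activity = "walk_up", width = 128,
                         data_group = "combined",
                         label_method = c("ITI", "LTLF"),
                         spec = cnn_spec(), k = 200, test_fraction = 0.33,
                         seed = 1, write_session_streams = FALSE,
                         write_plots = TRUE) {
  label_method <- match.arg(label_method)
  if (is.character(config)) {
    if (!dir.exists(config)) {
      abort(sprintf("Session directory '%s' does not exist.", config),
            class = "ff_config_error")
    }
    session <- read_session(config)
    # course geometry and lap count are needed for labelling
    session$config <- protocol_config(n_laps = session$n_laps %||% 1)
  } else {
    session <- generate_session(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  streams <- align_streams(session)
  timeline <- label_session(session)
  label <- session_label(session, method = label_method)

  ds <- window_activity(streams, timeline, activity, width, label,
                        channels = data_group)
  parts <- split_train_test(ds, test_fraction, seed = seed)
  sc <- fit_window_scaling(parts$train)
  train <- apply_window_scaling(parts$train, sc)
  test <- apply_window_scaling(parts$test, sc)
  model <- train_cnn(train, spec, seed = seed)
  eval_res <- evaluate_activity(model, test, k = k,
                                label_method = label_method)

  # artifacts
  write.csv(timeline, file.path(out_dir, "timeline.csv"), row.names = FALSE)
  write.csv(session$test_scores, file.path(out_dir, "test_scores.csv"),
            row.names = FALSE)
  write.csv(sensitivity_table(session$test_scores),
            file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
  write.csv(tibble::tibble(time = label_grid(session$duration_s, 1),
                           label = label$values[seq(1, length(label$values),
                                                    by = label$rate_hz)]),
            file.path(out_dir, "label_preview.csv"), row.names = FALSE)
  write.csv(as.data.frame(eval_res), file.path(out_dir, "eval.csv"),
            row.names = FALSE)
  write.csv(model$loss_trace, file.path(out_dir, "loss_trace.csv"),
            row.names = FALSE)
  if (write_session_streams) write_session(session, file.path(out_dir, "session"))
  if (write_plots) {
    ggplot2::ggsave(file.path(out_dir, "loss_trace.png"), autoplot(model),
                    width = 7, height = 4, dpi = 120)
    if (!eval_res$excluded) {
      ggplot2::ggsave(file.path(out_dir, "predictions.png"),
                      autoplot(eval_res), width = 8, height = 4, dpi = 120)
    }
  }

  run_cfg <- list(activity = activity, width = width,
                  data_group = data_group, label_method = label_method,
                  spec = unclass(spec), k = k,
                  test_fraction = test_fraction, seed = seed,
                  session_seed = if (is.character(config)) NA_integer_
                                 else config$seed,
                  n_laps = if (is.character(config)) NA_integer_
                           else config$n_laps)
  manifest <- list(config = run_cfg, config_hash = rlang::hash(run_cfg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(session = session, timeline = timeline, label = label,
                 model = model, eval = eval_res))
}
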