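# Shared fixtures, generated once per test run and cached in this
# environment.  A 2-lap session keeps every stage exercised while staying
# quick to synthesize.
.ff_cache <- new.env(parent = emptyenv())

ff_test_session <- function() {
  if (is.null(.ff_cache$session)) {
    .ff_cache$session <- generate_session(protocol_config(n_laps = 2,
                                                          seed = 11))
  }
  .ff_cache$session
}

ff_test_streams <- function() {
  if (is.null(.ff_cache$streams)) {
    .ff_cache$streams <- align_streams(ff_test_session())
  }
  .ff_cache$streams
}

ff_test_timeline <- function() {
  if (is.null(.ff_cache$timeline)) {
    .ff_cache$timeline <- label_session(ff_test_session())
  }
  .ff_cache$timeline
}

ff_test_label <- function() {
  if (is.null(.ff_cache$label)) {
    .ff_cache$label <- session_label(ff_test_session(), method = "ITI")
  }
  .ff_cache$label
}

# brute-force positive-going zero-crossing counter (independent oracle)
brute_crossings <- function(x) {
  n <- 0L
  for (i in seq_len(length(x) - 1)) {
    if (x[i] <= 0 && x[i + 1] > 0) n <- n + 1L
  }
  n
}

# brute-force rolling mean (independent oracle)
brute_rolling <- function(x, k) {
  vapply(seq_len(length(x) - k + 1), function(i) mean(x[i:(i + k - 1)]),
         numeric(1))
}
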