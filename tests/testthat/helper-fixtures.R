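# shared fixtures; expensive axon thresholds are memoized per test run
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

sine_threshold_1khz <- function() {
  memo("th_sine_1k", find_threshold(axon_params(),
                                    extracellular_drive(waveform_spec("sine", 1000)),
                                    duration_s = 0.4))
}

tis_threshold_1khz_5hz <- function() {
  memo("th_tis_1k", find_threshold(axon_params(),
                                   extracellular_drive(waveform_spec("tis_pair", 1000, 5)),
                                   duration_s = 0.4))
}

# a hand-built sim_result carrying only a stored trace (for spike detection)
trace_result <- function(t_ms, v) {
  structure(list(t_ms = t_ms, vm = matrix(v, ncol = 1), crossings = NULL,
                 params = list(node_count = 1)),
            class = "sim_result")
}
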