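test_that("spike detection applies the refractory merge rule", {
  t <- seq(0, 20, by = 0.01)
  flat <- rep(-80, length(t))
  expect_length(detect_spikes(trace_result(t, flat), 1), 0)

  # three upward 0 mV crossings >= 1 ms apart
  v3 <- -80 + 110 * (exp(-((t - 3)^2) / 0.02) + exp(-((t - 8)^2) / 0.02) +
                       exp(-((t - 15)^2) / 0.02))
  expect_length(detect_spikes(trace_result(t, v3), 1), 3)

  # a double crossing 0.1 ms apart is merged into one spike
  v2 <- -80 + 110 * (exp(-((t - 5)^2) / 0.001) +
                       exp(-((t - 5.1)^2) / 0.001))
  expect_length(detect_spikes(trace_result(t, v2), 1), 1)
})

test_that("an undriven axon stays at rest", {
  r <- simulate_axon(axon_params(),
                     extracellular_drive(waveform_spec("sine", 1000),
                                         amplitude_mA = 0), 0.1)
  expect_lt(max(abs(r$vm - (-80))), 0.1)
  expect_length(detect_spikes(r, 26), 0)
})

test_that("time-step and duration contracts are enforced", {
  ap <- axon_params()
  d <- extracellular_drive(waveform_spec("sine", 10000))
  expect_error(simulate_axon(ap, d, 0.05, dt_ms = 0.01), "floor")
  dm <- extracellular_drive(waveform_spec("tis_pair", 1000, 5))
  expect_error(simulate_axon(ap, dm, 0.1), "2 modulation periods")
})

test_that("subthreshold kHz drive rectifies into net depolarization", {
  ap <- axon_params()
  th <- sine_threshold_1khz()
  d <- extracellular_drive(waveform_spec("sine", 1000),
                           amplitude_mA = 0.8 * th)
  r <- simulate_axon(ap, d, 0.5)
  offset <- rectification_metric(r, 26)
  expect_gt(offset, 0.1)

  # no rectification with frozen (passive) channels
  rp <- simulate_axon(ap, d, 0.5, passive = TRUE)
  expect_lt(abs(rectification_metric(rp, 26)), 0.01)

  # rectified offset grows with amplitude
  d$amplitude_mA <- 0.4 * th
  r4 <- simulate_axon(ap, d, 0.5)
  expect_lt(rectification_metric(r4, 26), offset)

  # spiking traces reject the metric
  d$amplitude_mA <- 1.5 * th
  rs <- simulate_axon(ap, d, 0.5)
  expect_error(rectification_metric(rs, 26), "undefined")
})

test_that("suprathreshold kHz drive fires repetitively", {
  th <- sine_threshold_1khz()
  d <- extracellular_drive(waveform_spec("sine", 1000),
                           amplitude_mA = 1.5 * th)
  r <- simulate_axon(axon_params(), d, 0.4, store_vm = FALSE)
  expect_gt(length(detect_spikes(r, 10)), 5)
})

test_that("threshold search brackets, converges and validates bounds", {
  ap <- axon_params()
  d <- extracellular_drive(waveform_spec("sine", 1000))
  th <- sine_threshold_1khz()
  # invariant to the initial bracket (within tolerance)
  th2 <- find_threshold(ap, d, bounds = c(0.02, 0.5), duration_s = 0.4)
  expect_equal(th2, th, tolerance = 0.025)
  expect_error(find_threshold(ap, d, bounds = c(2 * th, 4 * th),
                              duration_s = 0.4), "lower bound")
  expect_error(find_threshold(ap, d, bounds = c(th / 8, th / 2),
                              duration_s = 0.4), "upper bound")
})

test_that("modulated and unmodulated thresholds are commensurate", {
  ratio <- tis_threshold_1khz_5hz() / sine_threshold_1khz()
  expect_gte(ratio, 1 / 1.5)
  expect_lte(ratio, 1.5)
})

test_that("an empty sweep yields an empty threshold table", {
  tab <- threshold_sweep(axon_params(), list())
  expect_s3_class(tab, "threshold_table")
  expect_equal(nrow(tab), 0)
})

test_that("threshold sweeps tabulate per-waveform thresholds", {
  ap <- axon_params()
  sweep <- list(waveform_spec("sine", 1000), waveform_spec("sine", 3000))
  tab <- threshold_sweep(ap, sweep, tolerance = 0.05, window_s = 0.4)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$carrier_hz, c(1000, 3000))
  # strength-frequency ordering at kHz
  expect_gt(tab$threshold_ma[2], tab$threshold_ma[1])
})
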