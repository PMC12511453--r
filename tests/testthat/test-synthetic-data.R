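test_that("ramp quantization ceilings onto the step grid", {
  expect_equal(apply_ramp_quantization(0.312, 0.025), 0.325)
  expect_equal(apply_ramp_quantization(0.325, 0.025), 0.325)  # on-grid
  expect_equal(apply_ramp_quantization(0.003, 0.05), 0.05)    # one step
  expect_equal(apply_ramp_quantization(0.1, 0), 0.1)          # disabled
  expect_error(apply_ramp_quantization(-1, 0.01), "positive")
  expect_error(apply_ramp_quantization(1, -0.01), "non-negative")
  # measured minus true always lies in [0, step)
  set.seed(3)
  x <- runif(500, 0.001, 2)
  q <- vapply(x, apply_ramp_quantization, numeric(1), step_ma = 0.025)
  expect_true(all(q - x >= -1e-12 & q - x < 0.025))
})

test_that("a noise-free generator reproduces the threshold law exactly", {
  cfg <- study_config("locust", subject_sd = 0, residual_sd = 0,
                      multipliers = c(sine = 1, am = 1, burst = 1),
                      ramp_step_ma = c(0, 0), n_subjects = 2)
  d <- generate_sf_dataset(cfg)
  expect_equal(nrow(d), 2 * 3 * 8)
  for (w in c("sine", "am", "burst")) {
    sub <- d[d$waveform == w & d$subject == "S01", ]
    expect_equal(sub$threshold_ma,
                 cfg$i0_ma * reilly_threshold(sub$carrier_hz),
                 tolerance = 1e-12)
  }
})

test_that("generation is deterministic given the seed", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_threshold_csv(generate_sf_dataset(study_config("locust", seed = 11)), f1)
  write_threshold_csv(generate_sf_dataset(study_config("locust", seed = 11)), f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- generate_sf_dataset(study_config("locust", seed = 12))
  expect_false(identical(read_threshold_csv(f1)$threshold_ma, d3$threshold_ma))
  unlink(c(f1, f2))
})

test_that("locust defaults recover the configured waveform ratios", {
  d <- generate_sf_dataset(study_config("locust", n_subjects = 5, seed = 1))
  r <- threshold_ratios(d, "am", "sine")
  expect_lt(abs(r$mean - 1.29), 0.04)
  rb <- threshold_ratios(d, "burst", "sine")
  expect_lt(abs(rb$mean - 1.06), 0.04)
})

test_that("generated ratios converge to the multipliers at large n", {
  d <- generate_sf_dataset(study_config("locust", n_subjects = 200, seed = 5))
  r <- threshold_ratios(d, "am", "sine")
  expect_lt(abs(r$mean / 1.29 - 1), 0.01)
})

test_that("the AMF design produces the expected U-curve", {
  amf <- c(0.5, 1, 2, 5, 10, 20, 50)
  # noise-free: exact per-subject minimum at the optimum, ~20% deep
  cfg0 <- study_config("human_motor", subject_sd = 0, residual_sd = 0,
                       ramp_step_ma = c(0, 0), n_subjects = 3)
  d0 <- generate_amf_dataset(cfg0, amf)
  for (s in unique(d0$subject)) {
    sub <- d0[d0$subject == s, ]
    expect_equal(sub$amf_hz[which.min(sub$threshold_ma)], 5)
    expect_equal(min(sub$threshold_ma) / max(sub$threshold_ma), 0.8,
                 tolerance = 0.02)
  }
  # sensory model dips at 1 Hz instead
  cfgs <- study_config("human_sensory", subject_sd = 0, residual_sd = 0,
                       ramp_step_ma = c(0, 0), n_subjects = 1)
  ds <- generate_amf_dataset(cfgs, amf)
  expect_equal(ds$amf_hz[which.min(ds$threshold_ma)], 1)

  # flat curve when the dip is disabled
  cfgf <- study_config("human_motor", subject_sd = 0, residual_sd = 0,
                       ramp_step_ma = c(0, 0), amf_dip_depth = 0,
                       n_subjects = 1)
  df <- generate_amf_dataset(cfgf, amf)
  expect_equal(diff(range(df$threshold_ma)), 0)

  # under defaults, normalized thresholds are >= 1 by construction
  dd <- generate_amf_dataset(study_config("human_motor", seed = 2), amf)
  for (s in unique(dd$subject)) {
    sub <- dd[dd$subject == s, ]
    expect_true(all(sub$threshold_ma / min(sub$threshold_ma) >= 1))
  }
})

test_that("ramp steps switch at 5 kHz and bound the quantization error", {
  cfg <- study_config("locust", seed = 9)
  d <- generate_sf_dataset(cfg)
  lo <- d$threshold_ma[d$carrier_hz < 5000]
  hi <- d$threshold_ma[d$carrier_hz >= 5000]
  expect_true(all(abs(lo / 0.005 - round(lo / 0.005)) < 1e-9))
  expect_true(all(abs(hi / 0.05 - round(hi / 0.05)) < 1e-9))
})
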