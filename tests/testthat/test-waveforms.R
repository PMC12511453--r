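test_that("synthesized tones have the requested structure", {
  s <- synthesize(waveform_spec("sine", 1000, 0, 1, duration = 1),
                  sample_rate = 1e5)[[1]]
  expect_equal(length(s$samples), 1e5)
  expect_equal(max(s$samples), 1, tolerance = 1e-6)
  expect_lt(abs(mean(s$samples)), 1e-10)

  two <- synthesize(waveform_spec("tis_pair", 2500, 10, 0.5, duration = 0.5))
  expect_length(two, 2)
  # second channel oscillates at f1 + df: count zero crossings
  z2 <- sum(diff(sign(two[[2]]$samples)) != 0)
  expect_equal(z2, round(2 * 2510 * 0.5), tolerance = 0.01)

  b <- synthesize(waveform_spec("sine_burst", 2500, 1, 1, duration = 2))[[1]]
  t <- (seq_along(b$samples) - 1) / b$sample_rate
  off <- (t %% 1) >= 0.5
  expect_true(all(b$samples[off] == 0))
  expect_gt(max(abs(b$samples[!off])), 0.99)
})

test_that("undersampled synthesis is rejected with the required rate", {
  spec <- waveform_spec("sine", 1000)
  expect_error(synthesize(spec, sample_rate = 20000), "40000")
})

test_that("two-tone envelope matches the closed form away from edges", {
  spec <- waveform_spec("am_additive", 2500, 1, 0.5, duration = 2)
  s <- synthesize(spec)[[1]]
  env <- signal_envelope(s, 2500)
  expect_equal(max(env$samples), 1, tolerance = 0.01)
  expect_lt(min(env$samples), 0.02)

  # A1 = A2 = 1: envelope is 2|cos(pi df t)| within 1% away from edges
  fs <- 1e5
  t <- (seq_len(2 * fs) - 1) / fs
  x <- sin(2 * pi * 2000 * t) + sin(2 * pi * 2010 * t)
  env2 <- signal_envelope(sampled_signal(x, fs), 2000)
  inner <- seq(0.05 * length(t), 0.95 * length(t))
  ref <- 2 * abs(cos(pi * 10 * t))
  expect_lt(max(abs(env2$samples[inner] - ref[inner])), 0.02)

  # A1 = 2, A2 = 1: constructive/destructive extremes 3 and 1
  x3 <- 2 * sin(2 * pi * 2000 * t) + sin(2 * pi * 2010 * t)
  env3 <- signal_envelope(sampled_signal(x3, fs), 2000)
  expect_equal(max(env3$samples[inner]), 3, tolerance = 0.01)
  expect_equal(min(env3$samples[inner]), 1, tolerance = 0.01)
})

test_that("envelope of an unmodulated tone is constant", {
  s <- synthesize(waveform_spec("sine", 1000, 0, 1, duration = 0.5))[[1]]
  env <- signal_envelope(s, 1000)
  inner <- seq(0.05 * length(env$samples), 0.95 * length(env$samples))
  expect_true(all(abs(env$samples[inner] - 1) < 0.01))
})

test_that("modulation index reflects carrier amplitude ratios", {
  fs <- 1e5
  t <- (seq_len(fs) - 1) / fs
  eq <- signal_envelope(sampled_signal(
    sin(2 * pi * 2000 * t) + sin(2 * pi * 2005 * t), fs), 2000)
  expect_equal(modulation_index(eq, 5), 1, tolerance = 0.01)

  flat <- sampled_signal(rep(1, 1000), 1000)
  expect_equal(modulation_index(flat), 0)

  # A1 = 3, A2 = 1 -> (max - min)/(max + min) = (4 - 2)/(4 + 2) = 1/3
  env31 <- sampled_signal(sqrt(9 + 1 + 6 * cos(2 * pi * 5 * t)), fs)
  expect_equal(modulation_index(env31, 5), 1 / 3, tolerance = 1e-6)

  expect_error(modulation_index(sampled_signal(rep(0, 100), 100)),
               "undefined")
})

test_that("spectral power of a carrier pair has no low-frequency energy", {
  spec <- waveform_spec("am_additive", 2500, 10, 1, duration = 2)
  s <- synthesize(spec)[[1]]
  p_low <- band_power(s, 10, 10)          # [0, 2 df]
  p_car <- band_power(s, 2500, 5)
  expect_lt(p_low / p_car, 1e-6)

  # partial-depth multiplicative AM (1 + m cos) sin has sidebands at fc +/- df
  fs <- 1e5
  t <- (seq_len(2 * fs) - 1) / fs
  am <- (1 + 0.5 * cos(2 * pi * 10 * t)) * sin(2 * pi * 2500 * t)
  sam <- sampled_signal(am, fs)
  side <- band_power(sam, 2510, 2) + band_power(sam, 2490, 2)
  floor_ref <- band_power(sam, 2700, 2)
  expect_gt(side / floor_ref, 1e4)

  # pure sine: >= 99% of total power within +/- 1 bin of f
  sp <- synthesize(waveform_spec("sine", 1000, 0, 1, duration = 1))[[1]]
  df_bin <- sp$sample_rate / length(sp$samples)
  p_at <- band_power(sp, 1000, 1.5 * df_bin)
  p_tot <- band_power(sp, sp$sample_rate / 4 - 1, sp$sample_rate / 4 - 1)
  expect_gt(p_at / p_tot, 0.99)
})

test_that("additive and multiplicative synthesis agree exactly", {
  fs <- 251000
  a <- synthesize(waveform_spec("am_additive", 2500, 10, 0.7, duration = 1),
                  sample_rate = fs)[[1]]
  m <- synthesize(waveform_spec("am_multiplicative", 2500, 10, 0.7,
                                duration = 1), sample_rate = fs)[[1]]
  rel_rms <- sqrt(mean((a$samples - m$samples)^2)) / sqrt(mean(a$samples^2))
  expect_lt(rel_rms, 1e-6)
})

test_that("envelopes are bounded and beat at the carrier offset", {
  for (kind in c("am_additive", "sine_burst", "sine")) {
    spec <- waveform_spec(kind, 2500, if (kind == "sine") 0 else 5, 0.8,
                          duration = 1)
    s <- synthesize(spec)[[1]]
    env <- signal_envelope(s, 2500)
    expect_true(all(env$samples > -1e-9))
    bound <- if (kind == "am_additive") 1.6 else 0.8
    # the analytic-signal estimator rings (Gibbs) at the hard gate edges
    # of a burst; smooth envelopes track the amplitude bound tightly
    slack <- if (kind == "sine_burst") 1.12 else 1.02
    expect_lt(max(env$samples), bound * slack)
  }
  # envelope period of a two-tone sum is 1/df within one sample
  fs <- 250000
  s <- synthesize(waveform_spec("am_additive", 2500, 4, 1, duration = 1),
                  sample_rate = fs)[[1]]
  env <- signal_envelope(s, 2500)$samples
  n_per <- fs / 4
  m1 <- which.min(env[seq_len(n_per)])
  m2 <- m1 + which.min(env[(m1 + 1):(m1 + n_per)])
  expect_lte(abs((m2 - m1) - n_per), 1)
})

test_that("waveform specs validate and round-trip through JSON", {
  expect_error(waveform_spec("sine", 1000, 5), "modulation_frequency = 0")
  expect_error(waveform_spec("am_additive", 1000, 600), "below")
  expect_error(waveform_spec("sine", -5), "carrier_frequency")
  f <- tempfile(fileext = ".json")
  spec <- waveform_spec("am_additive", 2500, 10, 0.5, duration = 2)
  write_waveform_json(spec, f)
  expect_equal(read_waveform_json(f), spec)
  unlink(f)
})
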