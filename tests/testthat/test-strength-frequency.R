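test_that("the threshold equation evaluates to its closed form", {
  expect_equal(reilly_threshold(500),
               (1 - exp(-1))^(-0.9) * (1 - exp(-50))^(-0.8),
               tolerance = 1e-12)
  # thresholds rise with frequency in the kHz range
  expect_gt(reilly_threshold(10000), reilly_threshold(1000))
  # I0 is a pure scale factor
  f <- c(20, 200, 2000, 20000)
  expect_equal(reilly_threshold(f, reilly_params(i0 = 2)),
               2 * reilly_threshold(f), tolerance = 1e-12)
  expect_error(reilly_threshold(0), "positive")
  expect_error(reilly_threshold(-100), "positive")
})

test_that("the strength-frequency curve is U-shaped with one minimum", {
  f <- exp(seq(log(1), log(5e4), length.out = 2000))
  th <- reilly_threshold(f)
  d <- diff(th)
  # strictly increasing towards f -> 0 below 10 Hz (accommodation)
  expect_true(all(d[f[-1] <= 10] < 0))
  # strictly increasing above 1 kHz
  expect_true(all(d[f[-length(f)] >= 1000] > 0))
  # exactly one sign change of the derivative: a unique interior minimum
  expect_equal(sum(diff(sign(d)) != 0), 1)
})

test_that("noiseless fits recover the scale exactly", {
  f <- c(500, 1000, 2500, 5000, 7500, 10000, 11500, 12500)
  d <- data.frame(carrier_hz = f,
                  threshold_ma = reilly_threshold(f, reilly_params(i0 = 2)))
  fit <- fit_reilly(d)
  expect_equal(fit$params$i0, 2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("fits of noisy data retain high explained variance", {
  f <- c(500, 1000, 2500, 5000, 7500, 10000, 11500, 12500)
  r2 <- vapply(1:15, function(s) {
    set.seed(s)
    d <- data.frame(carrier_hz = f,
                    threshold_ma = 0.5 * reilly_threshold(f) *
                      exp(rnorm(length(f), 0, 0.05)))
    fit_reilly(d)$r_squared
  }, numeric(1))
  expect_gte(median(r2), 0.99)
})

test_that("degenerate and invalid fit inputs are handled", {
  f <- c(500, 1000, 2500, 5000, 7500, 10000, 11500, 12500)
  flat <- data.frame(carrier_hz = f, threshold_ma = rep(1, length(f)))
  fit <- fit_reilly(flat)
  expect_lt(fit$r_squared, 0.5)
  expect_error(fit_reilly(data.frame(carrier_hz = c(100, 100, 200),
                                     threshold_ma = c(1, 1, 2))),
               "3 distinct")
  bad <- data.frame(carrier_hz = f, threshold_ma = c(-1, rep(1, 7)))
  expect_error(fit_reilly(bad), "positive")
})

test_that("releasing the shape constants still recovers generated data", {
  f <- exp(seq(log(100), log(20000), length.out = 12))
  truth <- reilly_params(i0 = 1.5)
  d <- data.frame(carrier_hz = f, threshold_ma = reilly_threshold(f, truth))
  fit <- fit_reilly(d, free_shape = TRUE)
  expect_equal(fit$params$i0, 1.5, tolerance = 1e-3)
  expect_gt(fit$r_squared, 1 - 1e-8)
})

test_that("threshold tables validate their schema and round-trip CSV", {
  d <- data.frame(subject = "S1", waveform = "sine",
                  carrier_hz = c(500, 1000), amf_hz = 0,
                  threshold_ma = c(0.1, 0.12))
  tt <- as_threshold_table(d)
  expect_s3_class(tt, "threshold_table")
  expect_error(as_threshold_table(d[, -5]), "missing columns")
  bad <- d; bad$threshold_ma[1] <- 0
  expect_error(as_threshold_table(bad), "positive")
  dup <- rbind(d, d[1, ])
  expect_error(as_threshold_table(dup), "duplicate")
  f <- tempfile(fileext = ".csv")
  write_threshold_csv(tt, f)
  back <- read_threshold_csv(f)
  expect_equal(back$threshold_ma, tt$threshold_ma)
  unlink(f)
})
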