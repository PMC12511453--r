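#' Specify a stimulation waveform
#'
#' Describes one of the four stimulation conditions used throughout the
#' package: a TIS carrier pair (two kHz tones at `f1` and `f2 = f1 + df`
#' delivered on separate channels), additive AM (the same two tones summed
#' on one channel), multiplicative AM (a premodulated carrier with the same
#' envelope), a gated sine burst, or an unmodulated sine. The carrier
#' frequency reported is `f1`; the modulation frequency is the beat / AM
#' frequency `df` (AMF).
#'
#' @param kind One of `"tis_pair"`, `"am_additive"`, `"am_multiplicative"`,
#'   `"sine_burst"`, `"sine"`.
#' @param carrier_frequency Carrier frequency `f1` in Hz (> 0).
#' @param modulation_frequency Beat / AM frequency in Hz (>= 0; must be 0
#'   for `kind = "sine"` and below `carrier_frequency / 2` otherwise).
#' @param per_channel_amplitude Per-carrier amplitude in mA (>= 0).
#' @param duration Signal duration in seconds.
#' @param burst_duty On-fraction of each modulation period for
#'   `"sine_burst"`, in (0, 1]. Default 0.5.
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(kind = c("sine", "tis_pair", "am_additive",
                                   "am_multiplicative", "sine_burst"),
                          carrier_frequency, modulation_frequency = 0,
                          per_channel_amplitude = 1, duration = 1,
                          burst_duty = 0.5) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(carrier_frequency), length(carrier_frequency) == 1L,
            is.finite(carrier_frequency), carrier_frequency > 0,
            is.numeric(modulation_frequency), modulation_frequency >= 0,
            per_channel_amplitude >= 0, duration > 0,
            burst_duty > 0, burst_duty <= 1)
  if (kind == "sine" && modulation_frequency != 0)
    stop("an unmodulated sine must have modulation_frequency = 0")
  if (kind != "sine" && modulation_frequency >= carrier_frequency / 2)
    stop("modulation_frequency must be below carrier_frequency / 2")
  structure(list(kind = kind, carrier_frequency = carrier_frequency,
                 modulation_frequency = modulation_frequency,
                 per_channel_amplitude = per_channel_amplitude,
                 duration = duration, burst_duty = burst_duty),
            class = "waveform_spec")
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat(sprintf("<waveform_spec> %s: f1 = %g Hz, AMF = %g Hz, A = %g mA, %g s\n",
              x$kind, x$carrier_frequency, x$modulation_frequency,
              x$per_channel_amplitude, x$duration))
  invisible(x)
}

#' Construct a uniformly sampled signal
#'
#' @param samples Numeric vector of sample values (mA or envelope units).
#' @param sample_rate Sampling rate in Hz.
#' @param channel_label Optional channel name.
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(samples, sample_rate, channel_label = "ch1") {
  stopifnot(is.numeric(samples), sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 channel_label = channel_label),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> '%s': %d samples @ %g Hz (%.4g s)\n",
              x$channel_label, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

# minimum oversampling of the fastest carrier present
.min_rate_factor <- 40
.default_rate_factor <- 100

.highest_carrier <- function(spec) {
  if (spec$kind %in% c("tis_pair", "am_additive"))
    spec$carrier_frequency + spec$modulation_frequency
  else if (spec$kind == "am_multiplicative")
    spec$carrier_frequency + spec$modulation_frequency / 2
  else spec$carrier_frequency
}

#' Synthesize a stimulation waveform
#'
#' Generates sampled signals for a [waveform_spec()]. A TIS pair returns the
#' two carrier channels (`f1` and `f2 = f1 + df`) separately; additive AM
#' returns their sum on one channel; multiplicative AM returns
#' `2A cos(pi df t) sin(2 pi fc t)` with `fc = f1 + df/2`, which is
#' trigonometrically identical to the additive sum; a sine burst gates the
#' carrier on/off at the modulation frequency with the given duty cycle.
#'
#' @param spec A [waveform_spec()].
#' @param sample_rate Sampling rate in Hz. Defaults to 100 samples per
#'   period of the highest carrier present; rates below 40 samples per
#'   period are rejected.
#' @return A list of one or two [sampled_signal()] objects (two for
#'   `"tis_pair"`).
#' @export
synthesize <- function(spec, sample_rate = NULL) {
  stopifnot(inherits(spec, "waveform_spec"))
  fhi <- .highest_carrier(spec)
  if (is.null(sample_rate)) sample_rate <- .default_rate_factor * fhi
  if (sample_rate < .min_rate_factor * fhi)
    stop(sprintf(paste("sample_rate %g Hz is below the floor of 40 samples",
                       "per carrier period; need at least %g Hz"),
                 sample_rate, .min_rate_factor * fhi))
  n <- round(spec$duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  f1 <- spec$carrier_frequency
  df <- spec$modulation_frequency
  A <- spec$per_channel_amplitude
  out <- switch(spec$kind,
    sine = list(sampled_signal(A * sin(2 * pi * f1 * t), sample_rate, "sine")),
    tis_pair = list(
      sampled_signal(A * sin(2 * pi * f1 * t), sample_rate, "carrier_f1"),
      sampled_signal(A * sin(2 * pi * (f1 + df) * t), sample_rate, "carrier_f2")),
    am_additive = list(sampled_signal(
      A * sin(2 * pi * f1 * t) + A * sin(2 * pi * (f1 + df) * t),
      sample_rate, "am_additive")),
    am_multiplicative = list(sampled_signal(
      2 * A * cos(pi * df * t) * sin(2 * pi * (f1 + df / 2) * t),
      sample_rate, "am_multiplicative")),
    sine_burst = {
      gate <- if (df > 0) as.numeric((t * df) %% 1 < spec$burst_duty) else 1
      list(sampled_signal(A * sin(2 * pi * f1 * t) * gate, sample_rate,
                          "sine_burst"))
    })
  out
}

#' Extract the slow envelope of a carrier signal
#'
#' Computes the analytic-signal magnitude (via FFT Hilbert transform) and
#' smooths it with a one-carrier-period moving average. For a sum of two
#' tones with amplitudes `A1`, `A2` offset by `df` the result equals
#' `sqrt(A1^2 + A2^2 + 2 A1 A2 cos(2 pi df t))` up to edge effects.
#'
#' @param signal A [sampled_signal()] containing at least 10 carrier periods.
#' @param carrier_frequency Carrier frequency in Hz; must be resolvable at
#'   the signal's sample rate.
#' @return A [sampled_signal()] holding the envelope.
#' @export
signal_envelope <- function(signal, carrier_frequency) {
  stopifnot(inherits(signal, "sampled_signal"), carrier_frequency > 0)
  fs <- signal$sample_rate
  if (carrier_frequency >= fs / 2)
    stop("carrier frequency is not resolvable at this sample rate")
  x <- signal$samples
  n <- length(x)
  if (n < 10 * fs / carrier_frequency)
    stop("signal must contain at least 10 carrier periods")
  # analytic signal: zero the negative frequencies, double the positive ones
  X <- stats::fft(x)
  hmask <- numeric(n)
  if (n %% 2 == 0) {
    hmask[1] <- 1; hmask[n / 2 + 1] <- 1; hmask[2:(n / 2)] <- 2
  } else {
    hmask[1] <- 1; hmask[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * hmask, inverse = TRUE) / n)
  # smooth over one carrier period to suppress ripple (centred boxcar)
  w <- max(1L, round(fs / carrier_frequency))
  if (w > 1L) {
    sm <- stats::filter(env, rep(1 / w, w), sides = 2)
    env <- ifelse(is.na(sm), env, as.numeric(sm))
  }
  sampled_signal(env, fs, paste0(signal$channel_label, "_env"))
}

#' Modulation index of an envelope
#'
#' `(max - min) / (max + min)` of the envelope, evaluated over complete
#' modulation periods when the modulation frequency is supplied (avoiding
#' edge bias), with a small edge trim otherwise.
#'
#' @param envelope A non-negative [sampled_signal()] envelope.
#' @param modulation_frequency Optional AM frequency in Hz; if given, the
#'   index is computed over `floor(T * f_mod) / f_mod` seconds.
#' @param edge_trim Fraction trimmed from each end when
#'   `modulation_frequency` is not given. Default 0.05.
#' @return Modulation index in \[0, 1\].
#' @export
modulation_index <- function(envelope, modulation_frequency = NULL,
                             edge_trim = 0.05) {
  stopifnot(inherits(envelope, "sampled_signal"))
  x <- envelope$samples
  if (any(x < -1e-9 * max(abs(x)))) stop("envelope must be non-negative")
  if (all(x == 0)) stop("modulation index is undefined for an all-zero envelope")
  n <- length(x)
  fs <- envelope$sample_rate
  if (!is.null(modulation_frequency) && modulation_frequency > 0) {
    nper <- floor((n / fs) * modulation_frequency)
    if (nper < 1) stop("signal shorter than one modulation period")
    x <- x[seq_len(round(nper * fs / modulation_frequency))]
  } else {
    k <- max(1L, round(edge_trim * n))
    x <- x[k:(n - k)]
  }
  (max(x) - min(x)) / (max(x) + min(x))
}

#' Integrated spectral power in a band
#'
#' Hann-windowed periodogram power integrated over
#' `[center - halfwidth, center + halfwidth]`. Used to verify that a pair
#' of kHz carriers carries no energy at the beat frequency.
#'
#' @param signal A [sampled_signal()].
#' @param center Band centre in Hz.
#' @param halfwidth Band half-width in Hz; `center + halfwidth` must be
#'   below the Nyquist frequency.
#' @return Band power in signal-units squared.
#' @export
band_power <- function(signal, center, halfwidth) {
  stopifnot(inherits(signal, "sampled_signal"), halfwidth >= 0)
  fs <- signal$sample_rate
  if (center + halfwidth >= fs / 2)
    stop("band extends beyond the Nyquist frequency")
  x <- signal$samples
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- x * w
  P <- Mod(stats::fft(xw))^2 / sum(w^2)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sel <- half & freqs >= (center - halfwidth) & freqs <= (center + halfwidth)
  sum(P[sel]) / n
}

#' Write a signal as a two-column CSV
#'
#' @param signal A [sampled_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "sampled_signal"))
  t <- (seq_along(signal$samples) - 1) / signal$sample_rate
  utils::write.csv(data.frame(time_s = t, value_mA = signal$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialize / read a waveform specification as JSON
#'
#' @param spec A [waveform_spec()].
#' @param path File path.
#' @return `write_waveform_json()` returns `path` invisibly;
#'   `read_waveform_json()` returns a [waveform_spec()].
#' @export
write_waveform_json <- function(spec, path) {
  stopifnot(inherits(spec, "waveform_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_waveform_json
#' @export
read_waveform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  waveform_spec(kind = x$kind, carrier_frequency = x$carrier_frequency,
                modulation_frequency = x$modulation_frequency,
                per_channel_amplitude = x$per_channel_amplitude,
                duration = x$duration, burst_duty = x$burst_duty)
}
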