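#' Activating-amplitude pair
#'
#' Per-carrier activating-function amplitudes `a1`, `a2` (V/m^2) at a point
#' in tissue, together with the common activation threshold `a_threshold`
#' (A_T, V/m^2). During one beat period the combined activating envelope
#' sweeps `sqrt(a1^2 + a2^2 + 2 a1 a2 cos(2 pi df t))`, i.e. between
#' `|a1 - a2|` and `a1 + a2`.
#'
#' @param a1,a2 Non-negative activating amplitudes in V/m^2.
#' @param a_threshold Activation threshold in V/m^2 (> 0). Default 1000,
#'   the calibrated value for a 2.5 kHz carrier.
#' @return An object of class `activating_pair`.
#' @export
activating_pair <- function(a1, a2, a_threshold = 1000) {
  stopifnot(all(is.finite(a1)), all(is.finite(a2)), all(a1 >= 0),
            all(a2 >= 0), all(is.finite(a_threshold)), all(a_threshold > 0))
  structure(list(a1 = a1, a2 = a2, a_threshold = a_threshold),
            class = "activating_pair")
}

# snap values within eps of 0/1 onto the exact branch value
.snap01 <- function(x, eps = 1e-12) {
  x[abs(x) < eps] <- 0
  x[abs(x - 1) < eps] <- 1
  x
}

#' Closed-form time over threshold
#'
#' Fraction of each modulation period during which the beat envelope of the
#' two interfering activating amplitudes exceeds the activation threshold:
#' 0 when `a1 + a2 < a_t` (never suprathreshold), 1 when `|a1 - a2| > a_t`
#' (always suprathreshold), and
#' `acos((a_t^2 - a1^2 - a2^2) / (2 a1 a2)) / pi` in between, with the
#' arccos argument clamped to \[-1, 1\] so the statistic is continuous
#' across the branch boundaries. Vectorized over the pair amplitudes.
#'
#' @param pair An [activating_pair()] (fields may be vectors).
#' @return Time over threshold, a fraction in \[0, 1\].
#' @export
tot_closed_form <- function(pair) {
  stopifnot(inherits(pair, "activating_pair"))
  a1 <- pair$a1; a2 <- pair$a2; at <- pair$a_threshold
  k <- max(length(a1), length(a2), length(at))
  a1 <- rep_len(a1, k); a2 <- rep_len(a2, k); at <- rep_len(at, k)
  tot <- numeric(k)
  lo <- (a1 + a2) < at
  hi <- abs(a1 - a2) > at
  mid <- !lo & !hi
  tot[hi] <- 1
  if (any(mid)) {
    prod2 <- 2 * a1[mid] * a2[mid]
    arg <- ifelse(prod2 > 0,
                  (at[mid]^2 - a1[mid]^2 - a2[mid]^2) / prod2,
                  -1)  # a1*a2 = 0 here implies a1 + a2 >= at: constant envelope over threshold
    arg <- pmin(1, pmax(-1, arg))
    tot[mid] <- acos(arg) / pi
  }
  .snap01(tot)
}

#' Dense-sampling time-over-threshold oracle
#'
#' Samples the beat envelope
#' `sqrt(a1^2 + a2^2 + 2 a1 a2 cos(2 pi delta_f t))` uniformly over one
#' modulation period and returns the fraction of samples at or above the
#' threshold. Serves as an independent check of [tot_closed_form()]; the
#' result does not depend on `delta_f` (the envelope shape is invariant
#' under time rescaling).
#'
#' @param pair An [activating_pair()] with scalar fields.
#' @param delta_f Beat frequency in Hz (affects only the time axis).
#' @param n_samples Number of samples over the period (>= 1000).
#' @return Fraction of the period at or above threshold.
#' @export
tot_oracle <- function(pair, delta_f = 1, n_samples = 10000) {
  stopifnot(inherits(pair, "activating_pair"), n_samples >= 1000,
            length(pair$a1) == 1, length(pair$a2) == 1)
  t <- (seq_len(n_samples) - 0.5) / n_samples / delta_f
  env <- sqrt(pair$a1^2 + pair$a2^2 +
                2 * pair$a1 * pair$a2 * cos(2 * pi * delta_f * t))
  mean(env >= pair$a_threshold)
}

#' Classify a stimulation region from its time over threshold
#'
#' @param tot Time over threshold value(s) in \[0, 1\].
#' @return `"subthreshold"` for 0, `"tonic"` for 1, `"phasic"` otherwise.
#' @export
classify_region <- function(tot) {
  if (any(!is.finite(tot)) || any(tot < 0) || any(tot > 1))
    stop("tot must lie in [0, 1]")
  tot <- .snap01(tot)
  ifelse(tot == 0, "subthreshold", ifelse(tot == 1, "tonic", "phasic"))
}
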