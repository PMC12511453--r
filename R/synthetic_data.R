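#' Configuration of a synthetic threshold study
#'
#' Describes the generative model for a synthetic strength-frequency or
#' AMF threshold study: per-subject thresholds follow the Reilly equation
#' scaled by a per-waveform multiplier, a lognormal subject random effect
#' and lognormal residual noise, and are then quantized by the staircase
#' ramp of the measurement procedure. Default waveform multipliers are
#' the observed threshold ratios relative to the unmodulated sine: locust
#' motor AM 1.29 / burst 1.06; human motor AM 0.99 / burst 0.97; human
#' sensory AM 0.93 / burst 0.84 (TIS behaves as AM). Ramp steps are
#' 0.005 mA below 5 kHz and 0.05 mA at or above 5 kHz for the locust
#' preparation, 0.025 / 0.25 mA for the human experiments.
#'
#' @param model `"locust"`, `"human_motor"` or `"human_sensory"`.
#' @param carrier_hz Carrier frequency grid. Default the 8-point grid
#'   `c(500, 1000, 2500, 5000, 7500, 10000, 11500, 12500)`.
#' @param waveforms Waveform labels. Default `c("sine", "am", "burst")`.
#' @param multipliers Named multipliers relative to sine; defaults per
#'   `model` as above.
#' @param n_subjects Number of subjects. Default 5.
#' @param subject_sd Lognormal subject-effect SD (log scale). Default 0.2.
#' @param residual_sd Lognormal residual SD (log scale). Default 0.05.
#' @param i0_ma Base Reilly scale I0 in mA; defaults 0.1 (locust),
#'   1 (human motor), 0.5 (human sensory).
#' @param ramp_step_ma Ramp increments `c(low, high)` used below / at-or-
#'   above 5 kHz; defaults per `model` as above.
#' @param amf_optimum_hz Optimal AMF of the U-curve; defaults 5 (motor
#'   models) or 1 (sensory).
#' @param amf_dip_depth Fractional threshold reduction at the optimal
#'   AMF. Default 0.2.
#' @param amf_log_width Log-scale width of the U-curve dip. Default 1.
#' @param seed Integer seed making generation deterministic. Default 1.
#' @return An object of class `study_config`.
#' @export
study_config <- function(model = c("locust", "human_motor", "human_sensory"),
                         carrier_hz = c(500, 1000, 2500, 5000, 7500,
                                        10000, 11500, 12500),
                         waveforms = c("sine", "am", "burst"),
                         multipliers = NULL, n_subjects = 5,
                         subject_sd = 0.2, residual_sd = 0.05,
                         i0_ma = NULL, ramp_step_ma = NULL,
                         amf_optimum_hz = NULL, amf_dip_depth = 0.2,
                         amf_log_width = 1, seed = 1) {
  model <- match.arg(model)
  if (is.null(multipliers))
    multipliers <- switch(model,
      locust = c(sine = 1, am = 1.29, burst = 1.06),
      human_motor = c(sine = 1, am = 0.99, burst = 0.97),
      human_sensory = c(sine = 1, am = 0.93, burst = 0.84))
  if (is.null(i0_ma))
    i0_ma <- switch(model, locust = 0.1, human_motor = 1, human_sensory = 0.5)
  if (is.null(ramp_step_ma))
    ramp_step_ma <- switch(model, locust = c(0.005, 0.05),
                           human_motor = c(0.025, 0.25),
                           human_sensory = c(0.025, 0.25))
  if (is.null(amf_optimum_hz))
    amf_optimum_hz <- if (model == "human_sensory") 1 else 5
  miss <- setdiff(waveforms, names(multipliers))
  if (length(miss))
    stop("no multiplier given for waveform(s): ", paste(miss, collapse = ", "))
  stopifnot(all(multipliers > 0), subject_sd >= 0, residual_sd >= 0,
            i0_ma > 0, all(ramp_step_ma >= 0), all(carrier_hz > 0),
            n_subjects >= 1, amf_dip_depth >= 0, amf_dip_depth < 1,
            amf_log_width > 0, amf_optimum_hz > 0)
  structure(list(model = model, carrier_hz = carrier_hz,
                 waveforms = waveforms, multipliers = multipliers,
                 n_subjects = as.integer(n_subjects),
                 subject_sd = subject_sd, residual_sd = residual_sd,
                 i0_ma = i0_ma, ramp_step_ma = ramp_step_ma,
                 amf_optimum_hz = amf_optimum_hz,
                 amf_dip_depth = amf_dip_depth,
                 amf_log_width = amf_log_width, seed = as.integer(seed)),
            class = "study_config")
}

#' Staircase ramp quantization of a measured threshold
#'
#' The measurement ramps the current upward in fixed increments until a
#' response appears, so the recorded threshold is the smallest integer
#' multiple of the step at or above the true threshold. A step of 0
#' leaves values unquantized.
#'
#' @param threshold_ma True threshold(s) in mA (> 0).
#' @param step_ma Ramp increment in mA (>= 0).
#' @return Quantized threshold(s) in mA.
#' @export
apply_ramp_quantization <- function(threshold_ma, step_ma) {
  if (any(!is.finite(threshold_ma)) || any(threshold_ma <= 0))
    stop("thresholds must be strictly positive")
  if (length(step_ma) != 1 || !is.finite(step_ma) || step_ma < 0)
    stop("step must be a single non-negative number")
  if (step_ma == 0) return(threshold_ma)
  ceiling(threshold_ma / step_ma - 1e-9) * step_ma
}

.ramp_step_for <- function(config, carrier_hz) {
  ifelse(carrier_hz < 5000, config$ramp_step_ma[1], config$ramp_step_ma[2])
}

#' Generate a synthetic strength-frequency dataset
#'
#' Thresholds are `I0 * Reilly(f) * multiplier(waveform) * exp(subject
#' effect) * exp(residual)`, ramp-quantized with the frequency-dependent
#' step. Generation is deterministic given the config's seed.
#'
#' @param config A [study_config()].
#' @return A threshold table with
#'   `n_subjects * length(waveforms) * length(carrier_hz)` rows.
#' @export
generate_sf_dataset <- function(config) {
  stopifnot(inherits(config, "study_config"))
  withr_seed <- .with_seed(config$seed)
  on.exit(withr_seed())
  subj <- sprintf("S%02d", seq_len(config$n_subjects))
  subj_eff <- stats::rnorm(config$n_subjects, 0, config$subject_sd)
  names(subj_eff) <- subj
  grid <- expand.grid(subject = subj, waveform = config$waveforms,
                      carrier_hz = config$carrier_hz,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- config$i0_ma * reilly_threshold(grid$carrier_hz) *
    config$multipliers[grid$waveform] * exp(subj_eff[grid$subject]) *
    exp(stats::rnorm(nrow(grid), 0, config$residual_sd))
  step <- .ramp_step_for(config, grid$carrier_hz)
  th <- vapply(seq_len(nrow(grid)), function(i)
    if (step[i] > 0) apply_ramp_quantization(base[i], step[i]) else base[i],
    numeric(1))
  out <- data.frame(subject = grid$subject, waveform = grid$waveform,
                    carrier_hz = grid$carrier_hz, amf_hz = 0,
                    threshold_ma = th)
  as_threshold_table(out)
}

#' Generate a synthetic AMF-dependence dataset
#'
#' Thresholds at a fixed carrier follow a U-shaped curve over the AM
#' frequency: `plateau * (1 - depth * exp(-(log(AMF/AMF_opt))^2 /
#' (2 w^2)))`, with the same subject/residual noise structure and ramp
#' quantization as the strength-frequency design.
#'
#' @param config A [study_config()].
#' @param amf_hz Positive AMF grid in Hz.
#' @param carrier_hz Carrier frequency. Default 2500.
#' @param waveform Waveform label recorded. Default `"am"`.
#' @return A threshold table with one row per subject and AMF.
#' @export
generate_amf_dataset <- function(config, amf_hz = c(0.5, 1, 2, 5, 10, 20, 50),
                                 carrier_hz = 2500, waveform = "am") {
  stopifnot(inherits(config, "study_config"), all(amf_hz > 0),
            length(carrier_hz) == 1, carrier_hz > 0)
  withr_seed <- .with_seed(config$seed + 1L)
  on.exit(withr_seed())
  subj <- sprintf("S%02d", seq_len(config$n_subjects))
  subj_eff <- stats::rnorm(config$n_subjects, 0, config$subject_sd)
  names(subj_eff) <- subj
  plateau <- config$i0_ma * reilly_threshold(carrier_hz)
  grid <- expand.grid(subject = subj, amf_hz = amf_hz,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dip <- 1 - config$amf_dip_depth *
    exp(-(log(grid$amf_hz / config$amf_optimum_hz))^2 /
          (2 * config$amf_log_width^2))
  base <- plateau * dip * exp(subj_eff[grid$subject]) *
    exp(stats::rnorm(nrow(grid), 0, config$residual_sd))
  step <- .ramp_step_for(config, rep(carrier_hz, nrow(grid)))
  th <- vapply(seq_len(nrow(grid)), function(i)
    if (step[i] > 0) apply_ramp_quantization(base[i], step[i]) else base[i],
    numeric(1))
  out <- data.frame(subject = grid$subject, waveform = waveform,
                    carrier_hz = carrier_hz, amf_hz = grid$amf_hz,
                    threshold_ma = th)
  as_threshold_table(out)
}

# run code under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
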