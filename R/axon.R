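#' Simplified myelinated-axon parameters
#'
#' A surrogate myelinated fibre: an odd number of active nodes of Ranvier
#' with Hodgkin-Huxley-type Na/K/leak channels, connected by purely
#' resistive internodes (perfectly insulating myelin). Channel kinetics are
#' accelerated by a temperature scaling factor so the node responds on the
#' sub-millisecond timescale of mammalian fibres. Absolute threshold
#' currents of this surrogate are not calibrated to any particular
#' experimental preparation; the model reproduces phenomena and threshold
#' ratios, not absolute currents.
#'
#' @param node_count Odd number of nodes (>= 21). Default 51.
#' @param internode_length_mm Internodal spacing in mm. Default 1.
#' @param node_length_um Nodal gap length in micrometres. Default 1.5.
#' @param diameter_um Axon diameter in micrometres. Default 7.
#' @param axoplasm_resistivity_ohm_cm Axoplasmic resistivity. Default 70.
#' @param capacitance_uF_cm2 Nodal membrane capacitance. Default 2.
#' @param g_na_mS_cm2,g_k_mS_cm2,g_leak_mS_cm2 Maximal nodal conductances.
#'   Defaults 1200, 90, 20 (nodal channel densities well above squid-axon
#'   values, as appropriate for nodes of Ranvier).
#' @param e_na_mV,e_k_mV Reversal potentials. Defaults +50, -90.
#' @param resting_potential_mV Resting potential; the leak reversal is
#'   solved internally so this is an exact fixed point. Default -80.
#' @param temperature_factor Multiplicative acceleration of all gating
#'   kinetics. Default 12.
#' @return An object of class `axon_params`.
#' @export
axon_params <- function(node_count = 51, internode_length_mm = 1,
                        node_length_um = 1.5, diameter_um = 7,
                        axoplasm_resistivity_ohm_cm = 70,
                        capacitance_uF_cm2 = 2, g_na_mS_cm2 = 1200,
                        g_k_mS_cm2 = 90, g_leak_mS_cm2 = 20,
                        e_na_mV = 50, e_k_mV = -90,
                        resting_potential_mV = -80,
                        temperature_factor = 12) {
  stopifnot(node_count %% 2 == 1, node_count >= 21, internode_length_mm > 0,
            node_length_um > 0, diameter_um > 0,
            axoplasm_resistivity_ohm_cm > 0, capacitance_uF_cm2 > 0,
            g_na_mS_cm2 > 0, g_k_mS_cm2 > 0, g_leak_mS_cm2 > 0,
            temperature_factor > 0)
  structure(list(node_count = as.integer(node_count),
                 internode_length_mm = internode_length_mm,
                 node_length_um = node_length_um, diameter_um = diameter_um,
                 axoplasm_resistivity_ohm_cm = axoplasm_resistivity_ohm_cm,
                 capacitance_uF_cm2 = capacitance_uF_cm2,
                 g_na_mS_cm2 = g_na_mS_cm2, g_k_mS_cm2 = g_k_mS_cm2,
                 g_leak_mS_cm2 = g_leak_mS_cm2, e_na_mV = e_na_mV,
                 e_k_mV = e_k_mV,
                 resting_potential_mV = resting_potential_mV,
                 temperature_factor = temperature_factor),
            class = "axon_params")
}

#' Extracellular point-source drive
#'
#' A monopolar point current source in a homogeneous medium of resistivity
#' `rho`; the extracellular potential at node i is
#' `rho * I(t) / (4 pi r_i)`. The drive waveform is normalized to unit
#' peak and scaled by `amplitude_mA`, so thresholds are expressed as the
#' peak current of the (possibly modulated) waveform — the same scale on
#' which experimental thresholds compare modulated and unmodulated
#' waveforms. For a TIS pair both carriers share the single point source,
#' so the delivered current is their (peak-normalized) sum.
#'
#' @param waveform A [waveform_spec()] (its `per_channel_amplitude` is
#'   ignored; `amplitude_mA` sets the scale).
#' @param position_mm Source position `c(x, y, z)` in mm relative to the
#'   centre of the axon, which runs along x. Default `c(0, 0, 1)`.
#' @param resistivity_ohm_cm Medium resistivity. Default 300.
#' @param amplitude_mA Peak current in mA. Default 1.
#' @param cathodic If `TRUE` (default) the leading phase is cathodic
#'   (negative), which depolarizes the node nearest the source.
#' @return An object of class `extracellular_drive`.
#' @export
extracellular_drive <- function(waveform, position_mm = c(0, 0, 1),
                                resistivity_ohm_cm = 300, amplitude_mA = 1,
                                cathodic = TRUE) {
  stopifnot(inherits(waveform, "waveform_spec"), length(position_mm) == 3,
            resistivity_ohm_cm > 0, amplitude_mA >= 0)
  structure(list(waveform = waveform, position_mm = position_mm,
                 resistivity_ohm_cm = resistivity_ohm_cm,
                 amplitude_mA = amplitude_mA, cathodic = cathodic),
            class = "extracellular_drive")
}

# per-unit-current extracellular potential at each node (mV/mA)
.node_potentials <- function(params, drive) {
  n <- params$node_count
  x <- (seq_len(n) - (n + 1) / 2) * params$internode_length_mm
  p <- drive$position_mm
  r_cm <- sqrt((x - p[1])^2 + p[2]^2 + p[3]^2) / 10
  if (any(r_cm <= 0)) stop("source position coincides with a node")
  drive$resistivity_ohm_cm / (4 * pi * r_cm)
}

# peak-normalized drive current waveform at the integration time step
.drive_current <- function(drive, dt_ms, n_steps) {
  t <- (seq_len(n_steps)) * dt_ms / 1000
  spec <- drive$waveform
  f1 <- spec$carrier_frequency
  df <- spec$modulation_frequency
  w <- switch(spec$kind,
    sine = sin(2 * pi * f1 * t),
    tis_pair = ,
    am_additive = sin(2 * pi * f1 * t) + sin(2 * pi * (f1 + df) * t),
    am_multiplicative = 2 * cos(pi * df * t) * sin(2 * pi * (f1 + df / 2) * t),
    sine_burst = {
      gate <- if (df > 0) as.numeric((t * df) %% 1 < spec$burst_duty) else 1
      sin(2 * pi * f1 * t) * gate
    })
  pk <- max(abs(w))
  if (pk > 0) w <- w / pk
  sgn <- if (drive$cathodic) -1 else 1
  sgn * drive$amplitude_mA * w
}

#' Simulate the axon under extracellular stimulation
#'
#' Integrates the cable equation for the surrogate fibre with a
#' backward-Euler membrane update and exponential (Rush-Larsen) gating,
#' which is stable for the stiff nodal dynamics at the kHz time steps
#' used. The default time step is `min(25 us, 1/(100 f_carrier))` with a
#' hard floor of 40 steps per carrier period.
#'
#' @param params An [axon_params()].
#' @param drive An [extracellular_drive()].
#' @param duration_s Simulated time in seconds. When the drive is
#'   modulated this must cover at least 2 modulation periods.
#' @param dt_ms Integration step in ms; defaults as above.
#' @param store_dt_ms Sampling interval of the stored membrane traces.
#'   Default 0.025 ms. Set `store_vm = FALSE` to skip trace storage
#'   (spike times are always recorded at full resolution).
#' @param store_vm Keep the membrane traces? Default `TRUE`.
#' @param passive If `TRUE`, freeze all gating variables at their resting
#'   values, making the membrane linear (used to demonstrate that
#'   rectification requires active channels).
#' @param stop_on_propagation If `TRUE`, stop integrating shortly after a
#'   spike reaches a node at least 5 internodes from the node nearest the
#'   source (used by threshold search).
#' @return An object of class `sim_result` with fields `t_ms`, `vm`
#'   (time-by-node matrix), `crossings` (full-resolution upward 0 mV
#'   crossing times per node), `vmax`, and metadata.
#' @export
simulate_axon <- function(params, drive, duration_s = 0.5, dt_ms = NULL,
                          store_dt_ms = 0.025, store_vm = TRUE,
                          passive = FALSE, stop_on_propagation = FALSE) {
  stopifnot(inherits(params, "axon_params"),
            inherits(drive, "extracellular_drive"), duration_s > 0)
  spec <- drive$waveform
  fhi <- .highest_carrier(spec)
  if (spec$modulation_frequency > 0 &&
      duration_s < 2 / spec$modulation_frequency)
    stop("duration must cover at least 2 modulation periods")
  dt_floor <- 1000 / (.min_rate_factor * fhi)
  if (is.null(dt_ms)) dt_ms <- min(0.025, 1000 / (100 * fhi))
  if (dt_ms > dt_floor + 1e-12)
    stop(sprintf("dt = %g ms violates the floor of 40 steps per carrier period (max %g ms)",
                 dt_ms, dt_floor))
  n_steps <- round(duration_s * 1000 / dt_ms)
  ve <- .node_potentials(params, drive)
  cur <- .drive_current(drive, dt_ms, n_steps)

  # internodal coupling per unit nodal membrane area (mS/cm^2)
  d_cm <- params$diameter_um * 1e-4
  l_node_cm <- params$node_length_um * 1e-4
  L_cm <- params$internode_length_mm / 10
  g_ax <- 1000 * d_cm /
    (4 * params$axoplasm_resistivity_ohm_cm * L_cm * l_node_cm)

  # leak reversal that makes the resting potential an exact fixed point
  gates <- .hh_rest_gates()
  vr <- params$resting_potential_mV
  ina <- params$g_na_mS_cm2 * gates$m^3 * gates$h * (vr - params$e_na_mV)
  ik <- params$g_k_mS_cm2 * gates$n^4 * (vr - params$e_k_mV)
  e_leak <- vr + (ina + ik) / params$g_leak_mS_cm2

  stop_nodes <- NULL
  if (stop_on_propagation) {
    ctr <- (params$node_count + 1) / 2
    stop_nodes <- setdiff(seq_len(params$node_count),
                          (ctr - 4):(ctr + 4))
  }
  res <- .cable_integrate(ve, cur, dt_ms, params$capacitance_uF_cm2,
                          params$g_na_mS_cm2, params$g_k_mS_cm2,
                          params$g_leak_mS_cm2, params$e_na_mV,
                          params$e_k_mV, e_leak, vr,
                          params$temperature_factor, g_ax, passive,
                          store_every = max(1L, round(store_dt_ms / dt_ms)),
                          store_vm = store_vm, spike_level = 0,
                          stop_nodes = stop_nodes)
  if (isTRUE(res$blowup))
    stop(sprintf("membrane potential exceeded 200 mV at t = %.3f ms; reduce the drive amplitude or time step",
                 res$blowup_t_ms))
  structure(list(t_ms = res$t_ms, vm = if (store_vm) res$vm else NULL,
                 crossings = res$crossings, vmax = res$vmax,
                 dt_ms = dt_ms, duration_s = duration_s, params = params,
                 drive = drive, passive = passive),
            class = "sim_result")
}

# HH gate steady states at rest (u = 0)
.hh_rest_gates <- function() {
  am <- 0.1 * 25 / (exp(2.5) - 1); bm <- 4
  ah <- 0.07; bh <- 1 / (exp(3) + 1)
  an <- 0.01 * 10 / (exp(1) - 1); bn <- 0.125
  list(m = am / (am + bm), h = ah / (ah + bh), n = an / (an + bn))
}

#' Detect spikes at one node
#'
#' Upward crossings of 0 mV with a 1 ms refractory merge window: crossings
#' closer than the merge window to the previous accepted spike are counted
#' as the same spike. Uses the full-resolution crossing times recorded by
#' the integrator when available, otherwise the stored membrane trace.
#'
#' @param result A `sim_result` from [simulate_axon()].
#' @param node_index Node number (1-based).
#' @param merge_window_ms Refractory merge window. Default 1 ms.
#' @return Spike times in ms.
#' @export
detect_spikes <- function(result, node_index, merge_window_ms = 1) {
  stopifnot(inherits(result, "sim_result"))
  n_nodes <- if (!is.null(result$params)) result$params$node_count
             else length(result$crossings)
  if (node_index < 1 || node_index > n_nodes) stop("invalid node index")
  raw <- if (!is.null(result$crossings) &&
             length(result$crossings) >= node_index)
    result$crossings[[node_index]]
  else {
    v <- result$vm[, node_index]
    up <- which(v[-1] >= 0 & v[-length(v)] < 0)
    result$t_ms[up + 1]
  }
  .merge_spikes(raw, merge_window_ms)
}

.merge_spikes <- function(times, merge_window_ms = 1) {
  if (length(times) == 0) return(numeric(0))
  times <- sort(times)
  keep <- times[1]
  last <- times[1]
  for (t in times[-1]) {
    if (t - last >= merge_window_ms) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}

# spike times pooled over all nodes >= `margin` internodes from the centre
.propagating_spikes <- function(result, margin = 5) {
  n <- result$params$node_count
  ctr <- (n + 1) / 2
  far <- setdiff(seq_len(n), (ctr - margin + 1):(ctr + margin - 1))
  .merge_spikes(sort(unlist(result$crossings[far])), 1)
}

#' Find the stimulation threshold by bisection
#'
#' Bisects the drive amplitude between `bounds` for the smallest peak
#' current that elicits at least one propagating spike (a 0 mV upward
#' crossing at a node >= 5 internodes from the node nearest the source)
#' within the stimulus window. The spike/no-spike response is checked at
#' both bounds before bisecting.
#'
#' @param params An [axon_params()].
#' @param drive An [extracellular_drive()] template (its amplitude is
#'   overridden).
#' @param bounds Lower/upper amplitude bracket in mA.
#'   Default `c(0.005, 1)`.
#' @param tolerance Relative amplitude tolerance. Default 0.01.
#' @param duration_s Stimulus window in seconds. Default
#'   `max(0.4, 2 / AMF)`.
#' @return Threshold peak amplitude in mA.
#' @export
find_threshold <- function(params, drive, bounds = c(0.005, 1),
                           tolerance = 0.01, duration_s = NULL) {
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[2] > bounds[1],
            tolerance > 0)
  amf <- drive$waveform$modulation_frequency
  if (is.null(duration_s))
    duration_s <- max(0.4, if (amf > 0) 2 / amf else 0)
  spikes_at <- function(a) {
    d <- drive
    d$amplitude_mA <- a
    r <- simulate_axon(params, d, duration_s, store_vm = FALSE,
                       stop_on_propagation = TRUE)
    length(.propagating_spikes(r)) > 0
  }
  lo <- bounds[1]; hi <- bounds[2]
  if (spikes_at(lo))
    stop(sprintf("lower bound %g mA already elicits a propagating spike", lo))
  if (!spikes_at(hi))
    stop(sprintf("no propagating spike at the upper bound %g mA", hi))
  while ((hi - lo) / hi > tolerance) {
    mid <- sqrt(lo * hi)
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

#' Threshold sweep over a list of waveforms
#'
#' Runs [find_threshold()] for each waveform specification with a fixed
#' stimulus window of `max(2 s, 2 modulation periods)` and collects the
#' results in a threshold table.
#'
#' @param params An [axon_params()].
#' @param sweep A list of [waveform_spec()] objects.
#' @param drive_template An [extracellular_drive()] whose waveform and
#'   amplitude are replaced per sweep entry.
#' @param bounds,tolerance Passed to [find_threshold()].
#' @param subject Subject label recorded in the table. Default
#'   `"model_axon"`.
#' @param window_s Stimulus window override; defaults to the fixed
#'   `max(2, 2/AMF)` seconds.
#' @return A threshold table with one row per specification.
#' @export
threshold_sweep <- function(params, sweep, drive_template = NULL,
                            bounds = c(0.005, 1), tolerance = 0.01,
                            subject = "model_axon", window_s = NULL) {
  if (length(sweep) == 0)
    return(as_threshold_table(data.frame(subject = character(0),
                                         waveform = character(0),
                                         carrier_hz = numeric(0),
                                         amf_hz = numeric(0),
                                         threshold_ma = numeric(0))))
  if (is.null(drive_template))
    drive_template <- extracellular_drive(sweep[[1]])
  rows <- lapply(sweep, function(spec) {
    stopifnot(inherits(spec, "waveform_spec"))
    d <- drive_template
    d$waveform <- spec
    amf <- spec$modulation_frequency
    win <- if (is.null(window_s)) max(2, if (amf > 0) 2 / amf else 0)
           else window_s
    th <- find_threshold(params, d, bounds = bounds, tolerance = tolerance,
                         duration_s = win)
    data.frame(subject = subject, waveform = spec$kind,
               carrier_hz = spec$carrier_frequency, amf_hz = amf,
               threshold_ma = th)
  })
  as_threshold_table(do.call(rbind, rows))
}

#' Mean rectified depolarization of a subthreshold trace
#'
#' Low-pass filters the membrane potential at one node (moving average
#' spanning ten carrier periods, which nulls the carrier and its harmonics
#' and passes components below about one tenth of the carrier frequency)
#' and returns the mean offset from rest over the second half of the
#' simulation. Positive values quantify carrier rectification; the metric
#' is undefined if the node spiked.
#'
#' @param result A `sim_result` with stored membrane traces.
#' @param node_index Node to analyse (1-based).
#' @return Mean rectified depolarization in mV.
#' @export
rectification_metric <- function(result, node_index) {
  stopifnot(inherits(result, "sim_result"), !is.null(result$vm))
  if (length(detect_spikes(result, node_index)) > 0)
    stop("rectification metric is undefined when the node spikes")
  v <- result$vm[, node_index]
  fs_khz <- 1 / (result$t_ms[2] - result$t_ms[1])
  fc_khz <- result$drive$waveform$carrier_frequency / 1000
  w <- max(1L, round(10 * fs_khz / fc_khz))
  if (w > 1L && w < length(v)) {
    sm <- stats::filter(v, rep(1 / w, w), sides = 2)
    v <- as.numeric(sm[!is.na(sm)])
  }
  half <- v[(length(v) %/% 2):length(v)]
  mean(half) - result$params$resting_potential_mV
}

#' Group propagating spikes into bursts and measure their spacing
#'
#' Spikes separated by more than `gap_ms` start a new burst; the mean
#' interval between successive burst onsets quantifies beat locking (for
#' suprathreshold TIS at beat frequency df, one burst per beat gives a
#' mean interval of `1000/df` ms).
#'
#' @param result A `sim_result`.
#' @param gap_ms Minimum silent gap between bursts. Default 50 ms.
#' @param skip_ms Ignore spikes before this time (onset transient).
#'   Default 50 ms.
#' @return A list with `onsets_ms` and `mean_interval_ms`.
#' @export
burst_intervals <- function(result, gap_ms = 50, skip_ms = 50) {
  sp <- .propagating_spikes(result)
  sp <- sp[sp >= skip_ms]
  if (length(sp) < 2)
    return(list(onsets_ms = sp, mean_interval_ms = NA_real_))
  onsets <- sp[c(TRUE, diff(sp) > gap_ms)]
  list(onsets_ms = onsets,
       mean_interval_ms = if (length(onsets) >= 2) mean(diff(onsets))
                          else NA_real_)
}

#' Export membrane traces as CSV
#'
#' @param result A `sim_result` with stored traces.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(result, path) {
  stopifnot(inherits(result, "sim_result"), !is.null(result$vm))
  df <- data.frame(time_ms = result$t_ms)
  vm <- as.data.frame(result$vm)
  names(vm) <- paste0("node_", seq_len(ncol(vm)))
  utils::write.csv(cbind(df, vm), path, row.names = FALSE)
  invisible(path)
}
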