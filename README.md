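# tiskit

Biophysics of kilohertz-carrier nerve stimulation, including temporal
interference stimulation (TIS), for researchers who need to reason
quantitatively about what kHz carriers — rather than their low-frequency
beat envelopes — do to peripheral nerves.

In TIS, two carriers at kHz frequencies f₁ and f₂ = f₁ + Δf are applied
through separate electrode pairs; their interference creates an
amplitude-modulated field beating at Δf. `tiskit` implements the
computational chain needed to analyse such experiments:

* **Waveforms** — synthesis of the TIS pair, additive/multiplicative AM,
  gated bursts and plain sines; envelope extraction, modulation index,
  band power (`synthesize()`, `signal_envelope()`, `modulation_index()`,
  `band_power()`).
* **Strength–frequency law** — the Reilly threshold equation
  I_TH(f) = I₀ (1 − e^(−500/f))^(−0.9) (1 − e^(−f/10))^(−0.8)
  and single-scale fits on log thresholds (`reilly_threshold()`,
  `fit_reilly()`).
* **Surrogate axon** — a McNeal-style cable of Hodgkin–Huxley nodes of
  Ranvier under extracellular point-source drive, exhibiting carrier
  rectification, temporal summation, beat-locked bursting and the
  strength–frequency rise; threshold search by bisection
  (`simulate_axon()`, `find_threshold()`, `threshold_sweep()`,
  `rectification_metric()`, `burst_intervals()`).
* **Time over threshold (TOT)** — the closed-form fraction of each
  modulation period that the combined activating amplitudes A₁, A₂
  spend above a threshold A_T:
  TOT = 0 if A₁+A₂ < A_T; 1 if |A₁−A₂| > A_T; else
  arccos((A_T² − A₁² − A₂²)/(2A₁A₂))/π — with a dense-sampling oracle
  and tonic/phasic/subthreshold region labels (`tot_closed_form()`,
  `tot_oracle()`, `classify_region()`).
* **Volume conductor** — a frequency-domain, three-layer (skin/fat/
  anisotropic muscle) finite-volume solver with constant-phase-element
  electrode–skin interfaces, activating-function maps |d²V/dx²| on the
  nerve plane, TOT maps under current steering, and an exact analytic
  disc model contrasting bimodal TIS with monomodal 2-electrode AM
  (`solve_pair()`, `activating_amplitude()`, `tot_map()`,
  `disc_compare()`).
* **Synthetic studies** — generation of threshold datasets with
  lognormal subject effects, waveform multipliers, AMF U-curves and
  staircase ramp quantization, plus the ratio and normalization
  summaries used to report them (`study_config()`,
  `generate_sf_dataset()`, `generate_amf_dataset()`,
  `threshold_ratios()`, `normalize_amf_curve()`, `run_study()`).

## Worked example

Generate a synthetic locust-style strength–frequency study (5 subjects,
3 waveforms, 8 carriers from 0.5 to 12.5 kHz), fit the Reilly equation
per waveform and summarize threshold ratios:

```r
library(tiskit)
report <- run_study(study_config("locust", n_subjects = 5, seed = 7))
report
#> <study_report> locust (seed 7)
#>   sine   I0 = 0.09908 mA, R^2 = 0.9990
#>   am     I0 = 0.1257 mA, R^2 = 0.9984
#>   burst  I0 = 0.1045 mA, R^2 = 0.9999
#>   am_over_sine     1.272 +/- 0.014 (n = 40)
#>   burst_over_sine  1.057 +/- 0.011 (n = 40)
```

The generator's true scale was I₀ = 0.1 mA with AM and burst multipliers
1.29 and 1.06: the pipeline recovers the scale within ~1%, fits with
R² ≥ 0.998, and the grand-mean ratios land within the sampling error of
the configured effects (n = 40 subject×frequency pairs each).

Classify a tissue point under TIS interference:

```r
tot_closed_form(activating_pair(a1 = 2.0, a2 = 0.5, a_threshold = 1.0))
#> [1] 1
classify_region(1)
#> [1] "tonic"
tot_closed_form(activating_pair(1, 1, sqrt(2)))
#> [1] 0.5
```

And ask the surrogate axon how a TIS drive locks to its beat:

```r
ap <- axon_params()
drive <- extracellular_drive(waveform_spec("tis_pair", 1000, 5))
th <- find_threshold(ap, drive, duration_s = 0.4)   # peak mA by bisection
drive$amplitude_mA <- 1.2 * th
sim <- simulate_axon(ap, drive, 1.4, store_vm = FALSE)
burst_intervals(sim)$mean_interval_ms
#> [1] 200
```

One spike burst per 5 Hz beat: 200 ms apart.

A thin command-line wrapper over the same functions is installed at
`inst/cli/tiskit.R` (subcommands `synth`, `tot`, `fit-sf`, `gen-study`,
`run-study`, `disc-compare`).

## Method details

The models, their assumptions, all default parameters and the numerical
choices are documented in `vignettes/methods.Rmd`.
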