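---
title: "Models and methods behind tiskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tiskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiskit)
```

# Scope

`tiskit` models the biophysics of kilohertz-carrier transcutaneous nerve
stimulation, in particular temporal interference stimulation (TIS), where
two kHz carriers at slightly different frequencies $f_1$ and
$f_2 = f_1 + \Delta f$ interfere inside tissue and create an amplitude
modulated (AM) field beating at $\Delta f$. The package chain runs from
stimulation waveforms, through a surrogate axon and a volume-conductor
model of the forearm, to synthetic threshold studies and their summary
statistics. This vignette documents the models, their assumptions, the
default parameter choices, and the numerical decisions, in that order.

# Waveforms and envelopes

Four stimulation conditions are synthesized by `synthesize()`: a TIS
carrier pair (two channels, pure tones at $f_1$ and $f_2$), additive AM
(the same tones summed in one channel), multiplicative AM
($2A\cos(\pi\Delta f t)\sin(2\pi f_c t)$ with $f_c = f_1 + \Delta f/2$,
trigonometrically identical to the additive sum), a gated sine burst, and
an unmodulated sine. The "carrier frequency" reported throughout is
$f_1$. Sampling defaults to 100 samples per period of the highest carrier
present, with a hard floor of 40; below the floor synthesis is refused
rather than silently aliased.

Envelopes are estimated by the magnitude of the FFT analytic signal,
smoothed by a one-carrier-period moving average. For a two-tone sum with
amplitudes $A_1, A_2$ the estimator reproduces the exact envelope
$\sqrt{A_1^2 + A_2^2 + 2A_1A_2\cos(2\pi\Delta f t)}$ to within 1% away
from the record edges. Two estimator artefacts are documented rather than
hidden: the smoothing rounds the sharp envelope nulls of an equal-
amplitude beat (so a measured modulation index is ≈ 0.99 rather than
exactly 1), and the analytic signal rings (Gibbs) by up to roughly 10% at
the hard gate edges of a burst. The modulation index
$(\max-\min)/(\max+\min)$ is evaluated over whole modulation periods when
the modulation frequency is supplied, to avoid edge bias.

The internal modulation depth of the multiplicative generator is not
independently configurable: full depth, matching the additive pair, is
assumed.

# The Reilly strength-frequency equation

Thresholds of sinusoidal stimulation follow the empirical law

$$I_{TH}(f) = I_0\,(1 - e^{-500/f})^{-0.9}\,(1 - e^{-f/10})^{-0.8},$$

a U-shaped curve rising both toward high frequencies (membrane
integration) and toward very low frequencies (accommodation). The four
shape constants are treated as fixed; only the scale $I_0$ (mA) is fitted
by default, because experimental strength-frequency data are summarized
by that one free scale. With fixed shape the least-squares problem on
log thresholds has the closed-form solution
$\log I_0 = \overline{\log I_{TH} - \log R(f)}$, which `fit_reilly()`
uses; an opt-in flag releases all five parameters and refines them with
Levenberg-Marquardt on the log scale. Fitting is done on log thresholds
because thresholds span more than an order of magnitude across
0.5-12.5 kHz and measurement errors are multiplicative; $R^2$ is
likewise reported on log thresholds.

# The surrogate axon

`simulate_axon()` integrates a McNeal-style cable: an odd number of
active nodes of Ranvier (default 51) joined by purely resistive
internodes (perfectly insulating myelin), driven extracellularly by a
point current source in a homogeneous medium of resistivity
300 Ω·cm, so node $i$ sees $V_e(t) = \rho I(t)/(4\pi r_i)$. Nodal
membranes carry Hodgkin-Huxley Na/K/leak kinetics with densities scaled
to nodal values (defaults $g_{Na} = 1200$, $g_K = 90$,
$g_L = 20$ mS/cm², $C_m = 2$ µF/cm²) and all gating rates accelerated by
a temperature factor (default 12) so the node responds on the
sub-millisecond timescale of mammalian fibres. The leak reversal is
solved at construction so the stated resting potential (−80 mV) is an
exact fixed point.

This surrogate deliberately does not reproduce any published
multi-compartment fibre model: absolute threshold currents are not
calibrated, and only phenomena and threshold *ratios* are asserted
anywhere in the package. The phenomena it does reproduce are the ones
that matter for kHz carriers:

* **Rectification / temporal summation.** The Na activation
  nonlinearity converts a symmetric kHz sine into net depolarization
  that accumulates over cycles. `rectification_metric()` quantifies it
  as the mean low-passed offset from rest (moving average spanning ten
  carrier periods, which nulls the carrier and its harmonics and passes
  components below about $f_c/10$); with gating frozen at rest
  (`passive = TRUE`) the membrane is linear and the metric vanishes.
* **Beat-locked firing.** Slightly suprathreshold TIS at
  $\Delta f = 5$ Hz reaches threshold once per beat, producing spike
  bursts 200 ms apart.
* **The strength-frequency rise.** Thresholds increase monotonically
  with carrier frequency in the 1-10 kHz range.

Numerics: backward-Euler membrane update with frozen-conductance
linearization and a tridiagonal Thomas solve per step, Rush-Larsen
exponential gating, $\Delta t = \min(25\,\mu s, 1/(100 f_c))$ with a
hard floor of 40 steps per carrier period; the integrator aborts if
$|V_m|$ exceeds 200 mV. Spike detection uses upward 0 mV crossings
recorded at full resolution with a 1 ms refractory merge; a *propagating*
response requires a crossing at least 5 internodes from the node nearest
the source, which excludes local non-propagating depolarizations.
`find_threshold()` bisects the peak drive amplitude (geometric midpoints,
1% relative tolerance by default) after validating spike/no-spike at both
bracket ends; at very large amplitudes the model exhibits conduction
block, so brackets should stay near the threshold range.
Thresholds are expressed as the **peak current of the whole (possibly
modulated) waveform**, the same scale on which the experimental
literature compares modulated against unmodulated waveforms; with a
single point source the TIS pair is driven as the peak-normalized sum of
its two tones. All simulations are deterministic; there are no
stochastic channels.

The sweep used in testing covers 1-10 kHz at six carriers with a fixed
2 s stimulus window (or two modulation periods if longer) and a coarse 5%
bisection tolerance; these problem sizes keep a full sweep in the
minutes range while leaving the monotonicity and ratio margins far above
the bisection tolerance.

# Time over threshold

At a tissue point receiving activating-function amplitudes $A_1, A_2$
from the two carrier pairs, the beat envelope sweeps
$[\,|A_1-A_2|,\ A_1+A_2\,]$ once per modulation period. The fraction of
the period spent at or above a common threshold $A_T$ is

$$\mathrm{TOT} = \begin{cases}
0 & A_1 + A_2 < A_T\\[2pt]
\frac{1}{\pi}\arccos\!\left(\dfrac{A_T^2 - A_1^2 - A_2^2}{2A_1A_2}\right)
  & |A_1 - A_2| \le A_T \le A_1 + A_2\\[6pt]
1 & |A_1 - A_2| > A_T.
\end{cases}$$

TOT = 0 marks unstimulated tissue, TOT = 1 a tonic region (always above
threshold), anything between a phasic region firing once per beat. The
arccos argument is clamped to $[-1, 1]$, which makes the statistic exactly
continuous across the branch boundaries; values within $10^{-12}$ of 0 or
1 are snapped before classification. A dense-sampling oracle
(`tot_oracle()`, fraction of envelope samples at or above threshold over
one period, ties counted as over) provides an independent check; closed
form and oracle agree to the sampling resolution on $10^4$ random
triples.

One property worth stating because it is counterintuitive: TOT is
monotone in the *common scale* of $(A_1, A_2)$ and antitone in $A_T$, but
**not** monotone in one amplitude alone — in a tonic region, raising only
the weaker amplitude deepens the modulation, pulls the envelope floor
below threshold, and reduces TOT. The test suite encodes this
counterexample.

# The layered volume conductor

`solve_pair()` solves the frequency-domain current continuity equation
$\nabla\!\cdot\!\big((\sigma + j\omega\varepsilon_0\varepsilon_r)\nabla V\big) = 0$
on a structured cell-centred finite-volume grid over a three-layer slab:
skin (1.5 mm), fat (5 mm), muscle (remainder of a 40 mm slab), with
muscle transversely anisotropic (0.6 S/m and $\varepsilon_r = 1.5\cdot10^5$
along the fibre/x direction, 0.35 S/m and $1\cdot10^5$ across; fat
0.0243 S/m / 3000; skin 0.0015 S/m / 40000). Layer thicknesses are
configurable defaults, chosen so the nerve plane at 1 cm depth lies in
muscle. Face conductances use the exact two-half-cell series form, which
handles layer interfaces and the non-uniform (geometrically graded)
depth spacing.

Each electrode is a square gel patch (default 20 mm) treated as one
equipotential unknown, coupled to the skin surface through the
electrode-skin interface: a constant phase element of per-area admittance
$(j\omega)^\alpha/K$ ($K = 35$ MΩ·s$^{-\alpha}$·cm², $\alpha = 0.9$) in
parallel with a charge-transfer resistance $R_p = 4.7$ MΩ·cm², in series
with the top half-cell. The active pair carries a prescribed total
current $\pm I$; the inactive pair floats at zero net current but remains
in the circuit and may shunt. Both carriers are solved at $f_1$ — for
beat offsets of a few Hz the per-pair transfer functions are numerically
indistinguishable. The default montage places the two pairs on either
side of the nerve midline (pair 1 at $y = -25$ mm, pair 2 at $+25$ mm,
electrodes at $x = \pm 30$ mm), so the per-pair activating amplitudes are
equal on the midline and modulation is maximal there; the default lateral
extent uses an odd cell count so the midline lies on the grid.

The pure-Neumann operator has a constant nullspace; one deep corner cell
is pinned to 0 V by deleting its row *and* column (exact, and it keeps
the operator symmetric). The complex system $R + jS$ (SPD real part, PSD
imaginary part) is solved by BiCGSTAB preconditioned with a CHOLMOD
Cholesky factorization of $R + S$, to a $10^{-12}$ relative residual —
typically a few tens of iterations and about a second at the default
$32\times25\times14$ grid. Potentials are therefore defined up to that
grounding choice, and accuracy checks against analytic references
compare offset-corrected potentials. Against the half-space point-source
solution $I/(2\pi\sigma r)$ in a homogenized medium the solver is within
5% at 3-10 cells from the electrode; per-electrode injected current is
reproduced essentially exactly because the gel equation *is* the
current constraint; superposition across pairs holds to solver
precision; and halving the grid spacing changes the nerve-plane
activating amplitude by under 5%.

Activating amplitudes are $A = |d^2V/dx^2|$ (modulus of the complex
second central difference along the fibre direction) on the nerve plane,
and `tot_map()` turns the two per-pair fields into TOT and region maps.
$A_T$ defaults to 1000 V/m², the calibrated threshold for a 2.5 kHz
carrier; since the electrode geometry behind that calibration is not
re-derivable, $A_T$ is a given constant here, not a computed quantity.
Because the discrete solution is linear in the injected currents,
current-steering sweeps (e.g. 5,5 → 1,9 mA) can rescale the two fields
without re-solving.

# The disc comparison

For the qualitative contrast between 4-electrode TIS and 2-electrode
premodulated AM the package uses a uniformly conductive disc, where the
field of a boundary source/sink pair has the exact Green's function
$V(z) = \frac{I}{\pi\sigma t}\,\ln\frac{|z-b|}{|z-a|}$ — harmonic in the
interior with zero normal current through the rest of the circle. Using
the closed form instead of a mesh makes every comparison exact and
instantaneous; the tests verify the Green's function independently
(discrete-Laplacian residual, boundary flux, and current integral around
the source).

Four electrodes sit at 45°, 135°, 225°, 315°. TIS drives the top chord
(pair 1, $f_1$) and the bottom chord (pair 2, $f_2$); AM drives both
tones through pair 1 alone. By mirror symmetry the two per-pair fields
at the centre are parallel and equal, so at equal per-carrier current
the centre sees *identical* fully modulated stimulation in both modes —
the equality asserted at 1% in the tests is exact in this montage, not a
numerical coincidence. Away from the centre the modes diverge: AM keeps
modulation index 1 everywhere (monomodal), while TIS develops an
unmodulated floor $\sqrt{|E_1|^2+|E_2|^2-2|E_1\!\cdot\!E_2|}$ that near
the electrodes exceeds the centre's envelope amplitude (bimodal: tonic
shells superficial to the phasic hotspot). Fields are reported as
$\bar E = E\sigma d/I$, which depends only on the montage geometry — a
property the implementation inherits exactly from the closed form.

# The synthetic study generator

`generate_sf_dataset()` draws per-record thresholds as

$$I = I_0\,R(f)\,m_w\,e^{u_s}\,e^{\varepsilon},\qquad
u_s \sim N(0, \sigma_s^2),\ \varepsilon \sim N(0, \sigma_r^2),$$

then snaps them up to the staircase ramp grid (smallest step multiple at
or above the true value — the experimental up-down bracketing collapses
to exactly this ceiling). Effects are lognormal because thresholds are
positive and the studies summarize multiplicative ratios. The defaults
*are* the study conditions being emulated: waveform multipliers
AM 1.29 / burst 1.06 (locust), 0.99 / 0.97 (human motor), 0.93 / 0.84
(human sensory), TIS treated as AM; an 8-point carrier grid from 0.5 to
12.5 kHz (the exact experimental grid points are not published; the
studies report 8 frequency levels); ramp steps 5/50 µA (locust,
below/at-or-above 5 kHz) and 25/250 µA (human); subject SD 0.2 and
residual SD 0.05 on the log scale, plausible magnitudes for
between-subject spread (~±20%) and within-session repeatability (~5%)
in such preparations; base $I_0$ of 0.1 / 1 / 0.5 mA chosen so that
quantization is a few percent of threshold, as in the experiments. The
AMF design multiplies a log-Gaussian dip into the plateau: optimum 5 Hz
(motor) or 1 Hz (sensory), 20% deep, one log-unit wide. Generation is
deterministic given the seed, with the caller's RNG state restored.

What the generator does *not* emulate: per-frequency heterogeneity of
waveform effects, perception/reporting bias (the burst effect is encoded
only as its net multiplier), session/electrode drift, and any
correlation between subject effect and frequency. Recovery tests passing
on these data therefore show that the pipeline's estimators are
consistent under the stated noise model, not that real data are this
clean.

`threshold_ratios()` forms ratios per matched (subject, frequency)
record and pools mean ± SEM over all pairs; whether the printed ratios
of the original analyses pool per-frequency means or per-pair values is
ambiguous, so both modes exist and pooled pairs is the default (the
subject effect cancels within each pair, which is what makes the ratio
the natural summary). `normalize_amf_curve()` normalizes each subject by
their own minimum before averaging, which is why the averaged curve need
not touch 1 anywhere. `run_study()` fits the Reilly scale to pooled
per-waveform mean log thresholds — per-participant fits are a
configuration away but pooled fits are the default, matching how a
single $R^2 > 0.99$ per waveform is reported.

# Known limitations

* The axon is a phenomenological surrogate: no published-model
  parameter set, no absolute currents, no conduction-block or network
  effects; the intrinsic burst rate of the model is not asserted.
* The volume conductor is a flat slab on a structured grid — no curved
  forearm geometry, no tissue dispersion beyond the single-frequency
  material values, no Joule heating.
* The scalar TOT statistic ignores phase offsets between the carrier
  pairs (the 180° phase structure between hotspots is not modelled).
* Stimulator hardware behaviour (current roll-off at high frequency) is
  out of scope; waveforms are ideal.
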