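---
title: "Estimating SR calcium release fluxes from low-affinity dye fluorescence"
author: "caflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating SR calcium release fluxes from low-affinity dye fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caflux)
```

## The measurement problem

In a skeletal muscle fiber, an action potential (AP) or a voltage-clamp step
opens the sarcoplasmic-reticulum (SR) release channels for a few
milliseconds. The quantity of physiological interest is the release flux
R(t), in µM of Ca²⁺ per ms delivered to the myoplasm — not the free-Ca²⁺
transient, which under recording conditions is shaped almost entirely by
the buffers present. The experimental trick this package models is to load
the fiber with a *low-affinity* indicator (OGB-5N, Kd ≈ 60 µM, sub-ms
kinetics) and a *high* concentration of the slow chelator EGTA. EGTA
dominates removal, suppresses contraction, and clamps resting free Ca²⁺
near its Kd; the fast dye then tracks release nearly proportionally, and
the remaining distortion can be inverted with a kinetic model.

`caflux` implements that computation chain: a forward single-compartment
buffering model, its kinetic inversion, and the downstream analyses of
single transients, tetanic trains, voltage dependence, and confocal
sarcomeric line scans — plus a seeded synthetic-data generator so the whole
chain can be validated without any experimental recordings.

## The single-compartment model

The myoplasm is one well-stirred compartment with five buffer pools, each a
single site that binds at most one ion:

| buffer      | total  | Ca²⁺ kon (µM⁻¹ms⁻¹) | Ca²⁺ koff (ms⁻¹) | Mg²⁺ kon | Mg²⁺ koff |
|-------------|--------|------|---------|---------|--------|
| parvalbumin | 900 µM | 0.025 | 0.7    | 1.5e-5  | 0.003  |
| troponin    | 240 µM | 0.15  | 0.45   | —       | —      |
| ATP         | 5 mM   | —     | —      | 0.013   | 0.15   |
| EGTA        | 30 mM  | 0.0105 | 0.00075 | —     | —      |
| OGB-5N      | 250 µM | 0.157 | 9.42   | —       | —      |

with 15 mM total Ca²⁺ (resting free 0.075 µM) and 5 mM total Mg²⁺ (resting
free 0.15 mM). Printed second-order on-rates of the form "µM ms⁻¹" are read
as µM⁻¹ ms⁻¹, the only dimensionally consistent interpretation.
Parvalbumin's Ca²⁺ and Mg²⁺ reactions compete for one 900-µM pool. There is
no SR-uptake (SERCA) term: in the high-EGTA regime, removal is by
buffering, and the inversion therefore returns pure release. Every
reaction follows mass action,

$$\frac{d[\mathrm{XB}]}{dt} = k_{on}[\mathrm{X}]\,(B_{tot}-[\mathrm{CaB}]-[\mathrm{MgB}]) - k_{off}[\mathrm{XB}],$$

with $d[\mathrm{Ca}]/dt = R(t) - \sum(\text{Ca binding rates})$ and the Mg
equation without a source.

### Initialization: clamped vs solved

Two resting states are offered. `"clamped"` (the default) fixes free Ca²⁺
and Mg²⁺ at the stated resting values and equilibrates every buffer against
them — this reproduces the published operating point exactly, at the cost
of implied totals that differ slightly from the nominal 15/5 mM.
`"solved"` instead solves the two conservation equations by nested monotone
bisection. The two disagree slightly, and the disagreement is informative:

```{r equilibria}
p <- default_params()
eq <- equilibrium_state(p, "solved")
round(c(ca_free = eq[["ca"]], mg_free = eq[["mg"]]), 4)
```

Solved free Ca²⁺ (≈0.0714 µM) sits essentially at the EGTA Kd
(0.00075/0.0105 = 0.0714 µM), a hair under the stated 0.075 µM — consistent
with the design of the 2:1 EGTA:Ca pipette mixture. Solved free Mg²⁺
is ≈117 µM, not the stated 150 µM: with an ATP–Mg Kd of 0.15/0.013 ≈ 11.5
µM, 5 mM ATP sequesters ~4.56 mM of the 5 mM Mg. The stated 0.15 mM was
estimated with different (physiological) binding constants than the model's
kinetic ones; both numbers are reported, the clamped mode is the default,
and the tests assert the solved values as computed. This is a known,
documented tension in the parameter set, not a solver artifact (the solved
state passes an independent grid-refinement oracle and detailed balance to
1e-9 µM/ms).

### Numerics

EGTA and dye binding rates reach ~250 ms⁻¹ at stimulation levels, i.e.
sub-10-µs time constants against a 30-µs sampling grid, so the system is
stiff. Integration uses a 2-stage L-stable SDIRK scheme (γ = 1 − √2/2)
with the analytic Jacobian, Newton iteration, step-doubling error control
at relative tolerance 1e-8, and a hard 10-µs cap on the internal step
(compiled code, RcppArmadillo). Two properties are worth noting:

* Runge–Kutta methods preserve linear invariants exactly, so total Ca and
  Mg are conserved to rounding error *provided* no step straddles a kink of
  the piecewise-linear forcing; internal steps are therefore aligned to the
  input grid. Conservation is re-checked at every output sample
  (tolerance 1e-6 relative, an error otherwise).
* The trajectory agrees with a 0.1-µs explicit-Euler reference to better
  than 1e-4 relative on AP-scale inputs (a test oracle kept free of any
  shared code).

Negative states abort with a diagnostic rather than being silently
clamped; tiny negative round-off (< 1e-6 of scale) is zeroed.

## Fluorescence model and kinetic inversion

The dye signal model is linear in occupancy: Ca-bound dye is φ times
brighter than free dye, so

$$\Delta F/F(t) = \frac{(\phi-1)\,(\mathrm{CaD}(t)-\mathrm{CaD}_{rest})}{D_{tot} + (\phi-1)\,\mathrm{CaD}_{rest}}.$$

φ defaults to 40 and is a configuration knob; every round-trip analysis is
φ-invariant because the forward and inverse transforms share it (tested for
φ ∈ {5, 40, 100}). The source reports ΔF/F without a brightness model, so
this block is explicitly package plumbing, chosen to be exactly invertible.

`flux_from_dfof()` inverts a transient in four steps: (1) algebraic
inversion of the brightness model to CaD(t); (2) inversion of the single
dye reaction to free Ca²⁺,
$[\mathrm{Ca}](t) = (d\mathrm{CaD}/dt + k_{off}\mathrm{CaD})\,/\,(k_{on}(D_{tot}-\mathrm{CaD}))$;
(3) forward integration of all *other* buffers driven by that free-Ca
trajectory (free Mg²⁺ integrated alongside, same stiff scheme, forcing
linearly interpolated); (4) summation of all Ca-appearance rates into
R(t). Derivatives come from a Savitzky–Golay filter (default 7 samples /
0.21 ms, order 3); edge samples whose window does not fit are *flagged
invalid*, never extrapolated, and `peak_flux()` ignores them. The
derivative is also biased within one window of a slope discontinuity
(e.g. a flux onset) — visible as a one-sample blip, irrelevant at the peak.
Negative excursions are reported as computed (clamping hides inversion
artifacts); a clamp-to-zero flag and a warning threshold exist.

The no-tuning validation is the round trip: simulate a 260 µM/ms,
2-ms-FDHM alpha-function release through the full model, convert to ΔF/F,
invert — peak and integral return within 2% (actually ~0.1% noise-free),
and linearity holds to 0.5% at small amplitudes.

## Transient, train, and voltage analyses

**Single transients.** AP onset is the first crossing of dV/dt ≥ 10 mV/ms
(the source states no criterion; configurable). Latency uses a 5%-of-peak
threshold, robust to baseline noise. FDHM is interpolated linearly at half
peak. Decays are fitted with a double exponential by variable projection —
amplitudes and offset are linear given the two time constants, so the
optimizer runs over (log τ₁, log τ₂) from a deterministic log-spaced grid
of starts, avoiding the classic local minima; components are returned
fast-first, and τ₁ ≈ τ₂ (within 1%) is flagged degenerate rather than
trusted.

**Trains.** For each stimulus the peak is read in (tᵢ, tᵢ + min(IPI, 10 ms)]
and the inter-pulse level as the minimum in the 1 ms ending at tᵢ (the
source draws the envelope through "inter-pulse values" without defining the
sample point). Envelopes are monotone piecewise-cubic interpolants
(no overshoot between anchors). The depression ratio is defined last/first
∈ (0, 1] — the published phrasing ("first and last") is directionally
ambiguous, but only last/first declines with frequency as plotted. Spike
detection requires one local maximum above −20 mV per stimulus window; AP
amplitude is measured from the pre-train baseline (mean of the preceding
5 ms), end-of-train depolarization as the minimum in the final inter-pulse
interval minus that baseline.

**Voltage dependence.** Sweep peak = maximum within the 20-ms pulse;
steady state = mean of the final 25% of the pulse (the marked "steady dot"
is otherwise undefined). The Boltzmann is implemented as the *increasing*
sigmoid $y = y_{max}/(1+e^{(V_{1/2}-V)/k})$: the formula as printed in the
source decreases with V, which contradicts its own figures; the sign
convention is corrected deliberately so k > 0 and release grows with
depolarization. Fitting again uses variable projection (amplitude linear)
over a deterministic (v_half, log k) multi-start. Voltages are absolute
(holding −90 mV plus step). A statistical note: with 0.02 ΔF/F noise on a
21-point family, the efficient (least-squares = maximum-likelihood)
estimator has SD(V₁/₂) ≈ 0.95 mV and SD(k) ≈ 0.8 mV; recovery claims are
therefore tested at 95%-coverage bounds (±2.5 mV, ±2.2 mV) rather than at
"10% of the parameter", which for V₁/₂ = 7 mV would demand sub-CRLB
precision.

**Population statistics.** Peak-flux distributions are summarized by a
single Gaussian fitted by least squares to histogram counts
(Freedman–Diaconis bins by default); because whether a published center
came from binned counts or raw moments is unknowable, the sample mean ± SEM
is always reported alongside (for anything near-Gaussian they agree).
Group comparison is the pooled-variance Student's t (the method named in
the source), with Welch behind a flag; no multiple-testing correction, as
none was used.

## Confocal line scans

A scan is a position × time ΔF/F matrix, 0.2-µm steps across ≥ 2 sarcomeres
of period ≈ 2.1 µm. Geometry: two triads (T) per sarcomere at ±0.5 µm from
each Z line (mammalian A–I junction placement), M line midway between Z
lines. The classifier works on the per-position temporal peak profile:
period by autocorrelation (searched around the nominal period, parabolic
refinement), then an exhaustive fine phase grid in which positions are
labeled by nearest canonical site and the phase maximizing the T-vs-M
contrast wins — the maximizing plateau's midpoint is used, so labels sit
centrally between flips. Profile maxima thus become T and the deepest
valleys M, matching the anatomical reading, and the classifier never sees
generator ground truth. A flat profile is an explicit failure, not a
guess.

### What the generator emulates — and a design choice worth recording

The generator models Ca²⁺ microdomains as Gaussian bumps centered on the
triads, observed through a 1-D Gaussian PSF (0.8 µm FWHM). Because a
Gaussian blurred by a Gaussian is again Gaussian, the observed profile is
analytic, and the generator *solves* the domain width, amplitude and
offset so the observed (post-PSF) profile passes exactly through the
programmed T/Z/M amplitudes (default 0.6/0.45/0.35). The programmed
amplitudes are therefore *observed* quantities. The alternative — fixing a
narrow underlying site template and convolving it — was checked numerically
and rejected: with triads only 0.5 µm from the Z line, an 0.8-µm PSF pools
both flanking triads onto Z and *inverts* the T > Z ordering, which no
published profile shows; published amplitudes are already post-PSF. With
`psf_fwhm = 0` the profile degenerates to the unblurred template, and a
`"plateau"` profile mode (every position carries its class amplitude
exactly) is provided for class-average recovery tests. The scan phase
default (0.17 µm) keeps every position strictly inside one class at the
0.2-µm step — positions exactly equidistant between two site classes are
otherwise genuinely ambiguous and flip on rounding.

Limitations: the generator is 1-D (no radial PSF tail), transients scale
with a single kernel (no position-dependent kinetics), and noise is
stationary Gaussian filtered at 2 kHz (4-pole Bessel approximation of the
stated signal conditioning; the source names only cutoff frequencies). A
green classification test therefore establishes the estimator's geometry
and contrast logic, not robustness to non-stationary motion artifacts or
photobleaching, which real scans contain.

## Synthetic data: the stated world

Generator defaults are the published operating conditions, fixed once:
30-µs sampling; AP-evoked ΔF/F transients with peak ≈ 0.63, 1.4-ms latency,
3-ms time-to-peak, 2-ms FDHM, double-exponential decay (0.63/1 ms,
0.04/19 ms); 1-s trains at 10–100 Hz with 0.5-ms pulses; 20-ms clamp steps
from −90 mV, −20 to +180 mV in 10-mV increments; Boltzmann examples
(0.77, 7 mV, 13 mV peak; 0.37, 6 mV, 11 mV steady); line scans with 2.1-µm
sarcomeres and T > Z > M amplitudes; release fluxes of 2-ms FDHM peaking at
hundreds of µM/ms. Optical noise defaults to rms 0.005 ΔF/F (the source
does not state its noise floor; this level reproduces the visual quality of
published single sweeps). All randomness flows through explicit seeds via a
private RNG stream — generators never touch the global `.Random.seed`. The
transient kernel solves its internal rise width and fast decay constant so
the requested latency/time-to-peak/FDHM hold exactly; the AP spike carries
a quartic taper completing repolarization within ~10 ms so that 100-Hz
trains return to baseline between stimuli.

Trains are built by kernel superposition plus an explicit inter-pulse
buildup term (fast path); the full forward-model path is exercised
separately by the round-trip tests. This is a deliberate split: envelope
analysis is tested against exact ground truth, model physics against the
integrator oracle.

## I/O and degenerate inputs

Traces travel as two-column CSV (`time_ms`, unit-tagged value column) at
full double precision with uniformity enforced on read; line scans as wide
CSV; model parameters as JSON with units embedded in field names
(`kon_per_uM_ms`). HDF5 and YAML interfaces were dropped: no R-side HDF5
or YAML package is available in the supported environment, and CSV/JSON
round trips are tested lossless. `run_pipeline()` executes a
synthesize-then-analyze stage from a config list or JSON file and is a pure
function of the config (byte-identical outputs, logged seeds and parameter
hash).

Degenerate inputs have defined behavior throughout: dye saturation in an
inversion reports the offending samples; a peak on a window edge is
flagged; all-equal histogram values and flat scan profiles are errors; a
missing spike reports its stimulus index; a single-fiber site average
returns NA SEM with a flag.

## Known limitations

* The compartment is spatially homogeneous; confocal "local" fluxes are
  the same inversion applied to site-class means, not a reaction–diffusion
  solution.
* No SERCA term: slow post-train relaxation kinetics are outside the
  model's scope.
* The brightness model is linear two-state; dye spectral shifts or
  Mg-sensitivity are not modeled.
* The solved resting free Mg²⁺ (≈117 µM) and the stated 0.15 mM cannot be
  reconciled under the printed ATP binding constants (see above); analyses
  default to the clamped convention.
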