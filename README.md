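# caflux

Estimation of sarcoplasmic-reticulum (SR) Ca²⁺ release fluxes in skeletal
muscle fibers from low-affinity indicator-dye fluorescence, for
electrophysiologists and modelers working on excitation–contraction
coupling. The package covers the full computation chain used in
voltage-/current-clamp dye studies of release — forward buffering model,
kinetic inversion, transient/train/voltage-dependence/confocal analyses —
together with a fully seeded synthetic-data generator, so every stage is
testable without experimental recordings.

## The model in brief

A single myoplasmic compartment with mass-action Ca²⁺/Mg²⁺ buffering by
parvalbumin (900 µM, competitive Ca/Mg), troponin (240 µM), ATP (5 mM, Mg
only), EGTA (30 mM) and the indicator OGB-5N (250 µM):

    d[XB]/dt = kon·[X]·(Btot − [CaB] − [MgB]) − koff·[XB]
    d[Ca]/dt = R(t) − Σ Ca-binding rates        (R: SR release flux, µM/ms)
    d[Mg]/dt = − Σ Mg-binding rates

In the high-EGTA regime removal is entirely by buffering (no pump term),
and a low-affinity, fast dye tracks release closely; the residual kinetic
distortion is inverted exactly:

    ΔF/F = (φ−1)(CaD − CaD_rest) / (Dtot + (φ−1)·CaD_rest)
    [Ca](t) = (dCaD/dt + koff·CaD) / (kon·(Dtot − CaD))
    R(t) = d[Ca]/dt + Σ_B d[CaB]/dt

Voltage dependence is summarized by the increasing Boltzmann
`ΔF/F(V) = ΔF/F_max / (1 + exp((V½ − V)/k))`; transient decays by
`ΔF/F0 + A1·e^(−t/τ1) + A2·e^(−t/τ2)`; trains by peak/inter-pulse envelopes
and their last/first amplitude ratio; confocal line scans by
triad/Z-line/M-line classification at the 2.1-µm sarcomere period.

## Worked example

```r
library(caflux)
params <- default_params()

# forward-simulate a 260 µM/ms, 2-ms FDHM release flux -> fluorescence
flux_in <- make_flux_waveform(
  flux_shape(peak = 260, latency = 2, rise_tau = alpha_rise_for_fdhm(2)),
  duration = 25)
traj <- simulate_forward(params, flux_in)
dfof <- dfof_from_trajectory(traj)
round(max(dfof$values), 3)
#> [1] 0.842

# invert the fluorescence back to flux: the 260 µM/ms peak returns
flux_out <- flux_from_dfof(dfof, params)
round(peak_flux(flux_out), 1)
#> [1] 260

# double-exponential decay fitting (here: the canonical fast/slow decay)
t <- seq(0, 60, by = 0.03)
fit <- fit_double_exponential(
  time_series(0.63 * exp(-t / 1) + 0.04 * exp(-t / 19), dt = 0.03))
round(c(A1 = fit$a1, tau1 = fit$tau1, A2 = fit$a2, tau2 = fit$tau2), 4)
#>     A1   tau1     A2   tau2
#> 0.6300 1.0000 0.0400 19.0000
round(fast_fraction(fit), 3)   # fast component carries ~94% of the decay
#> [1] 0.94

# voltage dependence: synthesize a clamp family, extract peaks, refit
fam <- make_clamp_family(voltage_clamp_protocol(),
                         boltzmann_fit(0.77, 7, 13), boltzmann_fit(0.37, 6, 11))
peaks <- sapply(fam$sweeps, function(s)
  extract_peak_and_steady(s, fam$pulse_window)$peak)
bfit <- fit_boltzmann(fam$truth$v_mV, peaks)
round(c(dfof_max = bfit$dfof_max, v_half = bfit$v_half, k = bfit$k), 4)
#> dfof_max   v_half        k
#>     0.77     7.00    13.00
```

The first two numbers are the round-trip check at the heart of the method:
a 260 µM/ms release produces a ΔF/F transient peaking at 0.842 under the
default dye-brightness ratio, and the kinetic inversion recovers the
260 µM/ms peak. The decay fit returns the generating amplitudes and time
constants exactly on noise-free input, and the Boltzmann refit reproduces
the generating maximum (0.77), midpoint (7 mV) and slope (13 mV).

See the methods vignette (`vignettes/caflux-methods.Rmd`) for the model
assumptions, numerical choices, and what the synthetic generator does and
does not emulate.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch — it regenerates a noise-free voltage-clamp family from the example
peak-release Boltzmann parameters and refits them; refits the canonical
double-exponential decay sampled at 30 µs; and draws seeded samples at the
published peak-flux distribution moments and refits their Gaussian
centers — then writes one JSON object with one numeric value per quantity:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`.
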