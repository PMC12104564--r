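---
title: "Methods: MEA-based analgesic screening on iPSC-derived sensory neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA-based analgesic screening on iPSC-derived sensory neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Inherited erythromelalgia (IEM) is a chronic pain disorder driven by
gain-of-function mutations in *SCN9A*, the gene encoding the voltage-gated
sodium channel Na~V~1.7. Sensory neuron-like cells differentiated from IEM
patient iPSCs fire spontaneously, and that hyperexcitability is a screenable
phenotype: a candidate analgesic should suppress spontaneous firing on a
multiwell microelectrode array (MEA) without killing the cells, its effect
should wash out, and its potency should be confirmable at the single-cell
level by patch clamp.

`meascreen` implements that analysis chain end to end:

1. **Spike detection** (`bandpass()`, `baseline_sd()`, `detect_spikes()`,
   `mean_rate()`, `classify_active()`) turns raw extracellular voltage into
   per-channel firing rates.
2. **Screen statistics and hit calling** (`screen_metrics()`,
   `screen_library()`, `call_hit()`) compare paired before/after rates per
   compound and apply the composite hit criteria with intensity tiering.
3. **Cytotoxicity and reversibility** (`ldh_activity()`, `is_cytotoxic()`,
   `classify_reversibility()`) prune hits that damage cells or bind
   irreversibly.
4. **Concentration-response fitting** (`fit_dose_response()` with
   `hill_activity()` and `boltzmann_inhibition()`) estimates IC50 and slope.
5. **Patch-clamp feature extraction** (`classify_gapfree()`,
   `classify_current_step()`, `spike_parameters()`, `extract_iv()`,
   `ttx_normalised_inhibition()`) characterises single cells and quantifies
   Na~V~ block against the TTX reference.
6. A **synthetic generator** (`simulate_plate()` and friends) reproduces the
   statistical structure of all of these recordings so that every stage is
   testable without instrument data.

`run_pipeline()` chains stages 1-4 plus candidate selection into the
screening funnel and asserts its monotonicity (candidates ⊆ reversible ⊆
non-toxic ⊆ hits) on every run.

## Spike detection

The detector is a two-sided threshold-crossing algorithm on band-passed
voltage. The tunables, all carried by `detector_config()`:

* **Band**: 1-10 kHz, 2nd-order Butterworth applied forwards and backwards
  (zero-phase), so detected spike times are not skewed by filter delay. At
  a 20 kHz sampling rate the nominal 10 kHz upper corner sits exactly at
  Nyquist; it is clipped to 0.45 × the sampling rate with a warning rather
  than silently accepted. Zero-phase IIR filtering leaves transients at the
  trace edges; the detection contract applies to the interior.
* **Threshold**: ±5 × the baseline SD. The SD is estimated as
  1.4826 × the median absolute deviation of the filtered trace — consistent
  for Gaussian noise, and essentially blind to the spikes themselves, which
  a plain SD is not. The estimate uses the whole trace; a sliding window
  adds parameters without changing behaviour on stationary noise.
* **Dead time**: 1 ms pre-trigger lockout plus a 2 ms post-trigger skip.
  Together these guarantee no two detections are closer than 3 ms, an
  invariant asserted on every output. A spike is stamped at its first
  crossing sample, not at the extremum.
* **Active channels**: a channel counts as active only when its mean rate
  *strictly exceeds* 0.33 Hz; a channel at exactly 0.33 Hz is inactive.

## Screen statistics and the composite hit call

For each compound, the channels that were active at baseline form the
paired rate lists (channels silent before compound cannot inform a
suppression call); `n_active` counts them. On those lists:

* **Normalised activity** = 100 × mean(after) / mean(before) — the ratio of
  means, not the mean of per-channel ratios, which would explode on
  channels approaching zero.
* **Paired Wilcoxon p**: exact two-sided signed-rank p, computed from the
  full sign-flip permutation distribution by dynamic programming over
  (mid)ranks. The exact computation matters: count-derived rates tie often,
  and the usual fallback to a normal approximation at small n (12 channels)
  distorts p right where the p < .01 criterion bites.
* **FDR**: Benjamini-Hochberg across the compound library, one p per
  compound. (Correcting across channels instead would conflate the
  per-compound question with plate size.)
* **Robust z′** = (median(after) − median(before)) / pooled raw MAD, with
  root-mean-square pooling of the two unscaled MADs. It is a nonparametric
  analogue of the z-score expressed in MAD units — deliberately *not*
  multiplied by 1.4826, and distinct from the assay-quality z-prime of HTS.
* **Cohen's d**: classical pooled-SD form with the n₁+n₂−2 denominator.

A compound is a **hit** when all of: normalised activity < 50%, FDR p <
.01, |robust z′| > 1.96, |d| > 0.80, and n_active ≥ 9. An optional sixth
criterion — median separation ≥ 2 pooled MADs — is implemented behind
`fig3_mode` and off by default, since the five-criterion rule is the
primary definition and the sixth appears only in the screening-figure
variant. Hits are tiered by the reduction r = 100 − normalised activity:
high (r > 90), moderate (70 < r ≤ 90), low (50 < r ≤ 70); the three
intervals partition the range r > 50.

## Cytotoxicity and washout reversibility

LDH release is read as background-subtracted absorbance (A490 − A680),
normalised linearly between the vehicle and lysis controls of the same
timepoint. A compound is cytotoxic if its activity exceeds 5% of the
positive control at *any* of the 1, 6 and 24 h reads (worst case; the
timepoints are not averaged).

Reversibility is an increase of activity after washout. Percent recovery is
the fraction of the inhibited gap regained,
100 × (washout − post) / (baseline − post), clipped to [0, 100]; the
alternative washout/baseline reading is available behind the `denominator`
argument. A compound that produced no inhibition has no defined recovery
and is flagged rather than scored. Candidates for patch clamp must have a
converged fit with IC50 ≤ 8 µM, recovery ≥ 60%, a reversible
classification and a clean LDH verdict.

## Concentration-response models

Two model forms, fitted by `fit_dose_response()`:

* **MEA mode** (`hill_log`): the two-parameter inhibitory Hill curve on the
  normalised-activity scale, A(c) = 100 / (1 + (c/IC50)^n). Asymptotes are
  fixed at 100 and 0 because screen responses are already
  baseline-normalised; at c = IC50 inhibition is exactly 50%, the defining
  anchor.
* **Patch mode** (`boltzmann_linear`): inhibition fraction
  1 / (1 + exp((IC50 − c)/h)) in *linear* concentration with the slope
  factor h in µM. The linear-concentration form is deliberate: published
  slope factors for these compounds reach 70 µM, far beyond any plausible
  log-domain Hill coefficient, so h carries concentration units. A
  consequence worth knowing: the model has a small nonzero block at c = 0,
  1/(1+exp(IC50/h)), which only vanishes when IC50 ≫ h.

Fitting minimises the sum of squared residuals with `stats::optim`
(Nelder-Mead) on log-parameters, which enforces positivity without bound
constraints. `nls` was rejected because it fails by design on zero-residual
data, and the generate-then-fit identity on noiseless curves is a core
contract here. The optimiser is multi-started from at least five log-spaced
IC50 values spanning the tested range; the lowest SSE wins, ties broken by
the smaller IC50. A fit that improves on the constant-mean model by less
than 1% of SSE is flagged `"no dose dependence"` and reported as
non-converged — the behaviour expected for compounds with no
concentration-effect relationship. R² = 1 − SSE/SST. Replicate points
enter individually, so duplicating every point leaves estimates unchanged.

Follow-up concentration grids are fixed per tier: high 10/8/6/4/2/0 µM,
moderate 12.5/10/7.5/5/2.5/0 µM, low 16.6/13.3/10/6.6/3.3/0 µM, with 0 µM
the vehicle.

## Patch-clamp feature extraction

Events in current-clamp sweeps are found on the rate of rise (dV/dt ≥
10 mV/ms on a 2 ms Savitzky-Golay smooth) rather than on a voltage
threshold, so "attempting" events that never reach 0 mV are still caught.
Gap-free classes: quiet (no events), attempting (events but all peaks
< 0 mV), spontaneous (any peak ≥ 0 mV). Current-step classes additionally
distinguish single responses (1-2 complete spikes at the best step) from
trains (≥ 3 — the count is a committed choice, "train" being otherwise
unquantified).

Spike parameters are measured on a Savitzky-Golay local-polynomial smooth
(order 5). The smooth and first derivative use a 1 ms window; the *third*
derivative — whose peak during the depolarising phase defines threshold —
uses a 3 ms window and a search region anchored within ±1 ms of the dV/dt
onset. Both choices are noise-management: derivative noise gain grows
steeply with order, and an unanchored search lets distant noise excursions
masquerade as the threshold. For a Gaussian spike of width σ the analytic
third-derivative peak sits at −√(3+√6)·σ before the peak, which puts the
threshold slightly above the base; the half-height width measured from that
threshold is 2σ√(2 ln(2/(1+e^{−(3+√6)/2}))) ≈ 2.244σ, about 4.7% below the
raw FWHM 2σ√(2 ln 2). The simulator records both closed forms as ground
truth, and parameter recovery is verified against them to 5%.

Voltage-step I-V extraction measures, relative to the pre-step holding
current: Na~V~ activation as the most negative current in the first 10 ms
of the test step; Na~V~ inactivation as the trough in the probe segment
between the test and recovery steps (the probe-window reading of an
under-specified protocol — a committed interpretation); and K~V~ steady
state as the mean over the final 50 ms of the step. Compound block is
expressed as (I_control − I_compound)/(I_control − I_TTX) at the −35 mV
step, where the Na~V~ current is maximal; values outside [0, 1.05] are
flagged, not clipped. AHP is referenced to threshold (not resting V~m~),
another committed choice where convention varies.

## What the synthetic generator emulates — and what it does not

`simulate_plate()` reproduces the statistical skeleton the analysis relies
on: 24-well × 12-electrode plates (defaults; tests use smaller),
homogeneous Poisson firing per channel with an absolute refractory period
equal to the detector dead time (so ground truth is recoverable), baseline
rates drawn log-normally (median 2 Hz, sdlog 0.5 — an elevated,
IEM-like spontaneous rate; the source data report no numeric rate
distribution, so these are free parameters chosen once as realistic) with
an inactive fraction (default 15%) exercising both sides of the 0.33 Hz
rule, Hill-law rate suppression after compound, linear recovery by
`recovery_fraction` on washout, and spikes rendered as a fixed
negative-leading biphasic template (two 0.25 ms lobes within a 1 ms
support — spectral energy near 2 kHz, inside the detection band, which is
what makes the 8 × noise-SD detectability contract meaningful) in Gaussian
noise. One seed stream is split per channel by stable hashing, so adding
wells never perturbs existing channels and identical seeds give
bit-identical plates.

It does **not** model: conductance-based membrane dynamics, network
bursting, temperature or K⁺ dependence (beyond the rate parameters),
electrode drift, or non-stationary noise. Passing tests therefore
demonstrate that the *analysis* is correct under the stated statistical
assumptions, not that those assumptions exhaust real MEA data.

`simulate_screen_rates()` is the rate-level counterpart (Poisson counts of
the true rates, no waveforms) used for library-scale repeated-seed
properties — e.g. recovery of 4 planted suppressors among 20 compounds in
≥ 95% of 100 seeds — where trace-level simulation would add nothing but
runtime: the property under test is the hit-calling statistics, and the
detector's fidelity is established separately on trace-level plates.

## Problem sizes and numerical choices

The test suite runs trace-level simulation at reduced scale (1-4 wells,
up to 12 electrodes, 5-25 s phases at 20 kHz) — sizes at which every
statistical contract is already decisive — and rate-level simulation at
full scale (300 s, 12-240 channels, 100 seeds). Optimiser tolerance is
`reltol = 1e-14` with up to 2000 Nelder-Mead iterations per start;
generate-then-fit identities hold to 1e-6 relative across IC50 ∈
[0.5, 200] µM for both model forms. Percent tallies round half-up to whole
percents (`tally_classes()`), matching how cohort shares are conventionally
printed. Degenerate inputs are handled explicitly: zero baseline SD
disables detection with a warning; zero pooled MAD/SD yields a signed
infinity (flagged) or 0 per the medians/means; an all-zero difference
vector gives p = 1; a flat concentration-response is flagged rather than
fitted.

## Known limitations

* The MEA-side IC50 table of the original screen is not reproducible here
  (it depends on unavailable raw recordings); the concentration-response
  machinery is instead validated by parameter recovery on synthetic data
  and by the published patch-clamp Boltzmann parameters.
* The washout model is a linear interpolation by `recovery_fraction`;
  real recovery kinetics are richer.
* No spike sorting: channels are treated as multi-unit activity, as in the
  screen itself.
* The Na~V~ inactivation measurement follows the probe-window reading of
  the protocol; other pre-pulse structures would need a different window
  definition.
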