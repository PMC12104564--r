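# meascreen

Phenotypic analgesic screening analysis for multiwell microelectrode-array
(MEA) recordings of iPSC-derived sensory neuron-like cells.

Sensory neurons derived from patients with inherited erythromelalgia (IEM,
a chronic pain disorder caused by gain-of-function *SCN9A*/Na<sub>V</sub>1.7
mutations) fire spontaneously. That hyperexcitability is a screenable
phenotype: an analgesic candidate should suppress spontaneous firing,
without cytotoxicity, reversibly on washout, and with a concentration
response confirmable by patch clamp. `meascreen` implements the full
analysis chain for such a screen, plus a synthetic data generator that
emulates the recordings so every stage is testable without instrument data.

## What it computes

**Spike detection.** Raw voltage (µV, 20 kHz) is band-passed 1-10 kHz
(zero-phase Butterworth) and spikes are detected at ±5 robust baseline SDs
(1.4826 × MAD) with a 1 ms pre- / 2 ms post-trigger dead time. Channels are
*active* when their mean rate exceeds 0.33 Hz.

**Hit calling.** Per compound, paired before/after rates on baseline-active
channels give: normalised activity `100·mean(after)/mean(before)`, an exact
paired Wilcoxon signed-rank p (Benjamini–Hochberg corrected across the
library), the robust effect size

    z' = (median(after) − median(before)) / sqrt((MAD_b² + MAD_a²)/2),

and Cohen's *d*. A hit requires normalised activity < 50%, FDR p < .01,
|z'| > 1.96, |d| > 0.80 and ≥ 9 active channels; hits are tiered by
reduction (high > 90%, moderate 70–90%, low 50–70%).

**Filtering.** LDH cytotoxicity (background-subtracted A490−A680,
normalised between vehicle and lysis controls; toxic if > 5% of positive
control at 1, 6 or 24 h) and washout reversibility (percent recovery =
fraction of the inhibited gap regained) prune hits; candidates need
IC50 ≤ 8 µM and recovery ≥ 60%.

**Concentration response.** Inhibitory Hill on % activity,
`A(c) = 100/(1 + (c/IC50)^n)`, for MEA data; linear-concentration Boltzmann
inhibition `1/(1 + exp((IC50 − c)/h))` for TTX-normalised patch-clamp block
(ΔI/ΔI<sub>TTX</sub>). Multi-start least squares, R², and a
"no dose dependence" flag.

**Patch clamp.** Gap-free and current-step activity classes, AP parameters
(threshold from the third-derivative peak, half-height width, dV/dt
extrema, AHP), Na<sub>V</sub>/K<sub>V</sub> I–V extraction from voltage-step
families, and TTX-normalised inhibition at the −35 mV step.

## Worked example

Simulate a 3-compound plate (a clean suppressor, a cytotoxic suppressor,
an inert compound) and run the full funnel:

```r
library(meascreen)

truths <- list(
  AZA = compound_truth("AZA", ic50_true = 2, hill_n_true = 3),
  AZB = compound_truth("AZB", ic50_true = 2, hill_n_true = 3, toxic = TRUE),
  AZC = compound_truth("AZC", ic50_true = 1e6, hill_n_true = 1))
spec <- plate_spec(n_wells = 3, n_electrodes = 12, duration = 10,
                   seed = 42, active_fraction = 1)
exposures <- data.frame(well = 1:3, compound_id = names(truths),
                        concentration = 10)
plate <- simulate_plate(spec, exposures, truths)

out <- run_pipeline(plate, cfg = detector_config(band_high = 9000), seed = 1)
print(out)
```

```
Screening funnel:
  compounds screened       3
  composite hits           2
  non-toxic hits           1
  reversible               1
  converged CR fits        1
  patch-clamp candidates   1
  candidates: AZA
```

Both suppressors are called hits (the inert compound fails every effect
criterion); the cytotoxic one is removed by the LDH stage, leaving one
candidate:

```r
out$screen[, c("compound_id", "normalised_activity", "p_fdr", "robust_z",
               "cohen_d", "n_active", "is_hit", "tier")]
```

```
  compound_id normalised_activity    p_fdr robust_z cohen_d n_active is_hit tier
1         AZA               1.739 0.000732   -4.243  -2.442       12   TRUE high
2         AZB               0.383 0.000732   -4.360  -3.054       12   TRUE high
3         AZC             108.980 0.320312    0.305   0.183       12  FALSE none
```

AZA reduced firing to 1.7% of baseline (a high-intensity hit), and its
tier-matched concentration-response fit recovers the generating
pharmacology (true IC50 2 µM, Hill n 3):

```r
out$fits$AZA
```

```
Concentration-response fit: inhibitory Hill (log-concentration)
  IC50  = 2.003 uM
  slope = 3.013
  R^2   = 0.9998   (SSE 3.569, 18 points)
```

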