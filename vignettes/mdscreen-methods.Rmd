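---
title: "Multidimensional suspect screening: model, calibration and design"
author: "mdscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional suspect screening: model, calibration and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscreen)
```

## The screening model

Suspect screening asks, for every measured feature and every compound on a
curated suspect list, how consistent the measurement is with that
compound. GC-APCI preserves the (quasi-)molecular ion of hydrophobic
organic contaminants, so four dimensions of evidence are available per
candidate pairing: the MS¹ spectrum (exact mass and isotope pattern of
M⁺˙ or [M+H]⁺), the retention time, the ion-mobility collision cross
section, and the MS² fragmentation spectrum. `mdscreen` treats the MS¹
evidence as a hard gate and the remaining three dimensions as continuous
scores fused into a single ranked quantity.

### MS¹ gates

Both gates are mandatory; a candidate failing either never enters the
scored set.

* **Exact mass.** The error between measured and theoretical adduct *m/z*
  must be below 5 ppm for ions at or above 200 Da and below 2 mDa for
  lighter ions. Both comparisons are strict. At exactly 200 Da the ppm
  rule applies: the two rules cross there (5 ppm × 200 Da = 1 mDa), so the
  ppm reading is the conservative choice. Adduct masses carry the electron
  mass explicitly (M⁺˙ = neutral − mₑ; [M+H]⁺ = neutral + 1.00727646 Da);
  at a 2 mDa gate the ~0.55 mDa electron term is not negligible.
* **Isotope pattern.** Theoretical isotopologue distributions are computed
  by per-element multinomial expansion convolved across elements, then
  aggregated into nominal-mass centroids (intensity-weighted mean mass),
  mirroring the centroided envelopes instruments report — ¹³C₂ and ³⁷Cl
  isotopologues collapse into one M+2 peak. Measured envelope peaks are
  paired to theoretical isotopologues by nearest *m/z* within the active
  mass tolerance. At least one non-base isotope ion must match, and the
  geometric mean of the per-isotope relative intensity deviations
  (|measured − theoretical| / theoretical × 100) must be strictly below
  5 %. All matched isotopologues enter the geometric mean; unmatched
  theoretical peaks beyond the required minimum are ignored rather than
  penalized, since weak isotopologues routinely fall below instrument
  detection. Compounds built entirely from single-isotope elements have a
  one-peak pattern; the gate then passes vacuously and the bypass is
  flagged on the candidate.

### Continuous RT and CCS scores

For a signed deviation Δ (measured − reference) and a high/low confidence
threshold pair with the high interval strictly inside the low one, the
score is 1 inside the high interval, 0 at or beyond the low boundary (the
candidate is excluded from the match), and decays linearly from 1 to 0
between the high and low boundaries on the side of the deviation. The
linear segment is the simplest shape consistent with the fixed endpoints;
`continuousScore()` exposes a `shape` hook so a steeper (e.g. quadratic)
decay can be substituted without touching the endpoints.

Thresholds are calibrated per reference source:

| dimension | source | CT_high | CT_low | rationale |
|---|---|---|---|---|
| CCS | literature | ±2 % | ±3 % | interlaboratory CCS reproducibility |
| CCS | predicted | ±5 % | ±7 % | prediction error for halogenated HOCs, kept below the smallest observed isomer CCS separation |
| RT | literature-converted | 0.15 ± 0.69 min | 0.15 ± 1.38 min | mean ± SD / mean ± 2 SD of conversion residuals (n = 36) |
| RT | predicted | 0.086 ± 1.13 min | 0.086 ± 2.26 min | residuals of the RI-prediction route (n = 102) |

The RT intervals are deliberately asymmetric: the calibration rule is mean
± SD, and the systematic bias of a reference source is information, not
noise. `calibrateRtThresholds()` re-derives intervals from any residual
set (≥ 3 values; a zero-spread set degenerates to a point and warns).
For references measured on the same system no separate calibration is
stated; the package assigns them the literature-converted intervals, the
tighter of the two published pairs, since in-house measured references
cannot be worse than converted literature values.

### MS² and fusion

MS² similarity is computed externally (structure-aware fragmentation
scorers are mature, heavyweight tools); the package's contract is file
based — `exportFragmentationInput()` writes the block-text record
(`>compound`, `>formula`, `>ionization`, `>parentmass`, `>ms2` peaks)
declaring the candidate's identity, and `readMs2Scores()` ingests the
resulting score table, rejecting (never clamping) scores outside [0, 1].
A score only counts when the feature carries at least two monoisotopic
fragments.

The multidimensional score is the weighted sum
W_RT·S_RT + W_CCS·S_CCS + W_MS2·S_MS2 with defaults (0.2, 0.4, 0.4): RT
depends on chromatographic conditions and gets the smallest weight. A
missing MS² score contributes 0 **without renormalizing the weights**.
This is a deliberate interlock with the 60 % retention cutoff: 0.2 + 0.4
is exactly the cutoff, so a candidate without MS² evidence is retained
only when RT and CCS are both perfect. Candidates at or above the cutoff
are flagged, and per suspect only the highest-scoring one is retained.
Ranking and retention tie-break deterministically: score, then smaller
|ΔCCS|, then smaller |ppm error|, then suspect id.

Stage-wise hit counts mirror the four workflow stages (MS¹+RT; +CCS;
above cutoff; best retained) and are non-increasing by construction.

## Numerical choices

* All threshold comparisons ("< 5 ppm", "< 5 %") are strict inequalities,
  matching their stated form; the score at exactly a low boundary is 0 and
  such candidates are treated as excluded.
* Retention uses `score ≥ cutoff − 10⁻⁹`: with IEEE doubles
  0.2 + 0.4 evaluates slightly above 0.6, and the epsilon makes the
  "perfect RT and CCS without MS² is retained" identity robust rather than
  dependent on summation order.
* A geometric mean over deviations containing an exact 0 is 0 (the log-sum
  is taken only when all deviations are positive).
* Candidate generation uses a ±0.02 Da sorted-window join before the exact
  gate, so screening cost scales with plausible pairs rather than the full
  feature × library product.
* `riToRt()` interpolates piecewise-linearly between anchors and
  extrapolates the terminal segments, flagging extrapolated values; the
  Kovats→Fiehn map is a single global least-squares line (both scales are
  near-affine in elution temperature over the working range), kept
  separate from the anchor table so either can be replaced.
* Isotope patterns default to pruning below 1 % relative intensity and at
  most 8 peaks, matching what centroided envelopes of halogen-rich ions
  realistically expose.

## The synthetic bench

`simulateDataset()` generates the study conditions the screening claims
are tested under: a library of unique random halogen-rich formulas
(C₆–C₂₄, up to Cl₆Br₃, valence-plausible H counts, at least one halogen),
retention times uniform over a 5–35 min window, CCS values following a
power law in ion mass with 5 % compound-to-compound scatter, and planted
features with Gaussian noise at the observed dispersions: RT SD 0.69 min
around the +0.15 min conversion bias, CCS SD 2 % (interlaboratory
reproducibility), 1 ppm mass noise, 2 % isotope intensity noise. MS²
similarity is simulated directly as truncated-Gaussian scores —
0.724 ± 0.180 for true pairings (the observed mean for known HOC
standards), and 0.5 ± 0.2 for decoy pairings, a value chosen once as
realistic for isomeric decoys (an isomer shares the formula, so a
structure-aware scorer degrades but does not collapse); 20 % of planted
features lack usable MS². Isomeric decoys replicate a planted suspect's
formula with CCS shifted by 3–5 % and RT by 0.5–2 min, emulating the
isomer confusion that dominates real false positives.

What the bench does **not** emulate: matrix chemical noise and co-eluting
interferents, in-source fragmentation, detector saturation, RT/CCS drift
within a run, and real fragmentation spectra. Passing the bench therefore
demonstrates the correctness and calibration of the scoring logic under
controlled dispersion — not instrument-level performance on sediment
extracts.

`evaluateScreening()` scores a result against the planted truth: the true
positive rate is computed over retained best-candidates, and false
positives are split into isomer-level (same formula as the planted
compound) versus other.

## Problem sizes and test design

The test suite checks the isotope convolution against an independent
exhaustive isotopologue enumeration for all ~500 formulas over {C, H, Cl,
Br} with ≤ 8 atoms (agreement within 10⁻⁶ relative intensity); runs the
parameter-recovery property (200 suspects, noise SDs at half the
high-confidence thresholds, 20 seeds, expecting a true positive rate of
exactly 1 in every replicate); runs the isomer-decoy property (decoy rate
0.3, noise at the calibrated dispersions, 20 seeds, expecting zero non-isomer false
positives); and verifies monotonicity (score decay, fusion, stage counts)
and lossless round-trips of every interchange format (feature tables,
libraries, MSP, ground truth, YAML config). These sizes keep the full
suite under two minutes on one core while giving the stochastic
properties enough replicates to be meaningful.

## Known limitations

* Charge states above 1, fine isotopic structure and in-source
  fragmentation are out of scope; the adduct set is M⁺˙, [M+H]⁺, [M−H]⁻.
* One reference CCS per compound: CCS differences between adduct forms of
  the same compound are assumed to fall within measurement uncertainty,
  so the CCS score ignores which adduct matched.
* Duplicate library compounds are resolved by exact InChIKey match only
  (first occurrence kept).
* The Kovats→Fiehn map is global-linear; strongly curved index
  relationships would need a segmented map supplied by the user.
* The bench's decoy MS² score distribution is an assumption; conclusions
  about MS²'s marginal contribution should be read against it.
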