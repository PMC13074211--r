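---
title: "Single-marker quantitation of Sichuan pepper alkylamides: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantitation of Sichuan pepper alkylamides: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qams)
```

## The analytical problem

The numbing taste of Sichuan pepper (*Zanthoxylum*) comes from unsaturated
alkylamides — the hydroxy-sanshools HαSS, HβSS, HγSS and HεSS (labelled
`HaSS`, `HbSS`, `HgSS`, `HeSS` in this package). Quantifying them by HPLC is
routine in principle but painful in practice: the sanshool reference
standards are expensive and oxidize in air, so every calibration depends on
compounds that degrade on the shelf.

The single-marker strategy (QAMS, *Quantitative Analysis of Multi-components
by a Single Marker*) sidesteps this by calibrating **one** stable, cheap
reference compound — here Nonivamide, a synthetic capsaicin analogue — and
quantifying every other analyte through a fixed response ratio. This package
implements that workflow end to end, together with a seeded chromatogram
simulator so that every stage is testable without instrument data.

## The model

Detector response per analyte is linear in on-column mass,
$A_i = s_i m_i + b_i$, with a per-wavelength relative response multiplier
(two working channels, 270 nm and 285 nm, behave as two detectors). Three
quantities drive the method:

* **Relative correction factor (RCF).** For internal reference $s$ and
  analyte $i$,
  $$f_{is} = \frac{A_s\,C_i}{A_i\,C_s},$$
  measured once from a mixed standard. Any gain common to all peaks of a
  run — detector sensitivity, injection error, concentration level — cancels
  in the ratio, which is why $f$ is durable across instruments, columns,
  flow rates, temperatures and injection volumes.
* **Single-marker quantitation.** Unknowns are then
  $$C_i = f_{is}\, C_s\, \frac{A_i}{A_s},$$
  requiring only the reference compound's standard solution. This is the
  exact algebraic inverse of the RCF definition, a property the test suite
  checks over thousands of random tuples.
* **Relative retention time (RRT).** Peaks are identified by
  $\mathrm{RRT} = t_{R,i}/t_{R,s}$, invariant under common retention
  rescaling (e.g. flow changes), with assignment to the nearest expected
  RRT within a ±5% relative tolerance.

Contents in the original sample follow
$W_i = C_i V K / M_m$ (extract volume $V$, dilution $K$, sample mass
$M_m$; defaults 25 mL, 1, 0.025 g). Method equivalence between the
external-standard method (ESM) and QAMS is judged by the standardized mean
difference
$$\mathrm{SMD\%} = \frac{|W_\mathrm{ref} - W_\mathrm{alt}|}{W_\mathrm{ref}}
\times 100,$$
accepted when strictly below 5%. The denominator is the reference method:
the statistic is deliberately asymmetric, and the tests pin that down so
nobody "fixes" it.

## Units and the calibration abscissa

Areas are mAU·s, times minutes, on-column masses µg, extract concentrations
µg/mL, contents mg/g. The shipped calibration lines (e.g.
$Y = 1.78\times10^7 X - 8686.99$ for HαSS) are expressed against *injected
concentration* (µg/mL) at the 10 µL reference injection; the package's
canonical mass-abscissa response slopes divide by 0.01 mL. This reading
keeps the printed intercepts below ~0.3% of any in-range peak area, which is
a precondition for QAMS (which carries no intercept) agreeing with ESM at
the bottom of the working ranges. RCFs depend only on slope ratios and are
unaffected by the convention.

## What the simulator emulates

`simulate_chromatogram()` builds traces as exponentially modified Gaussian
peaks (τ = 0, i.e. pure Gaussian, by default — peak shape is a free choice
here) on a linear drift plus seeded white noise, 50 min at 20 points/min by
default to match the reference gradient window. Condition changes are
simple parametric transforms: retention scales with inverse flow and shifts
−0.05 min/°C; areas scale with injection volume and channel factor;
instrument/column swaps apply a configured retention factor and a *shared*
area gain. Sharing the gain across co-injected analytes is precisely the
mechanism that makes RCFs durable, and the durability grid tests exercise
it.

Two deliberate calibration choices:

* **Channel factors.** The published constants — calibration slopes, the
  HαSS-referenced RCFs {1.6310, 1.5180, 1.4285} at 270 nm, and the
  Nonivamide-referenced RCFs {0.0513, 0.1321, 0.0566, 0.0571} at 285 nm —
  cannot all arise from one linear detector. The defaults in
  `channel_factors()` therefore calibrate per-analyte relative responses so
  the simulated instrument reproduces **both** published RCF sets on their
  respective channels (sanshools stay of order 1; Nonivamide's response
  roughly doubles from 270 to 285 nm, consistent with its red-shifted
  absorption maximum). Users reconciling their own instrument can override
  the map on any `response_model`.
* **Noise floor.** The default baseline noise is set so the synthetic HαSS
  channel's detection limit sits at 0.068 ng on column, the reported scale
  for that compound; `noise_spec(area_rsd = )` additionally provides
  constant-RSD multiplicative area noise (1% by default) for peak-table
  level simulation.

The simulator does **not** model gradient elution chemistry, full PDA
spectra, co-elution/deconvolution, extraction kinetics, or real detector
drift structure. Passing tests therefore demonstrate internal consistency
of the analysis chain under a faithful but idealized noise model — not
instrument-level validation.

## Numerical and statistical choices

* **Detection limits.** LOD and LOQ use the pharmacopoeial convention
  (peak height = 3× and 10× baseline noise), so LOQ/LOD = 10/3 exactly.
  The source material assigns the ratios the other way around while its own
  table prints LOQ = 3×LOD; neither is reproduced exactly, and the shipped
  LOD/LOQ values are carried as constants, not asserted.
* **Baseline.** Windowed low-quantile anchors joined piecewise-linearly,
  with an iterative pass that drops anchors sitting above the interpolation
  of their neighbours (otherwise a peak wider than one window drags the
  baseline up). Noise is estimated as 1.4826×MAD of peak-free residuals,
  and the baseline is re-centred so those residuals have zero median.
* **Integration.** Trapezoidal over baseline-corrected signal, bounds at
  0.1% of apex height or at a valley; areas clamp at ≥ 0. Noiseless
  isolated peaks integrate to spec within 0.5% at the default sampling.
* **Calibration weighting.** `fit_calibration()` is unweighted by default.
  Under constant-RSD (multiplicative) area noise, however, unweighted OLS
  concentrates variance in the intercept (of order the noise at the top
  calibration level), which visibly biases external-standard results at the
  bottom of a range spanning decades. The pipeline therefore fits with
  `"1/x2"` weights — the variance-matched estimator for that noise model.
* **Ties and degenerate inputs.** RRT assignment resolves competing claims
  globally by smallest |RRT − expected|; losers are reported missing, never
  silently reassigned. Rank-deficient calibration designs, inverted
  integration bounds, non-positive flows/masses and a missing internal
  reference are errors; an empty peak list from a blank trace is not.
* **Internal-reference location.** Strategies: `nearest-time`,
  `tallest-peak`, `labeled`, and `external-time`. The last exists because
  Nonivamide is not a pepper constituent: sample runs under the
  Nonivamide preset carry no IR peak, and the reference retention time
  comes from the separate standard injection instead. The IR's own content
  is quantified with $f = 1$ against that standard run.
* **Seeds.** Every stochastic entry point takes a `noise_spec` seed
  (default 20240101); replicates and levels derive child seeds by fixed
  offsets. Identical inputs and seed give bit-identical traces.

## The simulated batch study

`simulate_method_comparison()` reproduces the design of the field
experiment at desk scale: 28 samples × 4 sanshools with true contents drawn
uniformly within the reported field ranges (HαSS 11.20–45.01, HβSS
0.34–11.51, HεSS 0.25–2.48, HγSS 0.27–10.00 mg/g), 3 replicate injections
per sample on each channel with 1% area RSD, ESM via a 6-level standard
series on the 270 nm channel, and QAMS under both IR presets with 3
averaged standard injections each. `simulate_rcf_durability()` runs a
16-condition grid (4 flow rates × 4 temperatures) with a 5%-RSD shared
per-run gain and 1% independent area noise. These sizes run in seconds and
are the ones used by the test suite and the acceptance script; the study's
headline numbers (maximum SMDs, durability RSDs) are computed there, not
quoted here.

## Known limitations

* The RRT presets are published means from real instruments and differ by
  2–4% from the ratios of the integer-minute nominal retention times; they
  are configuration, not ground truth, and the ±5% assignment tolerance
  absorbs the gap.
* The Nonivamide-referenced RCFs are not derivable from the calibration
  slopes alone (the two experiments sit on different channels); the package
  encodes the reconciliation in the channel factors rather than asserting
  slope-ratio equality for Nonivamide.
* Fused peaks are split at valleys; there is no deconvolution, so heavily
  overlapped systems will bias areas.
* `compare_methods()` averages replicates before the SMD (with
  per-replicate SMDs also reported), and emits both per-analyte and
  summed-total comparisons, since the original acceptance rule does not say
  which aggregation was used.
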