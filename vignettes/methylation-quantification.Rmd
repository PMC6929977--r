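---
title: "Quantifying gene methylation from PCR-SERS spectra: models and methods"
author: "methylSERS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene methylation from PCR-SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylSERS)
```

## The measurement model

Sodium bisulfite deaminates unmethylated cytosine to uracil, which PCR reads
as thymine; 5-methylcytosine (and 5-hydroxymethylcytosine) at CpG sites is
protected. After amplification with methylation-independent primers, the
only sequence difference between molecules that were methylated and those
that were not is at the CpG cytosines: a methylated CpG leaves one extra C:G
base pair in the product duplex. For an amplicon of length $L$ with
$n_\mathrm{CpG}$ CpG sites and $N_0$ C:G base pairs in the fully
unmethylated converted duplex, the CG base-pair fraction at population
methylation level $m$ is exactly linear:

$$ f(m) = \frac{N_0 + m\, n_\mathrm{CpG}}{L},
   \qquad m = \frac{f - f_0}{f_{100} - f_0}. $$

`calibrationFromSequence()` computes $L$, $n_\mathrm{CpG}$ and $N_0$ from an
amplicon sequence by simulating the conversion of the top strand
(`bisulfiteConvert()`) and counting C/G positions in the converted strand —
each such position is one C:G pair of the product duplex.
`calibrationFromConstants()` instead reconstructs the integer $N_0$ from a
published CG percentage at either endpoint, which is how the three study
genes ship with the package:

```{r}
calibrationTable(studyCalibrations())
```

Three modelling commitments are worth making explicit. Conversion is
modelled on the top strand only: methylation-independent primers select one
converted strand, and the duplex CG fraction equals the C+G content of that
strand. Hemimethylation is not modelled; a population level $m$ is realized
as a mixture of fully methylated and fully unmethylated molecules, which is
how verification standards are actually prepared, and bulk spectroscopy only
sees the average. And levels are deliberately *not* clipped to $[0,1]$:
noise can push an estimate slightly negative, and the downstream 5% state
rule explicitly treats negative levels as unmethylated, so clipping would
only hide information.

Inverting the calibration amplifies spectral error by
$L/n_\mathrm{CpG}$ (about 13x for p16, 8x for MGMT, 11x for RASSF1), which
is why the preprocessing and unmixing conventions below matter more than
they might appear to.

## SERS spectra of PCR products

Spectra of dsCG and dsAT oligonucleotide duplexes share a set of backbone
and ring-vibration bands between 644 and 1636 cm$^{-1}$; several bands are
unique to one duplex (644, 1354, 1550 cm$^{-1}$ for C:G; 684, 734, 1336,
1575 cm$^{-1}$ for A:T). Because every base pair of the product contributes
to the scattered field independently to first order, the spectrum of a PCR
product with CG fraction $f$ is, up to instrument effects,

$$ S(\nu) = f\, S_\mathrm{CG}(\nu) + (1 - f)\, S_\mathrm{AT}(\nu). $$

Ordinary least squares of a measured product spectrum on the two measured
reference spectra over the whole grid (`mlrDeconvolve()`) recovers
coefficients $(c_\mathrm{CG}, c_\mathrm{AT})$, and

$$ \hat f = \frac{c_\mathrm{CG}}{c_\mathrm{CG} + c_\mathrm{AT}} $$

(`cgFractionFromCoefficients()`). Renormalizing the coefficients rather
than reading $c_\mathrm{CG}$ directly is the only scale-invariant
convention: every normalization choice made earlier in the chain multiplies
both coefficients equally and cancels. The fit is unconstrained — a noisy
spectrum of an unmethylated sample can legitimately produce
$\hat f < f_0$ and hence a negative level — and the intercept is off by
default because baseline correction precedes the fit; both are flags on
`mlrDeconvolve()` for robustness work. Near-collinear reference pairs
(condition number above $10^8$) are rejected rather than fitted, since the
coefficient split is then meaningless.

## Preprocessing: parameters and the reasoning behind the defaults

`preprocess()` applies, in order, Savitzky–Golay smoothing, asymmetric
least squares (AsLS) baseline subtraction, and normalization. All
parameters are user-facing in `preprocessingConfig()`.

* **Smoothing**: SG window 11 points, order 3 on the default 1 cm$^{-1}$
  grid. SG is the standard Raman choice because it preserves polynomial
  band shapes up to its order (the suite tests this identity directly) and
  so distorts 12 cm$^{-1}$-wide bands negligibly; an 11-point window
  suppresses shot noise without merging the 1336/1354 cm$^{-1}$ pair.
* **Baseline**: AsLS with asymmetry $p = 0.01$ and 10 reweighting
  iterations, penalty $\lambda = 10^7$. The asymmetry makes the Whittaker
  smoother hug the lower envelope, ignoring peaks. The penalty deserves a
  note: with the dense DNA band set, overlapping Lorentzian tails hold the
  inter-peak floor at 5–10% of peak height. A soft baseline
  ($\lambda \le 10^5$) climbs into that floor, and because AsLS is
  nonlinear it cuts mixtures and references differently, biasing the
  composition estimate by up to 0.15 in level — far beyond the noise
  floor. At $\lambda = 10^7$ the baseline is stiff over the 1101-point
  grid, still absorbs smooth fluorescence-like drift, and the residual
  peak-area loss (~5–7% of band height) cancels between samples and
  references, leaving level errors at the few-percent scale. Consequently
  a small, consistent bite out of every band is acceptable; a
  composition-dependent bite is not.
* **Normalization**: divide by the maximum intensity (unit-area optional).
  The choice genuinely does not matter for quantification — the
  renormalized coefficient ratio removes it — so the default is what makes
  overlaid plots comparable.

## The synthetic instrument

`makeReferenceSpectrum()` / `makeProductSpectrum()` stand in for the Raman
spectrometer. The signal model is a sum of Lorentzian lines (the natural
Raman line shape), FWHM 12 cm$^{-1}$, at the sixteen catalogued band
positions; unique bands carry amplitude on one channel only, shared bands
on both (the two bands with conflicting attributions in the source
material, 1024 and 1098 cm$^{-1}$, are kept shared; the peak table is an
ordinary data frame and fully configurable). Band height ratios are not
identifiable from published material — they cancel in
deconvolution-with-references — so unique bands default to height 1.0 and
shared bands to 0.7.

Instrument effects, applied in this order, are the three dominant
variability modes of a colloid-substrate SERS measurement:

1. a per-spectrum lognormal intensity scale (geometric sd
   $e^{0.05}$) — substrate batch and focus;
2. a random positive quadratic baseline, amplitude 5% of the maximum peak —
   residual fluorescence and colloid background;
3. additive white Gaussian noise, sd 1% of the maximum peak — detector
   noise.

Every generated spectrum is a pure function of its configuration and seed.
The generator does **not** emulate wavenumber miscalibration, cosmic-ray
spikes, peak-position shifts from adsorption geometry, or
composition-dependent enhancement; passing verification tests therefore
demonstrate correctness of the computational chain under the stated noise
model, not robustness to every instrumental pathology of real SERS.

`simulateVerificationSet()` reproduces the verification design: for each of
the three gene calibrations, products at methylation levels
0/1/5/25/50/75/100% in triplicate (63 spectra), each replicate with its own
noise draw. On this simulation the full pipeline recovers levels with a
worst replicate-averaged deviation of ~0.03 at the default noise
(the suite asserts $\le 0.06$), and is exact to $10^{-6}$ in the noiseless
limit.

## Simulated cohorts

`simulateCohort()` generates subject-level records emulating a case-control
plasma study: 48 cancer and 51 control subjects, clinical categoricals drawn
from the published marginal frequencies (gender, age band, pack-years band;
stage and histology for cases only). Per-gene methylation levels follow a
zero-inflated truncated normal: a gene is methylated with probability $\pi$
(0.5 per gene in cases, 0.041 in controls — chosen once so that the
independent three-gene union $1-(1-\pi)^3$ hits the observed any-gene
frequencies of 87.5% and 11.8%), and methylated genes draw a level from a
normal truncated to $[0.05, 1]$ (case mean 0.11, sd 0.06; control mean 0.08,
sd 0.03 — putting the group mean-level gap near 5 percentage points).
Configurable clinical effects shift the p16 positive-component mean with
smoking band and histology and shift the RASSF1 methylation probability
with stage, mirroring the qualitative associations the assay is meant to
detect. Genes are sampled independently; real co-methylation correlation
structure is not modelled, so multi-gene classifier performance on the
simulation should be read as a pipeline check, not a clinical claim.

## Evaluation statistics

* **Bland–Altman** (`blandAltman()`): differences are estimate − truth;
  limits are mean ± 1.96 sd.
* **ROC** (`rocYouden()`): thresholds are midpoints between distinct scores
  plus ±∞ sentinels, positive call at score ≥ threshold, optimum maximizes
  Youden's $J$, ties resolved toward the lower threshold (higher
  sensitivity) — the convention that favours rule-in sensitivity when two
  cutoffs are statistically indistinguishable. AUC is trapezoidal.
* **CART** (`cartFit()`): classical greedy Gini partitioning; candidate
  cuts at midpoints of distinct values; stop at purity, depth 3, or leaves
  below 5 samples (the scale of tree published for this assay); leaf ties
  go to the globally more frequent class, then lexicographic order; split
  ties keep the earliest feature then lowest cut, making trees fully
  deterministic. Reported tree accuracy is apparent (training-set)
  accuracy, matching how such trees are usually reported at $n \approx
  100$; it is flagged as such in the report.
* **Fisher's exact test** (`fisherExact()`): the standard sum of
  no-more-probable tables under the fixed-margins hypergeometric null,
  delegated to `stats::fisher.test()` after validation; the package adds
  the input contracts and an explicit enumeration budget (total ≤ 200,
  ≤ 12 categories) so callers are told to bin instead of silently
  approximating. Continuous levels enter contingency tests twice, as
  5%-threshold states and as tertile bins, and `cohortReport()` labels the
  two p-value families explicitly — conflating them is a known source of
  ambiguity in published tables.

## Numerical choices and degenerate inputs

Integer $N_0$ reconstruction from printed percentages tolerates 0.05 bp of
rounding slack (printed values carry two decimals; the three study genes
land within 0.005 bp). Amplicons without CpG sites are rejected as
degenerate calibrations (zero slope). Spectrum grids must be strictly
increasing with at least 16 points; resampling is linear and refuses
extrapolation. The unmixing $R^2$ is uncentered when fitted without an
intercept. State calling is a closed half-line: level ≥ 5% is methylated,
anything below — including negative estimates — is not.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
the study's own scale: 63-spectrum verification sets on 1101-point grids,
99-subject cohorts, and oracle comparisons at 20–200 random instances per
property. A full suite run takes well under a minute on one core.

## Known limitations

Single-gene spectra only (the two-reference design cannot unmix a
multiplexed product); no modelling of incomplete bisulfite conversion or
primer bias; 5mC and 5hmC are indistinguishable (both survive conversion);
the synthetic cohort's independence and distributional assumptions are
design choices, not estimates from patient data.
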