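---
title: "Methods: two-stage DRS analysis of oral mucosa spectra"
author: "mucospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage DRS analysis of oral mucosa spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucospec)
```

## The measurement and the problem

Diffuse reflectance spectroscopy (DRS) records the intensity of broadband
light backscattered from tissue as a function of wavelength. In the oral
mucosa, hyperkeratosis and other potentially premalignant changes alter the
spectrum in two regions: 400–600 nm, where hemoglobin and water absorption
and tissue fluorescence change with microvascularization, and 800–1000 nm,
where the growth of the keratinized layer changes the scattering
properties. `mucospec` implements the full analysis chain from repeated raw
spectra per anatomical site to diagnostic accuracy estimates, in two
stages: a pooled (cross-patient) benchmark and a patient-individual
difference-spectrum procedure.

Each site contributes a *series* of 15–30 repeated measurements
$I(\lambda)$ on an analysis grid of 360–1000 nm at 1 nm pitch (all input is
linearly resampled onto this grid on load; the pitch is a package choice —
spectrometer exports vary, and 1 nm is finer than the spectral features of
interest, so resampling error is negligible; extrapolation is never
performed).

## Stage 1: pooled analysis

**Source normalization.** Every measurement is divided elementwise by the
mean spectrum of the light source measured with the same probe,
$I_n(\lambda) = I(\lambda) / \bar I_{source}(\lambda)$, giving
dimensionless relative units (r.u.) that do not depend on the lamp profile.
The divisor is the *mean raw* source spectrum: that is the only convention
that makes $I_n$ dimensionless and instrument-independent. Wavelengths where
the source falls below $10^{-6}$ of its maximum (roll-off at the range
edges) are masked from the grid rather than amplified.

**Averaging and confidence band.** Per site the series is averaged and a
two-sided Student-t band attached,
$\bar I(\lambda) \pm t_{1-\alpha/2,\,n-1}\, s(\lambda)/\sqrt{n}$, with
$s$ the $n-1$ sample standard deviation and $\alpha = 0.05$ by default. A
Monte-Carlo test verifies nominal 93–97 % coverage at $n = 20$. The
companion repeatability measure is the normalized RMS
$s(\lambda)/\bar I(\lambda)$ (a coefficient of variation), used to compare
instruments.

**Separability profile.** The per-wavelength class separability between
intact and lesion spectra is

$$Q(\lambda) = \frac{\left|\bar I_{norm}(\lambda) - \bar I_{les}(\lambda)\right|}
 {\sqrt{\sigma^2_{norm}(\lambda) + \sigma^2_{les}(\lambda)}}.$$

The absolute value is deliberate: $Q$ is used as a magnitude of separation
and thresholded, so the sign of the difference is irrelevant. With several
averaged spectra per class the means and unbiased ($n-1$) variances are
taken *across* the per-site averaged spectra — the pooled ("total")
profile; with one spectrum per class the within-series standard deviations
are used instead (the patient-level profile). Pooling across per-site
averages, rather than across raw measurements, is the simplest aggregation
that yields a single profile and weights every site equally.

**Informative bands.** Maximal runs with $Q(\lambda) > Q_{th}$ become
closed intervals; everything below the threshold is excluded. Runs narrower
than 5 nm (configurable) are dropped as single-point noise crossings — the
width is a package choice to suppress spurious crossings at 1 nm pitch.
Raising $Q_{th}$ shrinks every band, so bands at a higher threshold are
nested inside bands at a lower one; note that a *connected* run may split
into two as the threshold rises through a saddle, so the band *count* is
only monotone for profiles with one hump per spectral effect. Typical
threshold grids are 1.2/1.0/0.7/0.4 for tongue tissue and 1.0/0.8/0.4 for
cheek tissue.

**Band-area features.** Each averaged spectrum is reduced to one area per
informative band, $S(\Delta\lambda_i) = \sum_{\lambda_{lo} \le \lambda <
\lambda_{hi}} I(\lambda)\, \Delta\lambda$ — a left Riemann sum with the
grid step $\Delta\lambda$ (the upper band edge is the right endpoint of the
last step and is excluded). Whether the step multiplies each term or the
whole sum only rescales columns by a constant, which is irrelevant after
the per-fold standardization below; the per-term convention is fixed and
tested exactly.

**Classifier benchmark.** Seven methods are compared: decision tree (DT,
`rpart` defaults), linear discriminant analysis (DA), logistic regression
(LR, maximum likelihood with intercept), Gaussian naive Bayes (NKB), RBF
support vector machine (SVM, cost 1), k-nearest neighbours (KNN, $k = 5$,
Euclidean), and random forest (RF, 100 trees). None of these
hyperparameters is dictated by the problem; they are conventional defaults
and exposed as arguments. Evaluation is stratified 5-fold cross-validation,
repeated 5 times by default (one repeat reproduces a single 5-fold cycle).
Distance- and margin-based methods (KNN, SVM, LR) see features z-scored
with training-fold statistics only; tree methods consume raw features. The
optional PCA transform (components retained up to 95 % cumulative
explained variance) is likewise fitted on training folds only — a leakage
canary test asserts that fitting it on train+test gives a different
transform. Reported per method are the class-conditional confusion
frequencies ($N_{TP} + N_{FN} = 1$ within the lesion class, $N_{TN} +
N_{FP} = 1$ within the intact class), and

$$Se = \frac{N_{TP}}{N_{TP} + N_{FN}}, \qquad
  Sp = \frac{N_{TN}}{N_{TN} + N_{FP}},$$

as mean ± sd over folds × repeats. A fold whose test split lacks one class
contributes only the defined quantities.

**Loading-based pruning.** `pca_prune_bands()` scores each band by its
maximum absolute loading on the leading principal components of the
feature matrix (at most the first two; fewer when one component already
reaches the variance target) and drops the lowest-scoring bands. The PCA
here is centered but *unscaled*: the loading-plot convention ranks bands by
their contribution to the dominant variance structure, which z-scoring
would erase. An alternative sum-of-squares contribution is exposed via an
argument.

## Stage 2: patient-individual analysis

Pooled classification fails when spectra carry a per-patient multiplicative
gain (probe pressure, coupling, pigmentation): the within-class dispersion
swamps the class difference. The individual procedure removes this
nuisance:

1. **Reference signal.** The patient's intact series ($n$ measurements) is
   bootstrap-resampled — $n$ draws with replacement — and averaged into a
   simulated reference of the intact area. Resampling *with* replacement is
   the only non-degenerate reading of drawing $n$ from $n$: without
   replacement the reference would equal the intact mean exactly and the
   intact delta would be identically zero.
2. **Joint normalization.** The intact, lesion, and reference means are all
   divided by the single maximum across the three, cancelling the patient
   gain while preserving every pairwise ratio.
3. **Delta spectra.** $\Delta_{intact} = I_{intact} - I_{ref}$ and
   $\Delta_{lesion} = I_{lesion} - I_{ref}$ on the restricted wavelength
   range.
4. **Classification.** Each patient contributes the two delta rows; a
   random forest is cross-validated with folds formed over *patients*
   (both rows of a patient stay in one fold; row-wise folds would let the
   same patient's pair straddle train and test). Accuracy is reported in percent over a
   grid of 25 wavelength ranges (lower edges 500–700 nm, upper edges
   900–701 nm, including the literal 1 nm-wide 700–701 range), with rows
   equally weighted (per-signal, not per-patient majority).

### A structural caveat

The intact delta shares its measurements with the reference (the reference
is a bootstrap of the same series), so under the null — a "lesion" site
statistically identical to the intact one — $\Delta_{intact}$ has roughly a
third of the variance of $\Delta_{lesion}$, a scale-free asymmetry that a
flexible classifier can detect. The package's null-calibration experiment
shows stage-2 accuracy of about 85–90 % on effect-free cohorts: the
procedure as specified is biased toward calling any second site a lesion.
This is a property of the design, not of the implementation (the label
permutation null, by contrast, calibrates to chance). Stage-2 accuracies on
real or synthetic data therefore conflate genuine spectral effects with
this asymmetry, and should be read against the null benchmark above rather
than against 50 %.

## The synthetic cohort generator

No public DRS cohort of oral mucosa exists, so the package ships a
generator that emulates the statistical structure the analysis assumes.
Reflectance follows a modified Beer–Lambert form with unit path factor,

$$R(\lambda) = S(\lambda)\, e^{-\mu_a(\lambda)} + F(\lambda),$$

with a Mie-like scattering baseline $S = A\,(\lambda/500)^{-b}$, an
absorption coefficient mixing synthetic Gaussian-band chromophore templates
(oxyhemoglobin bands at 542/577 nm, deoxyhemoglobin at 556 nm with a weak
760 nm band, water at 970 nm — documented constants in `drs_templates()`,
not literature extinction tables, which keeps every oracle analytic and the
package self-contained), and a Gaussian fluorescence background at 500 nm.
Measurements are $\text{gain}_p \cdot R(\lambda) \cdot
I_{source}(\lambda)\,(1 + \varepsilon)$ with a Planck 2800 K source model,
log-normal per-patient gain (sd 0.1 by default) and 2 % relative Gaussian
noise. Baseline optics parameters are drawn per patient from truncated
normal priors around physiologically plausible values (blood fraction
0.03 ± 0.005, saturation 0.7, water 0.65, scattering amplitude 0.5,
exponent 1.0, fluorescence 0.05).

Lesion effects come in two modes. The *biophysical* mode shifts blood
fraction (+0.02), water (+0.05), fluorescence (−0.015) and NIR scattering
(+0.25 inside a logistic window above ~840 nm), each times `effect_size`.
The NIR change is windowed rather than applied as a global exponent change
deliberately: a global exponent shift would alter 700–750 nm — a region
the generator keeps quiet so that band selection has a true negative region
— while the windowed form reproduces the intended NIR-localized scattering
change. The *bands* mode applies a flat multiplicative suppression (depth
0.3 × `effect_size`) confined exactly to configurable intervals (default
520–580 and 850–950 nm); it exists so band-recovery tests have a ground
truth with sharp edges. Default cohort layouts mirror the study
conditions: unpaired 14 lesion / 8 intact tongue areas (stage 1; 6/7 for
cheek) and paired intact+lesion sites per patient (stage 2). All
randomness flows from one seed through derived per-patient substreams, so
cohorts are bit-identical across runs.

What the generator does *not* emulate: real chromophore extinction shapes,
probe-geometry effects, spatial heterogeneity within a site, site-level
optical differences between a patient's intact and lesion locations
(intact and lesion share the patient's baseline parameters exactly), and
fluorescence re-absorption. Passing tests therefore demonstrate that the
pipeline recovers the structure this model encodes — localized class
effects under gain nuisance and noise — not that it would achieve any
particular accuracy on clinical spectra.

## Test and experiment sizes

The statistical experiments in the test suite use cohorts of 20–40
patients, 15 measurements per site, 5-fold cross-validation with 2–5
repeats, and 5–20 replicate seeds per experiment; the confidence-interval
and bootstrap calibrations use 2000 replicates. These sizes keep every
Monte-Carlo estimate's standard error well inside the asserted bands while
the full suite completes in a few minutes.

## Known limitations

* The stage-2 null bias described above is inherent to sharing
  measurements between the intact signal and its bootstrap reference.
* Band thresholding applies no multiple-testing control across wavelengths;
  the per-wavelength profile is a selection heuristic, not an inference.
* With very small cohorts (e.g. 6 + 7 cheek areas) per-fold confusion
  frequencies are coarse and their sds large; the benchmark reports them
  as-is.
* Classifier hyperparameters are fixed conventional defaults; no tuning is
  performed, matching the benchmarking intent rather than maximizing any
  single method.
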