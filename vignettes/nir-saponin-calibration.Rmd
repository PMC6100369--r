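---
title: "NIR calibration of a saponin content: models, choices, limits"
author: "nirquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIR calibration of a saponin content: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirquant)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the judgment calls made where the underlying methodology
leaves room.

## 1. The problem

Shengmaxinside I is a cycloartane triterpene saponin used as a quality
marker for honey-fried Rhizoma Cimicifugae. Its reference determination is
HPLC with evaporative light scattering detection (ELSD) — accurate but
slow and destructive. Near-infrared diffuse reflectance spectra of the
dried powder (absorbance-like `log(1/R)` over 4000–12000 cm⁻¹) can be
acquired in seconds; the task is a multivariate calibration that maps a
spectrum to a content in % w/w.

Two chains of computation are involved:

* **Reference chain** (`hplc` functions): ELSD peak area → content.
* **Spectral chain** (`SpectrumSet` → preprocessing → PLS): spectrum →
  content, trained against the reference chain's values.

## 2. The ELSD reference chain

ELSD response is a power law of analyte mass, so its standard curve is a
straight line in log–log space; `fitLogLog()` fits
`log10(area) = s·log10(mass) + b`. The same exponent links peak area and
content of real samples, which is how `fitPowerLaw()` obtains
`content = c·area^(1/s)` from a table of (area, content) pairs, and
`contentFromArea()` applies it, rounding half-away-from-zero to four
decimals (the reporting convention of the reference table).

The packaged reference table (`table2Fixture()`, 150 samples) is
internally consistent with a single power law to about one unit in the
fourth decimal: a leave-one-out refit reproduces 140 of 150 printed
contents exactly at four decimals and every one of them within ±0.0005.
Two quirks of the source data are kept verbatim rather than repaired:

* one sample (Sample 98, 1.4083 % w/w) lies far above the 0.12–0.52 %
  range of the remaining 149; range statements in documentation refer to
  the bulk, the record itself is untouched;
* the absolute dimensional chain (solution concentration × injection
  volume → injected mass) printed alongside the curve is inconsistent
  with the stated linear range by a constant factor of about 50.
  `linearRangeScale()` exposes the volume-scaling arithmetic, but
  quantitation is anchored on the (area, content) power law, which the
  table obeys exactly; the inconsistency is documented, not silently
  corrected.

## 3. The spectral container

`SpectrumSet` extends `SummarizedExperiment`: wavenumbers are rows
(strictly increasing, canonical ascending orientation even though
instruments scan descending), samples are columns, per-sample metadata
(`origin`, `content`, `peak_area`, `role`) lives in `colData`. Window
subsetting (`subsetWindows()`) keeps axis points inside closed intervals;
bounds are inclusive on both ends because interval notation like
"5200–6700" in common usage includes its endpoints — the choice matters
only for the single grid point at each boundary.

A windowed axis is a concatenation of uniformly spaced blocks. All
derivative-type filters operate per contiguous block (spacing uniform to
1e-6 relative within a block), so that windowing and filtering commute
sensibly and no derivative is ever taken across a spectral gap.

## 4. Pretreatment operators

* **SNV** standardizes each spectrum to mean 0, sd 1 (n−1 denominator).
* **MSC** regresses each spectrum on a reference by OLS
  (`x = a + b·ref`) and returns `(x − a)/b`. The reference is the mean
  calibration spectrum, fitted on calibration data only; a fitted
  pipeline reuses it unchanged on validation or new data. This
  statefulness is the single most important contract in the module: using
  the target set's own mean would leak information and silently change
  the model between sets.
* **FD/SD** are central finite differences (one-sided, same-accuracy at
  the ends, so length is preserved).
* **Savitzky–Golay** fits a degree-`polyorder` polynomial to a moving
  window and evaluates its `deriv`-th derivative at the center; edge
  points refit on the truncated one-sided window. Defaults: window 11
  points, polyorder 3. At the default 4 cm⁻¹ grid an 11-point window
  spans 44 cm⁻¹, comfortably below the ~60 cm⁻¹ width of the narrowest
  bands, so derivatives are smoothed without flattening real structure.
* **Norris** gap-segment derivatives difference running segment means
  across a gap; defaults segment 5, gap 5 (both in points; segment odd so
  it can center). Points whose segments would leave the axis take the
  nearest valid value.

Composite labels follow the field's conventions. `"MSC + SD + SG"` is
read as scatter correction first, then a *single* Savitzky–Golay second
derivative — not a finite-difference second derivative followed by
separate smoothing, which would differentiate twice. The same reading
applies to `"FD + SG"`. The underlying acquisition software's exact
window and polynomial settings are not recoverable from published
summaries; the defaults above are ordinary chemometrics practice, and
every parameter is exposed.

## 5. PLS, cross-validation, factor choice

PLS1 is fitted by NIPALS (deterministic for a single response; no random
initialization exists to seed). Columns of X and y are mean-centered;
spectral columns are *not* autoscaled, the standard choice for spectra
where the natural per-channel scale is informative. Extraction stops
early if the residual response variance falls below 1e-12 of its initial
value, recording the factor count actually extracted.

Cross-validation is leave-one-out: deterministic, split-free, and the
default of the acquisition software this workflow emulates. Each fold
refits from scratch, including re-centering and, in the full workflow,
refitting nothing of the preprocessing (the pipeline was fitted once on
the full calibration set; the fold refit concerns the regression only —
the pragmatic standard, since refitting an MSC mean over 119 of 120
samples changes it negligibly). Because NIPALS models are nested in the
factor count, one refit per fold serves every factor count at once; a
brute-force per-(fold, count) oracle in the tests confirms the shortcut
is exact.

The factor count is the smallest whose RMSECV is within 2 % of the curve
minimum. A pure argmin overfits the CV noise and drifts upward; the 2 %
band operationalizes "too few factors underfit, too many fit noise" as a
reproducible rule. Both the tolerance and the cap (`aMax = 10`) are
arguments.

Two determination coefficients are reported: `r2` from fitted calibration
predictions and `r2cv = 1 − PRESS/TSS` from cross-validated ones.
Published model summaries rarely say which convention their software
used; reporting both costs nothing and the screening tables and final
report use the cross-validated one, the more honest of the two. RPD is
sd(validation contents)/RMSEP, with the bias-corrected SEP also computed
and stored.

## 6. Splitting, screening, reporting

`splitCalibration()` assigns 120 of 150 samples to calibration uniformly
at random (seeded; a pure function of sample order, count and seed). If
the validation content range escapes the calibration range the workflow
warns — predictions there are extrapolations — but does not stop, since a
single extreme sample should be visible, not fatal. One contradiction in
the source methodology is resolved here: the sample-set description says
120/30, while the verification text elsewhere implies all 150 re-enter
the model; this package follows the 120/30 reading throughout.
`boxcarSelect()` provides the content-uniform ("boxcar") subset selection
used to assemble such designs from a larger pool: equal-width content
bins, near-equal per-bin quotas, seeded random choice within bins. It is
a documented stand-in with the same stated goal as the proprietary
selection tools, not a re-implementation of them.

`gridSearch()` evaluates every pretreatment × window cell independently
(failures are recorded per row, never fatal) and ranks by ascending
RMSECV with ties broken by descending cross-validated R². The default
grid is ten scatter-correction × derivative composites by six window
sets, 60 cells. Reports mirror the conventional final-model table
(Method, Spectral Preprocess, Spectral Range, Number of Factors,
Determination Coefficient, RMSECV, RMSEP, RPD). One oddity of the
published window-screening table is kept as printed: its RMSEP column is
on a scale inconsistent with its RMSECV column; the package reports both
metrics in % w/w and leaves the comparison to the reader.

## 7. The synthetic generator

Real spectra for this material are not publicly deposited, so end-to-end
validation runs on synthetic data with known truth. `generateSpectra()`
draws, per sample *i*:

```
clean_i  = y_i · analyte + background + Σ_k c_ik · interferent_k + (b0_i + b1_i·ν)
observed_i = mult_i · clean_i + add_i + ε_i
```

with contents `y` from the embedded reference table by default (so the
synthetic experiments share the real content distribution, including its
one extreme sample), lognormal interferent concentrations around 1
(relative sd 0.1), per-sample linear baselines, multiplicative scatter
`mult ~ N(1, 0.05)`, additive offset `add ~ N(0, 0.01)`, and Gaussian
noise of 1e-4 absorbance inflated tenfold on 4000–4200 cm⁻¹ — the noisy
fiber-absorption region that is the stated reason this range is excluded
from modeling. Every draw runs in a per-sample substream hashed from the
single seed, so extending `nSamples` never perturbs earlier samples.

The component library is where the design lives:

* the **analyte** has Gaussian bands at its assigned positions (4250,
  4357, 4762, 5168, 5776, 6848, 8248 cm⁻¹), 60 cm⁻¹ wide in the
  combination region and 120 cm⁻¹ for overtones, scaled so 0.3 % w/w
  contributes ≈0.05 absorbance at 5168 cm⁻¹;
* the **bulk-matrix background** (constant across samples) has two
  parts: very broad smooth bands carrying most of the absorbance level,
  and weak narrow matrix C–H/O–H bands at the *same positions* as the
  analyte's. Both parts are deliberate. The smooth part is what makes a
  mean-spectrum MSC (or SNV) an accurate scatter anchor, exactly as the
  common matrix absorption does in real powder spectra — and it vanishes
  under a second derivative. Co-locating the sharp background bands with
  the analyte's reflects that all organic matter absorbs at essentially
  the same C–H/O–H combination and overtone positions, and it means
  derivative-only pretreatments have no scatter-free sharp structure
  from which to infer the multiplicative factor. Together these give the
  generator its designed-in property that scatter-correcting pipelines
  genuinely outrank non-correcting ones, rather than merely tying them;
* the **interferents** (honey-sugar-like, cellulose-like, water-like)
  vary between samples, with strong bands mostly *outside* the final
  5200–6700 / 7700–8800 cm⁻¹ windows and weaker overlapping tails
  inside — mirroring the stated rationale for selecting those windows in
  the first place, and making window and factor selection matter on
  synthetic data.

Under these defaults the full pipeline (MSC + SG second derivative,
final windows, LOO-selected factors ≤ 10) reaches cross-validated
R² ≥ 0.9878 and validation RPD ≥ 5.513 — the headline figures of the
real-data study this workflow reimplements — in at least 8 of 10 seeds;
the acceptance tests check exactly that, and the margin is substantial
(median R²cv ≈ 0.996, median RPD ≈ 11 over seeds).

What the generator does **not** emulate: Kubelka–Munk radiative-transfer
physics, instrument line shape, wavelength-axis drift, detector
nonlinearity, or any true spectroscopic signature of the analyte beyond
its qualitative band positions. Passing tests on synthetic data therefore
demonstrate the *statistical* machinery — scatter correction, derivative
filtering, window selection, factor selection, validation metrics — under
a data-generating process with the assumed structure; they are not
evidence about any particular real instrument or matrix.

## 8. Numerical choices and scale

* Default axis 4000–10000 cm⁻¹ at 4 cm⁻¹ (1501 points): large enough to
  exercise every operator, small enough that the full test suite and the
  ten-seed acceptance runs finish in minutes on one core. The
  instrument-native 0.5 cm⁻¹ spacing is supported via `step`.
* All simulation-based checks use 150 samples with a 120/30 split — the
  design of the emulated study — and ten seeds where a stochastic claim
  is made.
* Contents are formatted at four decimals, rounding half away from zero.
* MSC errors if a per-sample slope falls below 1e-12; SNV errors on
  constant rows (naming the sample); axis equality between pipeline,
  model and data is enforced at 1e-8 cm⁻¹.
* Grid ranking ties break on cross-validated R²; remaining ties keep
  stable order.

## 9. Known limitations

* Leave-one-out CV refits the regression per fold but not the MSC
  reference (see §5); with 120 calibration samples the difference is far
  below every tolerance used here, but at very small n a fully nested
  refit would be preferable.
* `boxcarSelect()` redistributes quotas greedily; for pathological pools
  (many empty bins) the selected histogram is only as uniform as the pool
  allows.
* The power-law content converter is only anchored by the embedded
  reference table; applying it to areas from a different instrument or
  gradient requires refitting with `standards=`.
* No JCAMP-DX/OPUS/SPC readers: spectra enter via the CSV dialect of
  `readSpectraCSV()`.
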