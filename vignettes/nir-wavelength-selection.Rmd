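---
title: "Wavelength selection and PLS calibration for NIR spectra of plant biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection and PLS calibration for NIR spectra of plant biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsel)
```

## The problem

Near-infrared (NIR) spectroscopy is the standard rapid, non-destructive way
to quantify constituents such as cellulose and hemicellulose in ground plant
biomass. An NIR spectrum of corn stover covers thousands of wavenumber
variables, but the analyte information is concentrated in a handful of
overtone and combination bands of C–H, O–H and C=O groups; the rest of the
axis carries baseline, scatter and absorbance of other constituents.
Calibration models are built by partial least squares (PLS) regression
against wet-chemistry reference values, and a large body of chemometrics
practice holds that pruning the wavelength axis to characteristic variables
makes the models smaller, faster and often more accurate.

`nirsel` implements that complete workflow: spectral pretreatment selection,
Monte-Carlo cross-validation (MCCV) screening of abnormal samples,
independent-test-set withdrawal, SPXY calibration/validation splitting, five
wavelength-selection strategies (BIPLS, CARS, and the hybrid chains
BIPLS–CARS, BIPLS–GSA, CARS–GSA), PLS1 model building with
latent-variable (LV) selection by MCCV/PRESS, and the standard evaluation
statistics. A synthetic corn-stover-like generator with known ground truth
makes every stage testable end to end.

## The PLS core

Models are PLS1 (one analyte at a time), fitted by NIPALS deflation on
column-centered spectra and centered responses; no column scaling is applied,
which is the norm for absorbance data. For a single response the NIPALS
weight of each component has the closed form $w \propto X^\top y$, so no
inner iteration is required; components are extracted until the requested
count `A` or until the residual covariance norm falls below `tol = 1e-10`,
in which case the model is truncated and flagged. Regression coefficients
are recovered as $b = W (P^\top W)^{-1} q$.

Cross-validated error is always the pooled root mean squared error of
held-out predictions,

$$\mathrm{RMSECV} = \sqrt{\tfrac{1}{n}\sum_i (y_i - \hat y_{i,\text{out}})^2},$$

under either k-fold CV or MCCV (repeated random calibration draws). The
latent-variable count of the final models is chosen by minimizing PRESS over
`A = 1..lv_max` under MCCV with 100 runs and an 80 % calibration fraction
(`lv_max = 20` by default; reported stover models use 8–18 LVs, so 20 leaves
headroom). Both fold assignment and Monte-Carlo draws derive from the
configuration seed, so every RMSECV is reproducible; the package's
`selection_result` objects store the cross-validation configuration so the
achieved RMSECV can be recomputed exactly.

The fitting and cross-validation inner loops are implemented in
RcppArmadillo: the selectors below evaluate tens of thousands of small CV
problems, which would dominate the runtime in pure R.

## Pretreatments

Five pretreatments are provided — Savitzky–Golay filtering (`sg`),
multiplicative scatter correction (`msc`), standard normal variate (`snv`),
first derivative (`fd`) and unit-norm normalization (`norm`) — plus ordered
combinations. `select_preprocessing()` picks the candidate with the lowest
RMSECV (ties keep the first candidate; failing candidates are recorded, not
fatal). Choices worth noting:

* **SG defaults** are window 11, polynomial order 2, derivative 0; at the
  spectrum edges the polynomial is refitted on the truncated window instead
  of padding, so edge variables stay usable by downstream selection.
  Derivatives are scaled by the axis spacing.
* **MSC reference** is the mean calibration spectrum, frozen by
  `preprocess_fit()` and reused for validation/test rows, so no statistic of
  unseen samples ever enters the transform.
* **Order inside combinations** follows the listed order ("sg" then "msc"
  for the classical smooth-then-correct pipeline); it is configurable.
* Missing values are rejected at load time, never imputed.

A caution that the synthetic experiments below make vivid: MSC and SNV divide
each spectrum by a sample-dependent factor. When total absorbance is itself
informative about composition, that division is a mildly nonlinear transform
of the concentrations (so a linear model retains $R^2 \approx 0.995$, not
exactly 1, even on noise-free data), and the fitted MSC slope can *transfer*
analyte information into every spectral channel.

## Abnormal-sample screening

`mccv_residual_stats()` repeats random calibration/hold-out splits
(default 1000 runs, 75 % calibration), fits a PLS model per run with a
latent-variable count chosen once on the full data, and accumulates each
sample's held-out residuals. Samples are flagged when the mean of their
absolute residuals exceeds `mean_threshold` (default 2.5, in analyte
percentage points) **or** the variance of their signed residuals exceeds
`var_threshold` (default 0.3) — strictly greater in both cases, so a sample
sitting exactly on a threshold is kept. The absolute-value convention
matches the non-negative residual-mean maps used for screening; a signed
mode is available. Thresholds are analyte-scale quantities and should be
rescaled for responses on other scales.

## Partitioning

The independent test set is a uniform random draw (`random_itest()`,
seeded). The remaining samples are split by SPXY (`spxy_split()`): joint
distances

$$d(p,q) = \frac{d_x(p,q)}{\max d_x} + \frac{|y_p - y_q|}{\max d_y}$$

with Euclidean $d_x$ on the modeling (preprocessed) spectra; the most
distant pair seeds the calibration set and samples maximizing their minimum
distance to the selected set are added greedily. Ties break to the lowest
original index, making the split platform-independent. The default
calibration:validation ratio is 2:1.

Because uniformly drawn concentrations are dense near their range ends, the
calibration set contains the *exact* extreme samples only in roughly three
quarters of random datasets; what holds essentially always (and what the
package's property test asserts) is coverage of the validation range within
2 % of the response range — still far above what random splitting achieves.

## The five selectors

**BIPLS** divides the axis into `n` contiguous intervals of width
`floor(p/n)` (remainder distributed one per interval from the first) and
eliminates backwards: at each level the interval whose removal minimizes the
RMSECV of a model on the remaining intervals is dropped, until one interval
remains; the returned subset is the recorded state with the global minimum
RMSECV. `bipls_scan()` repeats this over a list of `n` values and then
scans the integer bracket between the two best coarse values.

**CARS** (`cars_once()`, `cars_repeat()`) runs `N` iterations per pass; in
iteration `i` a Monte-Carlo draw of 80 % of the calibration samples is
fitted, variables are force-reduced to the top $r_i\,p$ by absolute
regression coefficient under the exponentially decreasing function
$r_i = a e^{-k i}$, and adaptive reweighted sampling then draws that number
of variables with replacement, weighted by $|b_j|$, keeping the deduplicated
survivors. The EDF constants come from two boundary conditions — all $p$
variables kept at $i=1$, exactly 2 at $i=N$:

$$k = \frac{\ln(p/2)}{N-1}, \qquad a = e^{k}.$$

The published descriptions of this workflow give two different counts for
the sampling loop (1000 Monte-Carlo samplings vs a subset sequence of 100);
`nirsel` resolves this as `N = 100` EDF iterations per pass with the
Monte-Carlo draw refreshed every iteration, and both numbers remain
configuration knobs. Because ARS and the Monte-Carlo draw are stochastic,
the pass is repeated (`n_repeats`, default 200) with derived seeds;
per-variable selection frequencies are aggregated over the run winners and
the final subset is the winner of the run with the global minimum RMSECV.

**GSA** (`gsa_select()`) reselects variables from a candidate subset —
chromosome length equals the candidate count, which is why it always runs
after BIPLS or CARS rather than on the full axis. It is a binary genetic
algorithm (tournament size 2, uniform crossover 0.8, bit-flip mutation
0.02, population 50) whose replacement follows the Metropolis criterion: a
child worse than its parent by $\Delta$ still replaces it with probability
$e^{-\Delta/T}$, with $T_0 = 200$ cooled by $\alpha = 0.90$ per generation,
at most 200 generations. Two hundred is treated as a *maximum*: a run stops
once the best fitness has not improved for `patience` (40) generations,
which on 50–400-bit problems happens long before the cap and leaves results
unchanged. Runs are repeated (default 30); the final subset is cut from the
per-candidate selection frequencies at the threshold whose induced subset
has minimal RMSECV (scanning all thresholds). The published phrasing of the
threshold rule is ambiguous; the scan is one reading, and a `"best_run"`
mode (return the best single run's winner) is provided as the alternative.

**Chains** (`chain_select()`) run the second selector strictly inside the
first selector's subset, so chained results can never resurrect eliminated
variables; supported pairs are BIPLS→CARS, BIPLS→GSA and CARS→GSA.

Inside all selector fitness loops the LV count is capped at 10 to keep the
inner models cheap; final models re-select their LV count properly by
MCCV/PRESS. All randomness flows from one master seed through a
counter-based stream splitter (`derive_seed`), so every repeat, chain stage
and pipeline run is reproducible bit for bit.

## Evaluation metrics

`r2()`, `rmse()` and `rpd()` follow the conventional definitions with the
*population* denominator $n$:

$$R^2 = 1 - \frac{\sum_i (y_i-\hat y_i)^2}{\sum_i (y_i-\bar y)^2},\qquad
\mathrm{RMSE} = \sqrt{\frac{\sum_i (y_i-\hat y_i)^2}{n}},\qquad
\mathrm{RPD} = \sqrt{\frac{\sum_i (y_i-\bar y)^2}{\sum_i (y_i-\hat y_i)^2}},$$

so RPD equals the population SD over the RMSE and the identity
$\mathrm{RPD}^2\,(1-R^2) = 1$ holds exactly (tested to 1e-9). Published
summary tables usually print *sample* SDs; converting between conventions
explains sub-0.01 differences when recomputing published RPDs. A perfect
fit yields `Inf` RPD, returned as a value rather than an error.
`relative_rmse()` (percent of the measured mean, < 5 % conventionally
adequate) and `percent_change()` supply the derived comparison numbers, and
`compare_report()` assembles them against the Full-PLS baseline.

## The synthetic generator

`default_stover_spec()` emulates a corn-stover NIR study: a
3940–11542 cm⁻¹ axis with 1845 points; cellulose (36.067–51.527 %) and
hemicellulose (9.484–38.541 %) drawn uniformly; Gaussian absorption bands at
the prominent stover peaks (cellulose 6817/5182/4749 cm⁻¹, hemicellulose
5182/4749/4292 cm⁻¹ — partially overlapping, each analyte keeping a private
band so both stay identifiable); band heights in absorbance per percent so a
mixture spectrum is exactly $\sum_k c_k\,\mathrm{pure}_k$ before nuisances.
On top of the analyte signal sit, by default:

* a **stable matrix background** (broad bands plus offset, ~0.5 AU),
  standing in for the bulk absorbance of constituents that do not vary in
  the simulation — without it total intensity is "closed" to the analytes
  and scatter correction destroys the signal;
* two **interfering constituents** (lignin-like: 8600/5980/4680 cm⁻¹,
  12–28 %; moisture-like: 6900/5150 cm⁻¹, 3–9 %) drawn independently of the
  analytes, so off-band regions carry genuine analyte-uncorrelated
  variance;
* a **wavelength-dependent multiplicative scatter field**
  $1+\varepsilon(\lambda)$ built from cosine harmonics with decaying
  amplitudes (`scatter_sd = 0.05`, 4 harmonics; set `scatter_harmonics = 0`
  for the classical global `1+ε` factor), emulating particle-size and
  packing effects;
* a random quadratic additive baseline (`baseline_sd = 0.02`) and white
  noise (`noise_sd = 0.0025` AU, giving band-level SNR ≈ 20).

Reference-value outliers can be injected (`n_outliers`, shift in multiples
of the analyte SD) and are recorded in the ground truth, as is the
informative mask — axis positions within two band widths (Gaussian sigmas)
of one of the analyte's band centers.

What the generator deliberately does **not** emulate: detector nonlinearity
and saturation, instrument drift between sessions, wavelength-correlated
noise, reference-method (wet chemistry) error structure, and
analyte–interferent concentration correlations (an option exists but
defaults off to keep tests identifiable).

## What the benchmark shows — and honestly does not

`selector_benchmark()` is the package's reference simulation study: per
seed it generates stover-like data (default 120 samples × 400 points — the
full 1845-point axis carries the same structure at four times the cost),
smooths, splits 2:1 by SPXY, runs all five selectors (CARS at 30 repeats,
GSA at 6 repeats, population 24, early stopping — scaled-down workloads,
unchanged algorithms), and evaluates validation RMSEP per variant with LV
counts chosen by MCCV/PRESS.

Two structural findings from this study deserve emphasis, because they
qualify what passing or failing tests on synthetic data can say about real
spectra:

* On *linear, well-specified* synthetic data, full-spectrum PLS with a
  properly chosen LV count is extremely hard to beat: redundant channels
  cost PLS very little (even an oracle given exactly the informative mask
  does not reliably win), smooth nuisances make off-band channels
  genuinely useful for correction, and ratio-based pretreatments leak
  analyte information axis-wide. The reductions in model size the
  selectors deliver (routinely 5–20× fewer variables at near-par accuracy)
  are real; a systematic *accuracy* advantage over the full spectrum is
  not reproducible in this idealized world, and reported advantages on
  real data plausibly rest on effects listed above as not emulated.
* Consequently, mask-recovery statistics are informative about whether a
  selector concentrates on analyte bands, but RMSECV-optimal subsets are
  legitimately much smaller than the ±2σ mask and also include
  interferent-correction channels, so per-variable recall of the mask
  stays well below 1 even for well-behaved selectors.

The acceptance suite states the corresponding checks at their reference
values and reports the measured counts; the benchmark numbers written by
`scripts/acceptance.R` document both findings quantitatively.

## Pipeline and leakage

`run_pipeline()` executes the stages in order. The default `"strict"`
ordering draws the independent test set first and fits *every*
data-dependent statistic — pretreatment choice, MSC reference, centering,
screening, SPXY, selection — without it; the final pretreatment statistics
are refit on the calibration set alone. A regression test perturbs the
test-set spectra and verifies the fitted models are bit-identical. The
`"screen_first"` ordering reproduces the traditional published sequence
(screen abnormal samples on all data, then withdraw the test set; the
sample-count arithmetic of the emulated study implies that order). Both
orderings keep final pretreatment statistics calibration-only.

## Numerical conventions

* Indices are 1-based everywhere, reports included.
* Wavenumber axes are canonicalized to ascending order at load; descending
  files are reversed together with their spectral columns.
* Ties: candidate lists keep the first minimum; SPXY and BIPLS break ties
  to the lowest index; PRESS ties choose the smaller LV count.
* NIPALS tolerance 1e-10; component extraction stops (with a recorded
  truncation) when the residual covariance collapses.
* Text round trips write 15 significant digits.
* Degenerate inputs error early and by name: constant spectra (SNV), zero
  MSC slopes, constant responses (R², RPD), empty subsets, out-of-range
  indices, samples never held out during MCCV.

## Limitations

PLS2, robust PLS and leverage-based outlier diagnostics are out of scope;
JCAMP-DX support covers the plain `(X++(Y..Y))` form only; the GSA
threshold rule follows one reading of an ambiguous published description
(the alternative is available); and conclusions drawn from the synthetic
benchmark transfer to real spectra only to the extent discussed above.
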