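---
title: "Methods: spectral pre-processing, one-class screening and speciation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral pre-processing, one-class screening and speciation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meatspec)
```

## The problem

Handheld reflectance spectrometers make it feasible to screen meat at the
point of sale or certification. Two acquisition geometries are supported
here: a Vis-NIR device covering 400–1000 nm whose two light sources yield
two derived spectra per scan (concatenated to 1200 variables), and a NIR
device covering 900–1700 nm with 252 retained wavelengths. Each physical
sample is scanned at six points (five near the edges, one at the centre), so
every statistical decision in the package is *sample*-aware: replicate scans
are never allowed to straddle a train/test or cross-validation boundary,
because replicates of one cut are far more similar to each other than to
scans of another animal, and splitting them would inflate every performance
estimate.

Two complementary questions are addressed:

1. **Halal screening** — "is this sample compatible with pork?" — answered
   with one-class classifiers fitted to pork alone, so that lamb, beef,
   chicken, or any species never seen in training can still be flagged as
   *not pork meat*.
2. **Speciation** — "which of the four species is it?" — answered with
   discriminant models (PLS-DA and kernel SVM) trained on all four classes.

## The synthetic generator

No public spectra exist for this application, so the package ships a
generator (`simulate_spectra()`) whose output has the statistical structure
the analysis stages assume. Spectra are sums of a smooth baseline and
Gaussian absorption bands:

* in the visible range, haem-pigment bands at 418, 546 and 578 nm whose
  heights are ordered beef > lamb > pork > chicken (pigment load), a fat
  band near 930 nm and the 970 nm water band;
* in the NIR range, the shared 1450 nm O–H first overtone (water), the
  1200 nm C–H second overtone (fat, highest for pork), and smaller protein
  and C–H bands at 1510/1650 nm.

Between-species contrasts are deliberately larger in the visible than in the
NIR range, so that Vis-NIR simulations separate species more easily than NIR
ones — the ranking that motivates carrying both sensors. The default effect
sizes were chosen once to give realistic-but-imperfect separation
(one-class AUROC near but not always at 1 for Vis-NIR, visibly lower for
NIR); `species_effect = 0` collapses all species onto the mean profile and
provides the null configuration used by the chance-level tests.

Noise model, per scan: a per-sample relative band-height deviation (drawn
once per sample, `sample_sd`, default 0.08 — biological variation between
animals), an extra per-replicate band jitter for intact meat
(`intact_extra_replicate_sd`, default 0.03 — surface heterogeneity that
grinding removes), multiplicative scatter `1 + N(0, 0.05)`, an additive
offset `N(0, 0.02)` and independent channel noise `N(0, 0.005)`, all in the
arbitrary intensity units of handheld instruments. The replicate jitter is
drawn whether or not it is applied, so intact and ground runs under one seed
differ *only* through that term and paired comparisons are exact. R's
default Mersenne-Twister generator is used throughout with explicit seeds;
equal seeds give bit-identical datasets.

What the generator does **not** emulate: instrument response functions,
wavelength-dependent noise, temperature effects, detector saturation, or
breed/feed/ageing composition gradients within a species. Passing tests on
this generator therefore demonstrate that the *procedures* are implemented
correctly and behave sanely under a plausible data-generating process — not
that any particular accuracy will be reached on real meat.

`benchmark_datasets()` fixes the campaign sizes used in examples and checks:
157 Vis-NIR samples (37/40/40/40 lamb/beef/chicken/pork; 942 scans x 1200
channels) and 161 NIR samples (41/48/40/32; 966 scans x 252 channels).

## Pre-processing catalogue

Every operator is a pure transform with a serialisable parameterisation;
chains are written in a compact grammar (`"snv|detrend(deg=2)"`) that doubles
as the combination id in screening reports. Stateful operators (MSC/EMSC
reference, centering statistics, OSC weights) fit on training rows only —
`apply_chain()` enforces this, and the leak-freedom tests mutate test rows
and assert the fitted state is unchanged.

Numerical conventions worth recording:

* **Gap-segment derivatives** are defined on segment means `s(i)` (segment
  length must be odd so windows are centred): first order
  `(s(i+h) − s(i−h))/(2h)` with `h = ceiling(gap/2) + floor(segment/2)`,
  second order `(s(i+g) − 2s(i) + s(i−g))/g²` with `g = gap + segment − 1`,
  both per channel step. The convention is pinned by the property tests
  (second derivative of a quadratic row is exactly 2). Channels whose
  stencil leaves the row are trimmed and the retained-channel mask
  propagates through the chain.
* **Savitzky–Golay** filtering delegates to `signal::sgolayfilt`, whose edge
  handling is the polynomial fit within the first/last window — no trimming.
* **EMSC** scales the wavelength axis affinely to [−1, 1] before building
  the polynomial design, purely for conditioning; with `poly_degree = 0` it
  reduces exactly to plain MSC.
* **Weighted MSC** takes an explicit per-channel weight vector and defaults
  to uniform weights (= ordinary MSC); no canonical weighting is imposed.
* **DWT features** interpolate each spectrum linearly onto 128 points and
  run a periodic dyadic pyramid with either the 2-tap Daubechies (Haar)
  filter (levels 5–7, 4+2+1 = 7 features) or the 8-tap least-asymmetric
  filter (levels 3–5, 16+8+4 = 28 features). Only detail coefficients are
  returned: details are invariant to additive offsets, which is exactly the
  baseline robustness one wants; approximation coefficients would
  reintroduce baseline dependence. The transform is implemented in the
  package (no R wavelet dependency) and its filter banks are the standard
  published coefficients.
* **OSC** orthogonalises each extracted score vector against the class
  indicator matrix before deflation; weights are the minimum-norm solution
  of `X w = t`, exact whenever channels outnumber scans (the usual spectral
  case), which makes re-application to the training matrix reproduce the
  deflated matrix to rounding error.

## Sample-set partitioning and cross-validation

Distance-based splitting (duplex, Kennard–Stone) operates on one
representative per sample — the mean of its replicate spectra after SNV.
SNV-before-distance is a package decision: without it, multiplicative
scatter dominates the distances and the "diverse" selections chase scatter,
not composition. Splits run within each species stratum so every species
appears in the test set. Duplex seeds the training set with the farthest
pair, the test set with the next farthest pair, then alternates max-min
assignments until the test quota is met; all ties break to the lowest group
index, making both algorithms fully deterministic.

Venetian-blinds cross-validation assigns sample `i` (0-based) to fold
`floor(i/thickness) mod n_splits` — with the default (10, 1) this is "every
10th sample", at the group level so replicates share a fold. The screening
protocol uses 80 repeated random 70/30 splits of the pork samples.

## One-class screening and the ensemble

Five one-class algorithms are available, all fitted to pork training scans
only, all exposing a non-negative `class_distance()` with smaller = more
pork-like:

* **SIMCA** — `sqrt((Q/Q̄)(T²/T̄²))`, the geometric mean of the
  training-mean-normalised residual and leverage statistics (3 PCs). The
  normalisation makes the training mean of each factor exactly 1.
* **PCA residual** — the Q statistic alone (3 PCs).
* **Mahalanobis** — score-space Mahalanobis distance (3 PCs).
* **kNN distance** — mean distance to the k nearest training scores
  (2 PCs, k = 1).
* **OCSVM** — RBF one-class SVM (ν = 0.05, γ = 1/(p·var(X)));
  decision values are reversed (`max(0, m − f)`, `m` = max training value)
  so the orientation matches the others.

`screen_occ()` evaluates every chain x subset x algorithm combination over
the 80 repeats, reporting mean AUROC of pork against lamb, beef, chicken,
and all non-target scans pooled (pooling, rather than averaging contrasts,
is the package's reading of the "all" column; it is configurable in spirit
by recomputing from the per-contrast values). AUROC uses the Mann–Whitney
pair-counting form with ties at ½, so it is invariant under monotone
transforms of the distances.

The triplet of models is selected greedily — first the combination with the
best worst-class AUROC, then twice the combination that most raises the
ensemble's weakest per-class best — as an automatic stand-in for the
expert's manual choice; a `manual` override accepts three explicit ids.

Class limits come in two scenarios. Scenario 1 places the limit just above
the maximum training-sample median distance, so 100% of pork training
samples are in-class by construction — the certification-relevant setting,
since no pork must ever be certified as non-pork. Scenario 2 uses the 0.95
quantile of the training distances (the quantile is a package default; any
`q` can be supplied), accepting a small pork sensitivity loss for stricter
rejection of non-pork. Classification takes the median class distance of a
sample's replicates per model and flags *not pork meat* when at least 2 of
the 3 models call it out-of-class.

## Discriminant layer

PLS-DA is NIPALS PLS2 on the one-hot species indicators (implemented in the
package; an independent cross-check against `mixOmics::plsda` and against a
direct least-squares oracle at full rank is part of the test suite). The LV
count minimises group-aware venetian-blinds CV misclassification, ties to
fewer LVs; class assignment is the argmax of predicted indicators (ties to
the alphabetically first class). VIP scores follow the standard projection
formula and satisfy `sum(VIP²) = p` identically; the `> 1` rule marks
selected variables. Only VIP-based selection is implemented — a
regression-coefficient rule is sometimes mentioned in this literature
without a concrete formula, so `tidy()` exposes the scores and any custom
mask can be applied upstream.

Outlier removal uses Hotelling T² (F-distribution limit) and Q residuals
(Jackson–Mudholkar limit); the default flags a row only when **both**
exceed their limits — conservative, because removing training samples is
destructive — and is intended for training data, once, followed by a refit.

SVM tuning grids over RBF, quadratic and cubic kernels
(C ∈ {0.1, 1, 10, 100}, RBF γ ∈ 10^(−3..1); polynomial kernels use
γ = 1/p and coef0 = 1), selected by group-aware CV accuracy with ties to
the simpler kernel and smaller cost. Probability shares for the
leave-class-out cutoff come from e1071's pairwise-coupling estimates (an
approximation, as all SVM probabilities are); PLS-DA shares are a softmax
of the predicted indicators, used *only* for the 0.5 cutoff in
leave-class-out, never for ordinary classification.

Leave-class-out validation drops one species entirely, fits the 3-class
model on the rest, and tabulates where the held-out spectra land — a
prediction is only allocated when its share exceeds 0.5, otherwise it is
"unassigned". The allocation rows always sum to the held-out scan count.
Metrics are computed per scan (six spectra per sample), matching how the
confusion tables are usually reported; a per-sample majority vote can be
recovered from the decision tables if desired.

## Problem sizes and determinism

The test-suite simulations use 3–6 samples per species for operator and
integrity checks, and 40 samples per species (the campaign scale) for the
scenario calibration and ensemble-rate checks; screening in tests runs on
reduced grids with 6–80 repeats depending on what the check needs. These
sizes were chosen so the whole suite exercises every stage at realistic
dimensionality while remaining quick to run. Every stochastic stage takes
an explicit seed, and `run_pipeline()` fans a single master seed out to the
stages, so a config reproduces every table byte for byte.

## Known limitations

* The generator's Gaussian-band world is smooth and low-rank; real meat
  spectra carry instrument artefacts and compositional covariance the
  generator does not attempt.
* NIR "256 variables per measurement" appears in some device descriptions;
  the data matrix convention here is 252 retained wavelengths, which is
  what the package treats as authoritative for the NIR grid.
* The screening AUROC aggregates over repeats by the mean; other summaries
  (median, worst-case) are one `dplyr::summarise()` away from the
  per-combination records but are not built in.
* Scenario 2's quantile and the OCSVM ν/γ defaults are package defaults,
  not canonical constants; both are arguments.
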