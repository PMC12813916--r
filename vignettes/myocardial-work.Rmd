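---
title: "Myocardial work from pressure-strain loops: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myocardial work from pressure-strain loops: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myowork)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic cohort can and cannot tell you about real
echocardiographic data.

## The noninvasive pressure model

The pressure half of a pressure-strain loop cannot be measured directly
without catheterization. The established noninvasive approach anchors a
normalized reference pressure waveform to the subject's own valve-event
times and scales it so the peak equals the brachial systolic pressure
(SBP). The reference waveform used by commercial analysis software is
empirical (derived from invasive recordings) and unpublished, so this
package uses an analytic surrogate with the same landmark behaviour, built
from raised-cosine segments:

- diastole at a configurable floor (default 10 mmHg) outside MVC-MVO;
- a monotone raised-cosine rise during isovolumic contraction (MVC to AVO)
  from the floor to a shoulder level (default 0.95 of the peak range);
- a raised-cosine ejection hump peaking at exactly the SBP at a
  configurable phase of ejection (default mid-way between AVO and AVC);
- a monotone raised-cosine fall during isovolumic relaxation (AVC to MVO)
  back to the floor.

`pressure_template()` exposes all three shape parameters, and templates
serialize to JSON, so a vendor-specific waveform can be substituted without
touching anything downstream. Every contract the rest of the package relies
on (peak equals SBP, monotone isovolumic phases, floor at the cycle
boundaries, scale equivariance above the floor, invariance under time
dilation) holds for any template of this family.

Numerically, the curve is sampled on a uniform half-open grid over
`[0, cycle_length)` (default 1000 samples) and the sampled profile is
renormalized by its grid maximum, so `max(pressure)` equals the input SBP
*exactly* rather than to interpolation tolerance.

## Work indices

With strain ε(t) in percent (negative = shortening) and pressure P(t) in
mmHg, both linearly interpolated onto their merged time grid over the
analysis window MVC to MVO (with the AVC phase boundary inserted as an
exact grid point), the package forms per-interval trapezoidal work
increments `dW_i = mean(P) * Δε` and derives:

- `GWI = -Σ dW_i` — the signed loop area, positive for physiologic
  orientation (shortening at high pressure);
- `GCW = Σ max(-dW_i, 0)` over systole + `Σ max(dW_i, 0)` over isovolumic
  relaxation;
- `GWW` with the two classifications swapped;
- `GWE = 100 · GCW / (GCW + GWW)`, with an explicit `NA` (never a silent 0
  or 100) when total work is zero.

Systole is defined MVC to AVC (including isovolumic contraction) and
isovolumic relaxation AVC to MVO: the valve-event-bounded convention, which
is the only phase definition consistent with anchoring the whole analysis
on valve events. Working with shared increments rather than a separately
discretized `|P · dε/dt|` integral makes the algebraic relations exact at
any grid: `|GWI| ≤ GCW + GWW` always, sign-flipping the strain trace
exchanges GCW and GWW exactly, and uniform time re-parameterization leaves
all four indices unchanged. Note that `GWI = GCW − GWW` does *not* hold:
re-lengthening during isovolumic relaxation adds to GCW while reducing the
loop area, which is why population GCW exceeds GWI. An exported
`work_rate()` provides the instantaneous power signal `P · dε/dt` (central
differences, one-sided at the edges) for diagnostics.

Units are fixed throughout: ms, percent strain (never fractional), mmHg,
hence mmHg% for work — matching the magnitudes used in clinical reporting.

## Loop-shape analysis

Each loop is time-normalized to 1000 points: four segments of 250 uniformly
spaced samples between consecutive valve events (MVC-AVO, AVO-AVC, AVC-MVO,
MVO-end of cycle wrapping back to MVC), linearly interpolated per axis
against time. Group mean loops are pointwise averages; the uncertainty band
is the per-point marginal SD of each axis (the diagonal of the per-point
2×2 covariance of strain and pressure across subjects).

Two complementary distances compare loop shapes:

- **DTW** — classical dynamic programming with per-step Euclidean distance
  in the (strain, pressure) plane, boundary-matched endpoints and no
  warping window. Distances default to raw units (mmHg and %); because the
  published analysis does not state whether axes were unit-balanced, a
  `standardize` flag (pooled per-axis z-scoring) is provided, as is a
  path-length `normalize` flag. Raw, unnormalized cost is the default.
- **Procrustes disparity** — residual sum of squares after centering both
  configurations, scaling to unit Frobenius norm, and optimal rotation.
  Reflection is excluded (only translation, rotation and isotropic scaling
  are allowed), implemented by flipping the sign of the smaller singular
  value when the optimal orthogonal map would be improper.

Significance comes from permutation: group labels are reshuffled preserving
group sizes, mean loops and both distances recomputed, and
`p = #(permuted ≥ observed) / n_perm` — the literal proportion, with an
optional add-one smoothing flag for users who need p > 0. Only two-group
comparisons are supported (pairwise testing, as in the reference analysis);
the combined p-value is the *larger* of the DTW- and Procrustes-based
p-values for age-group comparisons and the *smaller* for reproducibility
comparisons. Permuted distances are computed between permuted group mean
loops, the reading most consistent with "labels randomly reassigned"; this
is a documented interpretation, not the only conceivable pooling.

The DTW recursion is the package's one compiled kernel (Rcpp): a
10 000-permutation comparison of 1000-point loops evaluates ~10^10 cell
updates in pure R, which is not viable, while the C++ two-row dynamic
program runs one 1000×1000 alignment in a few milliseconds.

## Cohort statistics

- **Reference intervals**: mean ± 1.96 SD (sample SD, n−1) for
  approximately normal variables; 2.5th/97.5th percentiles for skewed ones.
  The percentile rule is fixed to linear interpolation between closest
  order statistics (R quantile type 7) — a documented choice, since no
  interpolation rule is standard across software. Normality selection is
  per-variable configuration (the reference analysis used visual QQ
  inspection, which cannot be automated faithfully); defaults mirror the
  reporting convention: normal for GWI/GCW/GLS, percentile for
  GWW/GWE/SBP/heart rate. Percentile intervals warn below n = 40, where
  the empirical 2.5 % tails rest on a single order statistic.
- **Tukey outliers**: fences at Q1 − 1.5·IQR and Q3 + 1.5·IQR.
- **Back-transformation** of slopes fitted on log or logit scale:
  `100·(exp(β) − 1)` percent change (relative change of the outcome, or of
  its odds, per predictor unit).
- **Bland–Altman**: bias and bias ± 1.96 SD of paired differences.
- **ICC(2,1)**: two-way random effects, absolute agreement, single rater,
  from the ANOVA mean squares, with the standard F-based confidence
  interval. Incomplete tables are rejected rather than imputed.
- **Univariable OLS slope** with SE and two-sided p, optionally after log
  or logit outcome transformation — the regression form kept for age-effect
  estimation and parameter-recovery testing (multivariable and spline
  models are out of scope).

## The synthetic cohort generator

Real reference populations for myocardial work are application-only
datasets; the generator emulates the *statistical structure* of such a
population so that every pipeline stage has a realistic, fully specified
input. Calibration (chosen once, as study conditions, and documented here):

| quantity | model | defaults |
|---|---|---|
| age | uniform on range | 20-90 yr |
| sex | Bernoulli | 55 % female |
| GLS | Gaussian, truncated to (−35, −5) | −19.5 ± 2.3 %, +0.043 %/yr, females −0.9 % |
| SBP | shifted log-normal matched to median/IQR | 124 (IQR 20) mmHg, shift 70, +0.37 mmHg/yr |
| heart rate | shifted log-normal, truncated 40-100 | 66 (IQR 15) bpm |
| valve events | Gaussian gaps, orderings enforced | medians 25/80/369/465 ms |
| GWI | Gaussian around linear age/sex model | 1975 mmHg%, −1.45 mmHg%/yr, females +109, SD 300 |
| GCW | as GWI | 2318 mmHg%, +2.32 mmHg%/yr, females +61, SD 300 |
| GWW | log-normal | log-median log(104), log-SD 0.514, +0.011/yr |
| GWE | derived `100·GCW/(GCW+GWW)` | — |

Means-level parameters (population moments, age slopes, sex offsets) come
from the published characteristics of a 1239-participant healthy cohort;
dispersions reported as IQRs are converted via the normal/log-normal
quantile relations (e.g. log-SD = log(146/73)/(2·0.6745) ≈ 0.514). The
GWI/GCW residual SD of 300 mmHg% reproduces the printed marginal SD of
~310 once the age and sex terms are added. Age and sex effects are centred
at the mean age and the configured female fraction, so marginal moments
stay at their configured values whatever the slopes — which is also what
makes embedded effects cleanly recoverable by regression. Inter-variable
correlations are not published; the generator exposes a GLS-SBP
correlation parameter defaulting to 0 rather than guessing.

Each participant carries both the *population-model* index values (used by
the statistical stages and recovery tests) and a *raw signal pair* — a
synthetic strain trace plus SBP and valve events — from which the signal
pipeline computes indices independently. The strain waveform is a
piecewise raised-cosine family anchored at the valve events (zero until
MVC, shortening to the peak at AVC, 40 % early-diastolic recovery by MVO,
return to zero by end of cycle), sampled at the frame interval with
additive Gaussian noise (default SD 0.3 %). No published source specifies
trace morphology, only summary values; a smooth analytic family keeps every
oracle tractable.

Quality control mirrors the published exclusion rules: sitting SBP > 160
mmHg, beat-timing mismatch > 12 ms between the acquisitions used for event
timing, heart-rate variation > 30 % between acquisitions (implemented as
(max − min)/min of the per-modality cycle lengths, since the denominator is
not specified), and missing/unordered events. Clean participants are
generated inside all limits (their SBP is truncated at the exclusion
threshold, matching a post-exclusion population), and a single
`contamination_rate` (default 0.07, the published exclusion fraction)
injects exactly one violation per affected subject — so the expected
excluded proportion equals the configured rate, which is tested as a
calibration property.

Reproducibility: all participants are drawn sequentially from one RNG
stream seeded once per cohort. This makes generation bit-reproducible,
gives prefix sharing (the first k participants agree across cohort sizes),
and — unlike deriving per-participant seeds by adding the index to the
master seed — keeps cohorts with different master seeds statistically
independent (consecutive-integer seeding measurably correlates streams).

**What passing tests do and do not show.** The generator reproduces
marginal distributions, linear age/sex structure, skewness, and QC failure
modes. It does not simulate image acquisition, speckle tracking, segmental
(18-segment) strain, inter-variable correlations beyond the optional
GLS-SBP term, or measurement error structure of real observers. Tests
passing on synthetic cohorts therefore validate the *computational
pipeline*, not the clinical accuracy of any waveform surrogate.

## Numerical choices and degenerate inputs

- Linear interpolation everywhere (signals are band-limited and densely
  sampled; higher-order schemes would move values at the valve-event
  anchors the contracts pin down).
- Trapezoidal integration on merged grids with exact breakpoint insertion;
  one-sided difference stencils at window edges.
- The periodic wrap for the fourth loop segment interpolates between the
  last sample and the first sample shifted by one cycle.
- Ties in permutation distances count as "≥ observed" (conservative).
- Degenerate inputs fail loudly: zero-spread configurations in Procrustes,
  constant predictors in regression, empty loop lists, incomplete rating
  tables, non-overlapping time supports, `GCW + GWW = 0` in efficiency.
- Problem sizes in the test suite are chosen to keep the full run in a few
  minutes: permutation calibration uses 200 replicates × 200 permutations
  with 8-vs-8 groups of 1000-point loops; coverage properties use 10^5
  Gaussian draws; ICC consistency uses 500 subjects × 6 raters.

## Known limitations

- The pressure template is a documented surrogate, not the vendor's
  empirical curve; absolute index values from the signal pipeline are
  internally consistent but not interchangeable with vendor output.
- Only global (not segmental) work is computed; no bull's-eye maps, no
  post-systolic shortening index.
- The MVC→MVO integration window is the implemented convention; whether
  vendor software gates GWI differently is not published, so the window is
  carried by `phase_segmentation()` rather than asserted as ground truth.
- Reference intervals assume an (approximately) healthy, QC-passing
  population; no multivariable adjustment is provided by design.
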