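---
title: "Modelling a host-cleptoparasite range system across glacial time"
author: "paleoSDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a host-cleptoparasite range system across glacial time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoSDM)
```

## The problem

Presence-only species distribution models (SDMs) correlate where a species
has been recorded with gridded environmental layers, and project the fitted
response onto other places or times. paleoSDM implements a complete pipeline
for a particular, recurring study design: a parasite whose range may be
limited both by climate and by the availability of its host. The pipeline
asks two questions at once. First, how stable has each species' suitable
range been since the Last Glacial Maximum (LGM, about 21,000 years before
present), judged by hindcasting a model fitted on current climate onto
glacial climate reconstructions? Second, does adding the host's predicted
presence as an extra predictor variable improve the parasite's model, judged
by small-sample AIC?

Because answers from real occurrence data depend on large external rasters,
the package pairs the analysis pipeline with a virtual-species simulator:
synthetic climate scenarios and host/parasite occurrences drawn from a known
("true") niche, so every stage can be validated by parameter recovery at
desk scale.

## Models

**Bioclim envelope.** A site's score on one variable is twice the tail
percentile of that value within the calibration records, `2 min(F(x),
1 - F(x))`, and the site score is the minimum over variables. We use a
midrank convention for ties, rescaled so that a value at the exact
calibration minimum or maximum scores `2/(n+1)` rather than zero:
`F(x) = (#{v < x} + 0.5 #{v = x} + 0.5)/(n + 1)`. Values outside the
calibration range score exactly zero. This keeps the envelope's edges
non-degenerate while preserving the textbook behaviour (the per-variable
median of an odd-sized calibration set scores 1).

**Maximum-entropy model.** The presence-background model is the Gibbs
distribution over the landscape whose feature expectations match the
presence sample, fitted by maximizing the penalized presence log-likelihood

$$\frac{1}{m}\sum_i \eta(x_i) \;-\; \log \sum_b e^{\eta(x_b)}
  \;-\; \sum_j \lambda_j |\beta_j|,$$

with $\eta(x)=\beta^\top f(x)$ over SD-normalized linear and quadratic
features and $\lambda_j = \beta_{\text{mult}}\, s_j/\sqrt{m}$ ($s_j$ the
feature SD over presences plus background, $m$ the presence count). The
default feature set is deliberately restrained — linear and quadratic terms
only, no hinges or products — and the default multiplier is the conservative
`beta_multiplier = 2`: with a few dozen calibration records, more complex
feature classes cannot be distinguished from noise, and the L1 penalty
produces exactly-zero coefficients, which is what the AICc parameter count
`k` relies on. A binary predictor (the host layer) enters as a linear
feature only, since its square is itself.

Optimization is cyclic coordinate descent: per coordinate a Newton step on
the smooth part followed by soft-thresholding, with per-coordinate
backtracking so the objective never increases (the trace is stored on the
model and asserted in tests). Convergence is declared when the largest
coefficient change in a sweep is below `1e-6` or the objective change below
`1e-9`; non-convergence within the sweep cap is an error carrying the trace.
Constant features are excluded with a warning and kept at coefficient zero
rather than erroring, because synthetic configurations legitimately include
inert decoys.

Predictions come in two monotone-equivalent scales: `raw`, the Gibbs
probability normalized over the model's background reference (raw scores
over the background sum to 1 by construction), and `logistic`,
$\tau e^{\eta-g}/(1-\tau+\tau e^{\eta-g})$ with prevalence $\tau = 0.5$ and
$g$ the mean linear predictor over the presences; an all-zero model
therefore scores 0.5 everywhere.

## Occurrence filtering and evaluation

Raw presence records are typically spatially and environmentally biased.
The filter partitions environmental space — by default the three axes
bio4 (temperature seasonality), bio16 and bio17 (wettest/driest-quarter
precipitation), with cell widths of 200 units each — into hyper-rectangles
anchored at each variable's observed minimum, and keeps exactly one record
per occupied cell for calibration; everything else becomes the testing set.
Two consequences drive the design: the calibration count equals the number
of occupied cells and is therefore seed-independent, and re-filtering a
calibration set is the identity. The within-cell representative is drawn
uniformly under a logged seed rather than taken "first in file", to avoid
ordering artifacts. Filtering uses the three filter variables only, even
though models fit five.

Evaluation follows the presence/pseudo-absence convention at prevalence 0.5:
the testing presences are contrasted with an equal number of cells drawn
uniformly from the valid extent. AUC is the rank (Mann-Whitney) statistic
with ties counted one half. The binarization threshold maximizes
sensitivity + specificity over midpoints of consecutive distinct scores
(ties broken toward the lowest threshold, rule "suitable iff score ≥
threshold" everywhere); it is computed on the evaluation scores, i.e. the
same data that yield the testing AUC. Omission is the fraction of testing
presences below the threshold.

For model comparison, raw scores are standardized to sum to one over the
valid cells of the current scenario — the landscape, not the background
sample, is the reference extent — and `AICc = 2k - 2 log L +
2k(k+1)/(n-k-1)` with `k` the count of nonzero coefficients; AICc is
undefined (never infinite) when `n ≤ k+1` or when an occurrence has no
model support. Relative likelihood is `exp((AICc_min - AICc_j)/2)`. The
envelope model defines no likelihood and gets no AICc; across algorithm
families, only AUC is compared.

Two per-variable importance measures are reported. Permutation importance
permutes one variable jointly across presences and background (10 repeats
by default, seeded), and normalizes the mean training-AUC drops to 100.
"Variable contribution" is the share of absolute coefficient mass on the
normalized feature scale — a transparent surrogate for the classic
implementation's training-path bookkeeping, which is path-dependent and not
replicated here; the surrogate is scale-invariant by construction and is
documented as a dialect, not validated against the original's percentages.

## Projection, stability, and the host predictor

Fitted models project onto any aligned scenario stack; hindcast ensembles
are averaged cell-wise on the continuous scale *before* thresholding (order
fixed deliberately — thresholding first would let a single extreme member
dominate). Range stability between the glacial and current periods
classifies every valid cell as `stable`, `lost`, `gained` or `never`; the
four counts partition the valid extent by construction.

The host enters the parasite's model as the thresholded binary map of the
host's own model — "presence of the host", not its continuous suitability
(a configuration switch allows the continuous alternative). For glacial
projections the host layer is the host's LGM ensemble prediction binarized
with the host's current-data threshold: thresholds are properties of the
fitted model, not of the scenario. Host-parasite overlap in a period is
`|parasite ∩ host| / |parasite|` — the asymmetric quantity "where can the
parasite find its host"; a Jaccard denominator is available behind a flag.
The with/without-host comparison fits both models on identical occurrences,
background cells and seeds, and reports paired evaluation reports, AICc,
relative likelihoods, and the map of cells that are suitable under
climate-only but become unsuitable when the host is included.

## The synthetic generator

Each climate variable is a linear spatial trend (a different direction per
variable) plus a smoothed-noise field, over a masked ("ocean") grid; past
scenarios are additive per-variable shifts of the current fields, one shift
vector per circulation model. This is not a geostatistical simulation: the
goal is enough spatial autocorrelation for environmental filtering to be
meaningful, with bit-level reproducibility from a seed.

One design point deserves emphasis. The noise field is rescaled *after*
smoothing to a stated SD (default: half the trend magnitude). If the noise
were negligible, all five variables would be near-linear functions of the
two map coordinates and hence mutually collinear — any variable could stand
in for any other, and "inert decoy" variables would be unidentifiable in
principle. The default noise level gives every variable substantial
variation independent of the shared trend, which is what makes parameter
recovery a fair test.

Defaults, in WorldClim-style units (temperatures in °C × 10, seasonality in
SD × 100, precipitation in mm): a 100 × 100 half-degree grid over a
tropical South-America-like window, 10% ocean, five variables (bio4, bio8,
bio9, bio16, bio17), glacial offsets making the past cooler, drier and more
seasonal under two slightly different "circulation models". True niches are
Gaussian bells per variable. The default study system has a widespread host
(optima near the landscape centre, broad breadths; 290 raw records) and a
narrower parasite (44 raw records) with coupling strength 0.5 — the
parasite's realised suitability is its climate suitability times the host's
suitability raised to the coupling power. Niche positions and breadths were
chosen once so that both species are genuinely climate-structured at these
sample sizes (host training AUC around 0.7, parasite around 0.8, three to
four retained parameters) rather than degenerate (a host suitable
everywhere makes the host layer zero-variance and the comparison trivial).
With these defaults the filter keeps roughly 20-25 parasite and 75-90 host
calibration records, matching the scale of a realistic museum-record
analysis.

What the simulator does *not* emulate: dispersal limitation and
metapopulation dynamics, temporal autocorrelation between periods,
geographically structured sampling bias (available, but off by default),
and real GCM physics. Passing recovery tests on this generator shows the
statistical machinery is correct; it does not show that any real species
satisfies the model's assumptions.

## Numerical conventions and degenerate inputs

* Cell membership is half-open, `[west, east) × (south, north]`: every
  point belongs to exactly one cell, and points exactly on the far east or
  far south outer edge are out of bounds.
* Values are stored in double precision in whatever units the layers carry;
  integer-coded temperatures are not rescaled (filter widths are expressed
  in raw layer units).
* Occurrences on masked cells or outside the grid are excluded *and
  reported* in a rejection table — never silently dropped.
* Stack construction intersects the nodata masks of all layers, so one mask
  governs every statistic.
* An all-zero model yields a flat 0.5 logistic surface, zero parameters,
  all-zero contributions flagged degenerate, and zero permutation
  importance for every variable.
* Maps serialize as ESRI ASCII grids (integer-coded, with a plain-text
  legend sidecar); models serialize to JSON for exact reload. GeoTIFF is
  recognised as a format name but intentionally unsupported — there is no
  geotransform-aware TIFF reader in the package's dependency set, and a
  half-faithful reader would be worse than a clear error.

## Problem sizes used by the test-suite

The validation suite exercises the pipeline at sizes chosen to make every
stochastic check sharp but cheap: oracle-equivalence checks on hundreds of
random score sets and 50 random filter datasets; maximum-entropy fits
against an independent proximal-gradient optimizer on an 80-presence /
400-background design; parameter recovery on 100 × 100 grids with 200
presences and 10,000 background points across 10 seeds, with the
host-augmented model required to win AICc in at least 8 of 10 seeds under
full coupling and to stay unimportant (median importance < 10%) under zero
coupling; and two bit-identical full pipeline runs on a 40 × 40 grid. The
one integration check that needs the original occurrence tables and
2.5-arcmin layers is included but requires the user to supply those files
locally.

## Known limitations

* The maximum-entropy implementation is this package's own: it does not
  replicate the Java implementation's feature auto-selection, clamping,
  extrapolation flags, or training-path contribution bookkeeping, so
  importance percentages are comparable within this package only.
* Percentile and threshold conventions (midrank ties, lowest-threshold
  tie-break, score-≥-threshold rule) are fixed and documented rather than
  configurable.
* No reprojection, resampling, multi-band rasters or NetCDF; all layers
  must share one grid.
* AICc compares only models with a defined likelihood on identical data —
  here, the two maximum-entropy variants of the parasite.
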