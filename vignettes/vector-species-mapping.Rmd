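---
title: "Mapping vector sibling species with weighted boosted regression tree ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping vector sibling species with weighted boosted regression tree ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vectorsdm)
```

## The problem

Sibling species of African malaria vectors — the members of the *Anopheles
gambiae* complex and the Funestus group — are morphologically
indistinguishable and can only be told apart by molecular assays, yet they
differ in behaviour, habitat and insecticide resistance, and therefore in
the control measures that work against them. Mapping where each sibling
species occurs requires (i) presence records restricted to molecularly
confirmed identifications, (ii) a background sample that carries the same
spatial sampling bias as the presences, and (iii) a flexible model of the
relationship between occurrence and environmental covariates. `vectorsdm`
implements that workflow end to end, together with the curation and
summarisation of insecticide-resistance bioassay records for the same
species.

## The model

The core model is a weighted boosted regression tree (BRT) classifier for
a presence/background response. Writing $p_i = \sigma(F(x_i))$ with
$\sigma$ the inverse logit and $F$ an additive score, the fit minimises
the weighted Bernoulli deviance

$$D = -\tfrac{2}{\sum_i w_i}\sum_i w_i\,[\,y_i \log p_i + (1-y_i)\log(1-p_i)\,].$$

`fit_brt()` proceeds stagewise. The intercept is the log-odds of the
weighted prevalence. At each stage the pseudo-residuals $r_i = y_i - p_i$
are computed, a weighted bag of observations is drawn
(weight-proportional, without replacement, fraction `bag_fraction`), and a
small least-squares regression tree is grown on the bag: greedy binary
splits chosen to maximise the weighted sum-of-squares reduction, grown
best-first to at most `tree_complexity` terminal nodes with at least
`min_obs_leaf` bag observations per leaf. Each leaf then takes the Newton
step for the Bernoulli loss, $\sum w_i r_i / \sum w_i p_i(1-p_i)$, and the
score is updated by `shrinkage` times the tree. Relative variable
influence is the share of the total split gain attributable to each band,
normalised to 100%.

Three properties of this scheme are contractual and tested: the fit is
invariant to rescaling all weights; a weight-2 observation is equivalent
to the same observation duplicated (with bagging off and
`min_obs_leaf = 1`); and the training deviance is non-increasing when
`bag_fraction = 1`.

### Hyperparameter defaults

| parameter | default | why |
|---|---|---|
| `n_trees` | 1000 | many small steps; conventional for BRT distribution models |
| `shrinkage` | 0.005 | low learning rate, as BRT species-distribution practice recommends |
| `tree_complexity` | 5 leaves | up to 4 splits: low-order interactions without deep trees |
| `bag_fraction` | 0.75 | stochastic boosting; the common BRT-SDM default |
| `min_obs_leaf` | 5 | guards leaf Newton steps against tiny denominators |

All defaults are stored in every fitted model and in the run provenance.
An optional early-stopping mode holds out 20% of rows internally and stops
when the holdout deviance has not improved for 50 stages; the default is a
fixed tree count, which keeps submodels exchangeable across the ensemble.

## Data preparation rules

* **Presences** are molecularly confirmed records of the focal species;
  morphology-only identifications are excluded as potentially
  misidentified.
* **Background** records are all other surveys, classified by whether
  their identification methods could have detected the focal species
  (class 1) or not (class 2). Class 1 carries exactly twice the weight of
  class 2 — those surveys are informative absences in a way class 2 is
  not. By default the common factor is chosen so total background weight
  equals total presence weight; plain (2, 1) weights are available.
  Unknown method codes conservatively fall in class 2.
* **Pseudo-absences** (210 by default) are drawn uniformly from a desert
  mask: deserts are never surveyed but are known to hold no anophelines.
  They carry class-2 weight, since no survey method is attached to them.
* **Collection years** use the recorded year, the floor of the midpoint
  of a multi-year collection, or publication year minus two when no
  collection date is given. Years are clamped to the covariate range
  (2001–2012 by default) when linking records to annual layers.
* **Historical composite-taxon records** (`"gambiae_old"`: molecular
  identifications that predate the *An. gambiae* / *An. coluzzii* split)
  are resolved geographically: outside the buffered *An. coluzzii* range
  they can only be the new *An. gambiae* and are relabelled; inside the
  overlap of both buffered ranges they are ambiguous and discarded.
  Records inside the buffered *An. coluzzii* range but outside the
  overlap cannot be attributed either way; we discard them under a
  distinct reason code rather than guess, and the counts are reported.

## Ranges and geometry

A species range is a union of buffered shapes: each shape is a polygon
ring (or a degenerate point, standing for a disc) plus a buffer distance,
and a point belongs to the shape if it is inside the ring or within the
buffer distance of its boundary. This makes the two operations the
pipeline actually needs — membership tests and buffering — exact:
`buffer_range()` adds to the per-shape distance rather than offsetting
polygons. The cost is that areas have no closed form; `range_area()`
rasterises the membership predicate on a fine grid, with error of order
boundary length × cell size (the tests verify the buffered unit square
against its closed form $1 + 4d + \pi d^2$ to 1%).

Ranges are extended to encompass confirmed records found outside them by
unioning a disc around each such point. The field workflow this package
reproduces does not fix how far a range should grow around a new record;
we use a 25 km disc
(configurable) — enough to encompass the location without inflating the
range. Composite (complex/group) ranges are the union of member ranges
followed by extension with the pooled presences. The final maps are masked
to the range plus a 300 km buffer, pixel centres deciding membership.

In synthetic worlds all geometry is planar, in kilometre units with
1 pixel = 5 km, which mirrors the 5 × 5 km mapping resolution while
avoiding geodesic machinery in tests; the `crs_tag` field marks planar
versus geographic data so the two are never mixed silently.

## The ensemble and its summaries

`fit_ensemble()` fits `n_submodels` (default 200) BRTs, each to an
independent bootstrap of the training points. The bootstrap is stratified
by label by default — presences resampled among presences, background
among background, class sizes preserved — because a pooled bootstrap can
produce single-class resamples that cannot be fitted; pooled resampling is
available by flag. Submodel seeds are derived deterministically from the
master seed, so results do not depend on fitting order or parallelism.

`summarise_ensemble()` predicts every submodel at every valid pixel of the
chosen year's covariates (the most recent by default) and reduces the
per-pixel distribution to its mean, median and 0.025/0.975 quantiles
(type-7 linear interpolation, the standard default; recorded in
provenance). Per pixel the contract `q_low ≤ median ≤ q_high` is asserted;
the mean is not forced inside the quantiles. Note that the outer sample
quantiles of a small ensemble are biased narrow — the extremes of 10
draws underestimate a 95% interval — so the interval width typically
*grows* toward its converged value as submodels are added; the tests
assert convergence of the width, not shrinkage.

## Validation

A random 10% of *locations* (not records) is withheld from each of the
presence and background sets — co-located records must never straddle the
split, and the withheld count is rounded half-up with a minimum of one.
The mean map is scored at the withheld points and summarised by the
rank-based (Mann–Whitney) AUC with ties counted one half: the probability
that a random presence outranks a random background point. The fast rank
implementation is checked against brute-force pair enumeration.

Whether the original workflow sampled 10% of pooled locations or 10%
within each set is ambiguous; we read "from both the presence and
background datasets" as within-each (so small presence sets are always
represented in the test data) and expose pooled sampling by flag.

## The synthetic world

Because the compiled occurrence database and the real 5 × 5 km covariate
and range layers are not redistributable, every stage is exercised against
seeded synthetic worlds with known ground truth (`generate_world()`):

* **Covariates** are Gaussian-filtered white-noise fields (filter width —
  FWHM — of `grid_width / 8` pixels), standardised, drifting across years
  by a small additive smooth perturbation (s.d. 0.1). Bands are
  independent by default; an optional `band_correlation` parameter chains
  them with a common correlation.
* **Suitability** is the inverse logit of a linear predictor over the
  active bands, evaluated on the most recent year. The defaults — two
  active bands of eight, coefficients 3, intercept −1 — describe a species
  that is locally prevalent but globally rare across the surveyed domain,
  as the mapped vector species are. Under these conditions a default
  world yields roughly 300 presences and 600 survey background records,
  and the *true* suitability surface separates withheld presences from
  background at AUC ≈ 0.88 (median over seeds).
* **The desert** covers the most environmentally hostile corner of the
  world: the `desert_fraction` (15%) of pixels with the lowest linear
  predictor, perturbed by an independent smooth field so borders are
  irregular. This mirrors why deserts work as pseudo-absences in the real
  workflow — they are environmentally extreme, not randomly placed.
* **Surveys** are drawn from spatial clusters (centres uniform on
  non-desert pixels; scatter s.d. 20 km), re-drawn if they land in desert
  or off the grid — the deliberate sampling bias that the bias-matched
  background corrects for. Each survey uses a molecular, focal-capable
  method with probability 0.7; capable surveys become presences with
  probability equal to the pixel's true suitability, otherwise class-1
  background; non-capable surveys are class-2 background. All uniform
  draws are stored, so tests can regenerate the labels exactly.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate — includes real geography (coastlines, country
borders, true desert covariate semantics), gazetteer/geocoding error,
spatially structured identification effort, covariate collinearity beyond
the optional single-parameter chain, and inter-annual covariate trends
with direction (drift is exchangeable noise). Results on synthetic worlds
validate the machinery, not the published maps.

It is worth stating what the AUC of even a perfect map can be under this
design: capable surveys that failed to find the species sit at moderately
suitable sites, and class-2 surveys sit anywhere, so the achievable AUC
for the *true* suitability is far below 1 (≈ 0.85–0.90 here) — consistent
with the 0.78–0.87 range reported for real sibling-species maps. The
fitted ensembles track that ceiling within about 0.02.

## Resistance bioassay summaries

Bioassay records carry a species-composition vector, insecticide class,
year, country and percent mortality. Records are kept only if molecularly
identified and if more than 95% (strictly; the boundary case is excluded,
and the threshold is configurable) of the sample belongs to one species;
mixed samples and non-molecular records are tallied separately rather than
deleted. Years bin into the reporting periods ≤2000, 2001–2005, 2006–2010,
2011–2015 (and subsequent five-year bins); a species × insecticide-class
group with fewer than 10 records collapses to a single all-years bin.
Summaries report n, min, max and the unweighted arithmetic mean mortality
(the record, not the mosquito, is the unit) with the sorted list of
countries sampled.

## Numerical choices

* Split thresholds are midpoints between consecutive distinct feature
  values; ties in gain resolve to the lowest feature index, then the
  lowest threshold — fits are bit-reproducible given a seed.
* Leaf-value denominators are floored at 1e-12 against pure-leaf blowups.
* Bagging uses weight-proportional sampling without replacement
  (exponential-key method), which preserves the 2:1 background weighting
  inside bags and is invariant to weight rescaling.
* Pixels are half-open with the origin at the upper-left: a point on an
  interior boundary deterministically belongs to the pixel to its
  east/south.
* Rasters are exchanged as ESRI ASCII grids written with 17 significant
  digits (doubles round-trip exactly); model JSON uses the same precision.
* The problem sizes used throughout the test-suite recovery experiments —
  64 × 64 pixel worlds, ~900 surveys, ensembles of 10–20 submodels of
  1000 trees, ten seeds — are the package's chosen test conditions,
  scaled down from the 200-submodel production ensembles the pipeline
  defaults to.

## Known limitations

* Geographic-CRS buffering is delegated to the planar engine after a
  metric projection chosen by the caller; the synthetic pipeline never
  exercises geodesic buffers.
* The purity threshold reading (">95%" strict) and the fate of
  unresolvable historical records are judgement calls, flagged above and
  surfaced as configuration or reason codes.
* Presence–background AUC is not comparable across species with different
  background structures; the per-species reports carry the class counts
  needed to interpret it.
* No spatial cross-validation: the location-withheld split matches the
  original workflow, and spatially blocked validation is out of scope.
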