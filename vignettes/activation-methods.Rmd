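---
title: "Measuring neighborhood activation and modeling park use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neighborhood activation and modeling park use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkactivation)
```

## The measurement model

The package operationalizes "neighborhood activation" — the condition of a
neighborhood's establishments being populated and in use — from
Popular-Times-style data: for each establishment, a 7×24 integer matrix of
relative popularity (rows Monday-first days, columns local hours 0–23,
values 0–100 with 100 marking the establishment's single busiest hour of
the week and 0 meaning closed or unused).

Three park-level exposures are computed over the establishments inside a
buffer around the park's observed target areas:

1. **Density**: the establishment count. As a covariate it is Z-scored
   across parks (sample SD, divisor *n*−1) so its effect is per standard
   deviation and comparable between data sources of very different
   coverage.
2. **Diversity**: the number of distinct broad establishment types. Raw
   category strings are harmonized into 15 broad types by a swappable
   `category_map`; the shipped default covers common Google-Places-style
   categories, and any replication can supply its own `raw,type` CSV —
   the diversity statistic requires only a consistent partition, not one
   canonical mapping.
3. **Activation evenness**: each establishment's mean daily popularity
   vector (hourly mean over the seven days) is pooled across the buffer
   and normalized over the 24-hour day into the *activation distribution*
   — hour *h*'s entry estimates the conditional probability that a
   visitor to any buffer establishment on an average day is present at
   hour *h*. The park's measure is the Euclidean (L²) norm of this
   24-vector: 1/√24 ≈ 0.204 for perfectly even activation, 1 for
   single-hour concentration. The L² norm is scale invariant (doubling
   all popularity changes nothing), permutation invariant in hours, and
   increases under any transfer of probability mass from a quieter to a
   busier hour, which is exactly the ordering a concentration measure
   must respect.

A popularity value of 0 participates in the sums like any other
magnitude; no open/closed distinction is drawn beyond the data itself.

### The daytime sensitivity window

`l2_norm_windowed()` recomputes the norm using only hours in a window
(default 9 through 19, i.e. the 9am hour through the 7pm hour, bracketing
typical observation times). The denominator is **renormalized within the
window** by default, so the result is the norm of a proper distribution
over *k* window hours and keeps the interpretable range [1/√k, 1]. An
alternative reading keeps the full-day denominator; both are available
(`renormalize = FALSE`), the renormalized form is the default because it
preserves the bounds interpretation. A window containing no popularity
mass is a degenerate input and errors rather than returning NaN.

### Degenerate inputs

All-zero popularity in a buffer means the activation distribution is
undefined; the package raises a typed degenerate-input error
(`pa_degenerate_error`) instead of propagating NaN into the model tables.
Structurally malformed input (wrong matrix shape, out-of-range values,
orphan scans, single-cluster model tables) raises `pa_structural_error`.
This separation lets pipelines distinguish "fix your file" from "this
park has no measurable activation".

## Buffers and geometry

Buffers are Minkowski dilations of the target-area geometries by a radius
(default 250 m), unioned per park. Because no planar geometry engine is
assumed, the package works from the exact distance function:

- **Containment** is `distance(point, geometry) ≤ radius` (closed: a
  boundary point counts as inside, a deterministic tie rule). This is
  exact for points and polygons alike.
- **Area** for point target areas is computed exactly as the area of a
  union of equal discs, by removing the covered arcs of each circle and
  integrating the remaining boundary with Green's theorem. A single disc
  evaluates to πr² to machine precision; overlapping pairs are verified
  in the tests against the two-circle lens closed form. Buffers with
  polygon target areas fall back to a fine-grid area (documented accuracy
  of a few tenths of a percent); their containment remains exact.

Coordinates must already be projected metric. A helper
(`lonlat_to_local()`) provides a local equirectangular projection for
WGS84 inputs; at city scale (≲20 km) its distance distortion is below
about 0.1%, verified in the tests against geodesic distances. Buffers of
neighboring parks may overlap and an establishment may legitimately count
toward several parks; no cross-park deduplication is performed.

## Imputation onto exhaustive listings

Only a small fraction of establishments carry observed popularity.
`impute_popularity()` assigns each popularity-less establishment a copy
of the weekly matrix of the *nearest same-type* establishment that has
one. Choices made where the procedure is underdetermined:

- "Nearest" is planar Euclidean distance in projected meters, consistent
  with the buffer construction.
- The candidate pool is the full reference set, not just the same
  buffer: that is the plain reading of "nearest establishment of the same
  category", and it is the more permissive choice.
- Exact distance ties break to the lexicographically smallest reference
  id, for reproducibility.
- A type with no reference anywhere is an error under the strict policy;
  the lenient policy falls back to the nearest reference of any type and
  flags the row in the provenance record (`target_id`, `source_id`,
  `distance_m`, `fallback`).

Imputed matrices are bitwise copies; the tests verify equivalence against
an exhaustive O(n·m) search.

## The outcome model

The outcome is the person count of one instantaneous scan of one target
area. Counts are modeled marginally with Poisson generalized estimating
equations, log link, **parks as clusters** (target areas and repeated
rounds within a park are correlated), with no exposure offset — scan
counts are instantaneous and comparable across parks of different sizes.
Three fixed configurations form the battery, every one controlling for
Z-scored density and park quality (CPAT, the mean of six 0–100 domain
scores, taken as already standardized — the package does not invent a
domain rescaling):

| model | focal covariates |
|---|---|
| `types_only` | diversity |
| `l2_only` | activation L² |
| `types_plus_l2` | both |

Under the mediation hypothesis (diversity → even activation → use), the
diversity coefficient should shrink when L² joins the model; the battery
reports this attenuation explicitly.

Numerical choices:

- **Working correlation**: exchangeable by default (the conventional
  choice for cluster-level exposure designs), independence available. A
  regression test asserts that per-SD coefficient estimates agree closely
  between the two and that no clearly significant result under one
  becomes clearly null under the other.
- **Robust variance**: the cluster sandwich, by default with the
  Mancl–DeRouen bias correction — each cluster score is premultiplied by
  (I − H)⁻¹, computed cheaply through the Woodbury identity as
  (I − BᵢB⁻¹)⁻¹. With a modest number of clusters (twenty parks) the
  uncorrected sandwich is biased downward and its nominal 95% intervals
  cover noticeably below 95%; the corrected estimator restores coverage
  close to nominal, which the 200-replicate recovery test measures
  directly. The classical sandwich remains available
  (`correction = "none"`), and both variants are cross-checked in the
  tests against independent implementations (statsmodels GEE and
  `glm` + `sandwich::vcovCL`). If a cluster has leverage one the
  correction factor is singular and a Moore–Penrose inverse is used.
- **Intervals**: estimate ± 1.96 × robust SE on the log scale, with
  significance marked at p < 0.05 — the presentation convention of the
  field's results tables.
- Fisher scoring is initialized at the Poisson GLM estimate and iterated
  to a 1e-10 relative step tolerance; non-convergence is flagged on the
  returned object and warned about, never silent. A single cluster or a
  rank-deficient design is a structural error.

`compare_measures()` (Pearson r with the t-based two-sided p on n−2 df)
quantifies agreement between the observed-data and imputed-data versions
of each park measure.

## What the synthetic generator emulates

`gen_study()` generates a complete study with magnitudes taken from the
design it emulates: 20 parks, 4–13 point target areas each, 250 m
buffers, about 10,000 scans (8 visits × 2–3 periods × 1–4 completed
rounds × all target areas), a grand mean near 5 persons per scan, CPAT
overall scores mostly in the 45–65 range, exhaustive listings of
300–3000 establishments per park vicinity of which 6% carry observed
popularity — so the observed subsets land in the tens-to-low-hundreds
per buffer. Type frequencies are heavily skewed (a few ubiquitous types,
a long rare tail), so diversity varies across parks even for exhaustive
listings. Popularity matrices follow per-type 24-hour base shapes
(day-peaked retail, night-peaked bars, bimodal transit, ...) with
multiplicative lognormal day and cell noise, rescaled so the weekly
maximum is exactly 100.

Scan counts are drawn as Poisson(exp(β·x + u)) where x are the park's
*actual computed* exposures and u is a park-level normal random intercept
(default SD 0.3 on the log scale). The random intercept is essential: it
induces genuine within-park correlation, so the cluster-robust machinery
is exercised rather than vacuously correct. Default planted coefficients
are small associations of the magnitude such studies report; all latent
parameters are returned in a truth record, and every run is fully
determined by a single seed.

`effect_scale = "standardized"` plants coefficients per standard
deviation of each covariate (and the recovery tests fit with identically
standardized covariates). This choice is deliberate: across twenty parks
the raw L² norm varies by only a few hundredths, so a raw-scale L² slope
carries a per-fit standard error of several units, and no finite
simulation could distinguish a small bias from noise on that scale.
Standardization makes "bias below 0.05" a property of the estimator
rather than of the covariate's units. The qualitative-pattern experiment,
by contrast, fits the battery's raw-covariate models exactly as
specified, with a planted per-SD density effect of 0.25 — chosen a
priori as a moderate effect detectable at twenty clusters (roughly
z ≈ 3.7 given the random-intercept scale), so the experiment tests the
battery's logic rather than raw statistical power.

What the generator does **not** emulate: real street geography (parks sit
on a well-separated grid, so cross-park buffer overlap never occurs in
synthetic data, although the package allows it), day-of-week or seasonal
scan scheduling structure, establishment-level popularity heterogeneity
beyond lognormal noise around type shapes, and any systematic
non-representativeness of which establishments carry popularity
(coverage is missing completely at random). Passing tests on synthetic
data therefore demonstrate correctness of the computations and honest
frequentist behavior of the estimator under the stated design — not that
real Popular-Times coverage is unbiased, which is a known limitation of
the data source itself.

## Problem sizes used by the test suite

The oracle-equivalence suites use 1,000 random establishment sets (L²)
and 100 random imputation instances of 200 targets × 30 references. The
recovery experiment fits 200 replicate studies at the full design scale
(20 parks, ~10,000 scans each) and checks mean bias (< 0.05 per SD) and
empirical CI coverage (within [90%, 99%]); the pattern experiment runs
100 replicates of the three-model battery. Pipeline-level tests run on
reduced establishment listings, which changes nothing structural.

## Known limitations

- Polygon target areas: containment and buffering are exact, but the
  buffer *area* uses a grid approximation and GeoJSON export of dilated
  polygons is not provided. Point target areas (the common case for
  playground/court/field centroids) are exact end to end.
- The windowed L² has two defensible denominators; the package defaults
  to within-window renormalization and does not claim the alternative is
  wrong.
- The GEE implementation covers the Poisson/log case with exchangeable
  or independence working correlation — the scope this design needs —
  not a general GEE framework.
- Reference-period mismatch between an exhaustive listing and the
  popularity source (e.g., listings and profiles collected years apart)
  is not modeled; inputs are treated as contemporaneous.
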