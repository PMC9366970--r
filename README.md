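# parkactivation

Neighborhood activation measures and clustered Poisson models of park use.

## The problem

Whether mixed-use neighborhoods increase use of their parks is usually
studied with land-use-mix indices that confound *how much* commercial
activity surrounds a park with *how varied* it is. This package implements
an alternative measurement strategy built from establishment-level hourly
popularity profiles (Popular-Times-style data): within a metric buffer
around each park's observed target areas it computes

- **land-use density** — the number of establishments in the buffer;
- **commercial activity diversity** — the number of distinct broad
  establishment types (restaurant, retail/services, grocery, ...) present;
- **temporal activation evenness** — the L² norm of the buffer's daily
  activation distribution.

For establishment *i* (of *n* in a buffer) let **pop**ᵢ be its mean daily
popularity vector (the mean over the seven weekdays of its hourly 0–100
popularity). The activation distribution gives, for each hour *h*, the
estimated conditional probability that a visitor to any buffer
establishment on an average day is there at hour *h*, and the park's
evenness measure is its Euclidean norm:

```
L² = sqrt( Σₕ [ Σᵢ popᵢ,ₕ / Σₕ Σᵢ popᵢ,ₕ ]² ),   h = 0, …, 23
```

L² ranges from 1/√24 ≈ 0.204 (perfectly even activation through the day)
to 1 (all activation concentrated in a single hour); larger values mean a
*less* even neighborhood rhythm. A windowed variant recomputes the norm
over a daytime window (default the 9am through 7pm hours).

Around these measures the package provides:

- nearest same-type popularity **imputation** onto exhaustive (NETS-style)
  establishment listings, with a provenance record;
- exact 250 m **buffer geometry** (union-of-discs areas via Green's
  theorem, distance-based containment) without requiring a geometry engine;
- **Poisson GEE** models of SOPARC-style scan counts (one instantaneous
  person count per target-area scan) clustered by park, with
  Mancl–DeRouen bias-corrected cluster-robust 95% CIs, in a three-model
  battery that inspects whether the diversity coefficient is attenuated
  when the hypothesized mediator (L²) enters the model;
- a seeded **synthetic-data generator** reproducing the full study design
  (20 parks, 4–13 target areas, ~6% popularity coverage, clustered
  counts), used by the test suite for oracle and parameter-recovery
  checks.

## Worked example

```r
library(parkactivation)

study <- gen_study(sim_config(seed = 42))
head(study$contexts[, c("park_id", "n_establishments", "n_types",
                        "l2", "l2_windowed", "cpat")])
#>   park_id n_establishments n_types    l2 l2_windowed cpat
#> 1  park01               61      11 0.242       0.305 56.5
#> 2  park02               18       9 0.234       0.306 61.8
#> 3  park03               85      10 0.241       0.306 52.6
#> 4  park04               87      10 0.236       0.305 57.3
#> 5  park05               84      12 0.236       0.304 64.7
#> 6  park06              132      10 0.240       0.305 50.0

tab <- build_analysis_table(study$scans, study$contexts)
fit_gee(tab, "l2_only")
#> Poisson GEE (exchangeable working correlation), 12498 scans in 20 parks
#> estimated alpha: 0.2687
#>                term estimate                ci
#>         (Intercept)    3.192  (-7.862, 14.246)
#>                  l2   -7.416 (-50.603, 35.771)
#>  n_establishments_z    0.008   (-0.125, 0.140)
#>                cpat    0.003   (-0.021, 0.028)
```

Each row of `study$contexts` is one park: 18–132 establishments with
observed popularity in its buffer, 9–12 broad types, and an activation L²
close to the uniform bound (these synthetic neighborhoods are active most
of the day, so evenness varies in a narrow band — as it does in dense
urban data). In the `l2_only` model the L² coefficient is a log
rate-ratio per unit of L²; since L² only spans a few hundredths, its CI is
wide. `n_establishments_z` is the density effect per standard deviation
of the establishment count.

Imputing popularity onto the full listing and comparing measure sets:

```r
imp <- impute_popularity(study$establishments, policy = "lenient")
ctx_full <- compute_park_contexts(imp$establishments, study$buffers, study$cpat)
compare_measures(study$contexts$n_establishments, ctx_full$n_establishments)
#> observed vs imputed establishment count: r = 0.964, p = 8.2e-12
```

The whole pipeline (read inputs → types → buffers → measures → imputation
→ GEE battery → comparisons, with all artifacts written as CSV/GeoJSON)
is available as `run_pipeline()` on a `run_config()`, or from a shell via
`Rscript inst/cli/parkactivation.R run --config cfg.json`.

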