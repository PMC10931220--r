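# nichetrap

Spatial niche analysis for capture-mark-recapture (CMR) live-trapping
studies of small-mammal communities.

Coexisting rodents can partition space rather than food or time: each
species concentrates its activity on a subset of the available habitat
patches, and the width of that subset — and how much it is shared with
other species — is shaped by vegetation structure, soil, climate, and the
other species themselves. `nichetrap` implements the full quantitative
chain for asking those questions from seasonal PIT-tag trapping data:

* **Abundance** — minimum number known alive per session,
  `MNKA = a + b`, where `a` individuals were caught in the session and
  `b` marked individuals were caught before *and* after it but not during
  (known alive by bracketing);
* **Spatial niche breadth** — normalized Shannon entropy of a species'
  per-plot use, `B_i = [lg N_i − (1/N_i) Σ_j N_ij lg N_ij] / lg r ∈ [0, 1]`;
* **Spatial niche overlap** — the Colwell-Futuyma / Schoener
  proportional-similarity index
  `O_ik = 1 − ½ Σ_j |N_ij/N_i − N_kj/N_k| ∈ [0, 1]`;
* **Habitat indices** — shrub average height, density, coverage
  (`C = 3.14·SR²·Den/100 m²`), total coverage and biomass, plus Shannon,
  Gini-Simpson and Pielou diversity, assembled into a plot × 31-factor
  table;
* **Factor screening** — seeded random-forest permutation importance
  against a shadow-feature ensemble (the "Mean"/"MAX" rule), followed by
  iterative variance-inflation-factor filtering at VIF ≥ 10;
* **Ordination** — Hellinger transformation, redundancy analysis (RDA)
  with Ezekiel-adjusted R², permutation pseudo-F tests, and
  `ordiR2step`-style forward selection with the double stopping rule —
  all implemented from first principles and cross-checked against
  independent oracles (including `vegan`) in the test suite;
* **Synthetic studies** — a seeded generator emulating a multi-year
  desert trapping design (24 plots × 7×8 trap grid × 4 days × 3 seasons ×
  5 years = 80,640 cage-days) with known latent truth, so every stage is
  testable without field data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` summaries for fitted objects, and `autoplot()` figures.

## Worked example

Simulate a complete virtual study and run the whole pipeline:

```r
library(nichetrap)

cfg   <- sim_config()                      # the default 5-year design
study <- simulate_dataset(cfg, seed = 42)  # captures + environment + truth

mnka_tbl <- mnka_table(study$captures)
breadth  <- niche_breadth(mnka_tbl)
summarize_by_season(breadth)
#> # A tibble: 12 × 5
#>    species season  mean      se n_years
#>  1 MZ      spring 0.830 0.0156        5
#>  2 MZ      summer 0.793 0.0142        5
#>  3 MZ      autumn 0.792 0.0109        5
#>  4 SZ      spring 0.933 0.00710       5
#>  ...
#> 10 ZW      spring 0.945 0.0156        5
#> 11 ZW      summer 0.962 0.00431       5
#> 12 ZW      autumn 0.962 0.00291       5
```

Each row is one species-season: the mean spatial niche breadth across the
five study years with its standard error. The concentrated hamster (`MZ`,
simulated with a low occupancy-evenness α) sits near 0.8 while the
generalist gerbil (`ZW`) approaches the uniform-use ceiling of 1 — the
ordering the generator was configured to produce.

The environmental stages run from the same bundle:

```r
res <- run_pipeline(data = study, config = cfg, seed = 42)

res$vif_report
#> <vif_filter> threshold 10
#>   retained: 25 factor(s)
#>   removed: H.G, E.S, H.S, D.G, D.R

glance(res$rda)
#> # A tibble: 1 × 5
#>      r2 adjusted_r2 total_variance n_samples n_factors
#> 1 0.802       0.787          0.147       358        25

res$permutation
#> <rda_permutation> F = 53.732  p = 0.001  ( 999 permutations )

tidy(res$forward)
#> # A tibble: 5 × 6
#>   order factor     r2 adjusted_r2 pseudo_F p_value
#> 1     1 MZ     0.285        0.283    142.    0.001
#> 2     2 WZ     0.190        0.473    129.    0.001
#> 3     3 SZ     0.175        0.647    177.    0.001
#> 4     4 ZW     0.0922       0.739    126.    0.001
#> 5     5 H.R    0.0409       0.780     66.4   0.001
```

The VIF filter drops five collinear diversity indices; the RDA of the
Hellinger-transformed species block on the retained factors explains 80%
of total variance (adjusted R² 0.79), the global permutation test is at
its p floor, and forward selection admits the four species' population
sizes and the rodent Shannon index — exactly the biotic coupling the
generator builds in, since each species' plot use is the other species'
"environment". With `outdir =` set, `run_pipeline()` writes the full CSV
and JSON report bundle plus a seeded manifest.

`autoplot(res$rda)` draws the RDA triplot, `autoplot(res$screens$...)` an
importance histogram with the shadow Mean/MAX thresholds, and
`plot_mnka_trend(mnka_tbl)` the seasonal abundance series.

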