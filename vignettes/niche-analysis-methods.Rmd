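---
title: "Methods: spatial niche analysis of live-trapping studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial niche analysis of live-trapping studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nichetrap` implements the quantitative chain used to ask how a community of
coexisting small mammals partitions space, and which habitat features drive
that partitioning: capture-mark-recapture abundance estimation, spatial
niche breadth and overlap indices, habitat structure indices, machine-
learning screening of environmental factors, and constrained ordination
with permutation-based forward selection. This vignette documents the
models, the assumptions behind them, the tunable parameters, and the design
choices made where the methodology was genuinely open.

## Study design and abundance estimation

The package is organized around a seasonal live-trapping design: a set of
one-hectare plots, each holding a 7 x 8 grid of live traps at 15 m spacing,
checked twice daily (morning, afternoon) for 4 consecutive days, in spring,
summer and autumn of each study year (winter is not trapped; several desert
rodents hibernate). Every captured animal carries a PIT tag, so capture
records resolve to known individuals. The default design (24 plots, 5
years) places 56 x 24 x 4 x 3 x 5 = 80,640 cage-days.

A *session* is one (year, season, plot) block of 4 trapping days. Within a
session, recaptures of the same individual collapse to a single presence:
the abundance estimator operates at session granularity, and whether the
two daily checks were ever treated as separate occasions is not something
the session-level estimator can use.

Abundance per session is the **minimum number known alive** (MNKA):

$$\mathrm{MNKA}_t = a_t + b_t$$

where $a_t$ is the number of individuals actually caught in session $t$ and
$b_t$ the number of marked individuals caught both before and after $t$ but
not during it — they were necessarily alive at $t$. $b$ is zero at the
first and last sessions by construction, which gives MNKA a known negative
bias that is worst at the endpoints of a study: with constant true
population size and constant capture probability, the mean MNKA series
peaks at interior sessions. The test suite reproduces this endpoint bias
over 500 replicate simulated studies; `sim_config(buffer_session = TRUE)`
appends a trailing session so the final study year's $b$ term is informed,
mirroring the practice of extending trapping one season past the analysis
window.

MNKA is an estimator, not truth: with per-check detection probability $p$
and eight checks per session, per-session detection is $1-(1-p)^8$, high
but below one, and individuals alive yet never caught on either side of a
gap are invisible. Recovery tests therefore compare against simulator
truth with this documented negative bias; equality with truth is asserted
only at $p = 1$.

Densities divide counts by the effective trapped area, 1 ha per plot by
default (configurable: a 7 x 8 grid at 15 m spans 90 m x 105 m = 0.945 ha,
and boundary-strip conventions differ). The `log10(n + 1)` transform used
for right-skewed density data is exposed as an explicit function and never
applied silently.

## Niche breadth and overlap

Spatial niche breadth treats each survey plot as one resource level. With
$N_{ij}$ the use of plot $j$ by species $i$ (its per-plot MNKA for the
year-season) and $N_i = \sum_j N_{ij}$:

$$B_i = \frac{1}{\lg r}\left[\lg N_i - \frac{1}{N_i}\sum_j N_{ij}\,
\lg N_{ij}\right]$$

which is algebraically the normalized Shannon entropy $H/\log r$ of the
use proportions — 0 when one plot is used, 1 when use is uniform over all
$r$ plots. Two notes on this formula as commonly printed:

* Renderings of the bracketed term as a quotient
  ($\sum N_{ij} / \lg N_{ij}$) cannot keep $B_i$ in $[0,1]$ and do not
  reduce to the Shannon-Wiener construction; the product form
  $\sum N_{ij} \lg N_{ij}$ is the only self-consistent reading and is what
  `breadth_index()` computes. The test suite pins the identity
  $B_i = H/\log r$ to 1e-12 against an independent entropy oracle.
* The base-10 logarithm is conventional but immaterial: the base cancels
  in $H/\log r$, which the suite also asserts.

Zero-use plots contribute nothing; an all-zero row (species absent for a
season-year) is undefined and returned as `NaN` with a notice, and such
rows are excluded from summaries.

Pairwise spatial overlap uses the proportional-similarity form
(Colwell-Futuyma / Schoener):

$$O_{ik} = 1 - \tfrac12 \sum_j \left|\frac{N_{ij}}{N_i} -
\frac{N_{kj}}{N_k}\right|$$

one minus half the L1 distance between plot-use proportion vectors: 0 for
disjoint use, 1 for identical proportions, invariant to rescaling of
either vector.

Both indices are computed per year and then summarized per season as mean
± standard error across years. The across-years grouping is the one
choice that yields a standard error per season in a multi-year design
(n = number of years); a single year yields se = 0 by convention.

## Habitat productivity and concealment indices

Shrub structure is summarized by five indices per quadrat record, then
averaged over the (three) quadrat replicates per plot:

* average height $AH = (LH + MH + SH)/3$ over the large, medium, small
  height classes (cm); records missing a class can exclude it from the
  mean rather than propagating missingness;
* density $Den = IN / 100\,\mathrm{m}^2$;
* per-species coverage $C = (3.14 \times SR^2 \times Den)/100\,
  \mathrm{m}^2$, reported in percent. $SR$ is recorded in cm; it is
  converted to metres before this formula is applied — the only unit
  reading under which coverage is a sane fraction (a shrub of 0.5 m canopy
  radius at density 4 per 100 m² covers $3.14 \cdot 0.25 \cdot 4 / 100 =
  3.14\%$). The constant 3.14 is used verbatim rather than `pi` so the
  computation matches the printed convention of the field protocol;
* total coverage $TC.S = \sum_i C_i$, allowed to exceed 100% for
  overlapping canopies (warned, not truncated);
* biomass $TB = (P \times DW \times Den)/100$ in g/m², with $P$ the
  sampled fraction of current-year branches and $DW$ the dry weight.

Community diversity uses the standard forms these index names denote:
Shannon $H = -\sum p \ln p$, Gini-Simpson $D = 1 - \sum p^2$, Pielou
$E = H/\ln S$ (undefined for $S = 1$). The factor catalogue lists the
rodent and shrub Shannon indices under the same acronym in some sources;
the package disambiguates them as `H.R` (rodents) and `H.S` (shrub).

`assemble_factor_table()` joins all sources into one row per (plot,
season, year) with 31 factor columns — 7 biotic (rodent diversity indices
and per-species population sizes) and 24 abiotic (shrub and grass
structure/diversity, four soil moisture and four soil hardness layers,
monthly temperature, humidity and sunshine joined via the trapping month
of each season: April, July, October). Replicates are averaged; missing
cells are flagged `NA` with a warning, never imputed; an unmappable
meteorology key is a hard error.

## Factor screening

Which of the 31 factors matter for a species' niche breadth is screened
with a seeded random-forest regression and a shadow-feature calibration:
each factor is accompanied by `shadow_copies` row-permuted copies of
itself, which preserve the marginal distribution while destroying any
association with the response. Permutation importance is computed for all
columns; the mean ("Mean") and maximum ("MAX") of the shadow importances
define the thresholds — factors above Mean have high contribution, above
MAX very high contribution.

The thresholds need calibrating because under a pure-noise response the
real and shadow columns are exchangeable: with one shadow per factor, the
chance that *some* real factor exceeds MAX is exactly 1/2. The default of
19 shadow copies per factor makes that family-wise chance
$\approx 1/(1+19) = 5\%$, the conventional error level, at modest extra
cost (the forest backend, `ranger`, handles the widened matrix quickly).
The screen is bit-reproducible for a fixed seed and input ordering, and
is a filter, not a predictor: no tuning, no cross-validation.

Multicollinearity among the pooled selected factors is then removed by
iterative VIF filtering: $VIF_j = 1/(1 - R^2_j)$ from regressing factor
$j$ on all others, dropping the single worst column while any VIF meets
the threshold (10, the usual strong-multicollinearity cut), recomputing
after each removal. Ties on the maximum break toward the later column;
exact collinearity yields `Inf`, not an error. The retained set always
satisfies max VIF < 10, asserted on every run.

## Ordination

The species block — per-(plot, season, year) use values of the focal
species — is Hellinger-transformed (row-wise square root of proportions),
which makes Euclidean-based linear ordination appropriate for
abundance-like data; the factor block is standardized. Redundancy
analysis is implemented from first principles: canonical eigenvalues come
from the singular value decomposition of the fitted values of the
multivariate least-squares regression of the centered response on the
factors, residual eigenvalues from the residuals, with

$$R^2 = \frac{\sum \lambda_{canonical}}{\text{total variance}},\qquad
R^2_{adj} = 1 - (1 - R^2)\frac{n-1}{n-m-1}$$

(Ezekiel's adjustment, $m$ = number of factors). Variance conservation
(canonical + residual = total, tolerance 1e-8) and agreement with an
independent brute-force projection oracle — and with `vegan::rda` — are
asserted in the tests. Biplot scores are correlations of the factors with
the canonical site scores (type-2 scaling convention).

Model significance uses a permutation pseudo-F test,
$F = (\sum\lambda_c/m) / (\sum\lambda_r/(n-m-1))$, with unrestricted row
permutation of the response (no stratification) and the add-one p-value
rule $p = (1 + \#\{F_\pi \ge F_{obs}\})/(1 + n_\pi)$, so $p$ is never 0
and its floor at the default 999 permutations is 0.001. A seed is
mandatory wherever permutations occur.

Forward selection follows `ordiR2step` semantics — the double stopping
rule of Blanchet and colleagues: at each step the candidate with the
largest adjusted $R^2$ of the extended model is considered; selection
stops if that adjusted $R^2$ fails to improve on the current model or
would exceed the full model's adjusted $R^2$ (the scope), otherwise the
candidate is admitted if its *conditional* permutation test — residuals
of the response on the already-selected factors are permuted
(reduced-model permutation) — has $p \le \alpha$ (default 0.05).
Conditional rather than marginal testing at each step matches the
reference semantics of `ordiR2step`.

One behavior of this rule is worth knowing. The adjusted $R^2$ is
calibrated so that adding pure-noise factors leaves its expectation
unchanged; a consequence is that when exactly one factor is informative
and the rest are noise, the signal-only model's adjusted $R^2$ and the
full model's are statistically indistinguishable, and the scope check can
halt the selection before any admission — `vegan::ordiR2step` behaves
identically on such data. The rule trades power in that corner case for
strong null control: under an all-noise design it admits on average well
under one factor per run, where an unguarded best-of-candidates
permutation test would be badly anticonservative. The suite asserts the
properties that actually hold: every nonempty selection leads with the
informative factor, and all-noise runs select almost nothing.

## The synthetic study generator

Because deposited field data do not exist for designs like this, every
stage is exercised against a generator with known latent truth:

* **Occupancy.** Per species and year, plot-use weights are drawn from a
  symmetric Dirichlet; the concentration $\alpha$ is an interpretable
  evenness dial mapping directly to expected niche breadth (the truth
  object stores each draw's exact breadth). Defaults map to the breadth
  ranking typical of such communities: a widespread generalist gerbil
  ($\alpha = 8$), two intermediate jerboas ($\alpha = 3$), a
  concentrated hamster ($\alpha = 0.8$).
* **Demography.** Expected per-season totals over the 24 plots default to
  90, 60, 40 and 30 individuals for the four species; individuals are
  plot-faithful, survive between sessions with probability 0.5 (a
  realistic seasonal survival for small desert rodents; configurable to 0
  across winter for hibernators), and shortfalls against the multinomial
  allocation are filled by newly tagged recruits — so the bracketing term
  of MNKA is genuinely exercised.
* **Detection.** Each alive individual is Bernoulli-detected per check
  with $p = 0.25$, i.e. ~90% per 8-check session.
* **Environment.** Latent plot-level factor values are baseline + linear
  links to true species densities + Gaussian noise; raw quadrat records
  are constructed so plot-level aggregation recovers the latent value
  exactly for the continuous factors (heights, soil layers, weights),
  while count-based factors (densities, diversity indices) are emergent
  Poisson draws. With the noise set to zero a linked factor is an exact
  affine function of density, which the tests assert through the full
  raw-table round trip.

What the generator does *not* emulate: within-grid spatial movement,
trap-happiness or trap-shyness, inter-plot dispersal, observation error
in the plant and soil measurements beyond the latent Gaussian noise, and
real meteorological autocorrelation. Passing tests therefore demonstrate
the estimators' algebra, calibration and recovery behavior under the
stated design — not robustness to behavioral heterogeneity in real
trapping data.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: all-zero use rows give `NaN`
with a warning (breadth, overlap), all-zero community vectors error
(diversity), all-zero response rows error by name (Hellinger), exact
collinearity gives `Inf` VIFs and a rank-deficiency error in the RDA that
points to `vif_filter()`. Eigenvalues below 1e-12 of the leading one are
treated as zero. Station indices are 0-based internally with an option to
accept 1-based labels on input.

The test suite's simulation sizes are chosen to make the statistical
assertions sharp while keeping the default run quick: 10,000 random
vectors for the index-bound sweeps, 500 replicate studies for the MNKA
endpoint-bias property, 1,000 null trials at 199 permutations for the
type-I calibration of the permutation test (n = 20 rows, 3 response
columns, 2 factors per trial), and 100 seeded runs for the
forward-selection and screening recovery rates.
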