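---
title: "Heterospecific pollen deposition and network specialization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterospecific pollen deposition and network specialization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollennet)
library(dplyr)
```

This vignette is the package's account of its methods: the statistical
models it fits, the conventions it adopts where the literature offers
several, and what its synthetic-data generator does and does not emulate.

## The scientific setting

A flowering community with generalized pollination has high pollinator
overlap: the same insects visit many plant species, so a stigma can receive
pollen from the wrong species (heterospecific pollen, HP) along with its
own (conspecific pollen, CP). Two species-level responses are
distinguished. Under **HP avoidance**, floral or behavioural mechanisms
keep HP off stigmas; HP arrival is then an occasional accident,
statistically independent of CP arrival. Under **HP tolerance**, visits
deliver CP and HP together, so HP load grows with CP load — linearly when
every visit carries a similar pollen mixture, or exponentially (in either
direction) when high-quality and low-quality pollinators visit at different
rates. The diagnostic is therefore the within-species relationship between
per-stigma CP and HP counts, classified per species, and the cross-species
question is whether floral phenotype or a species' position in the
plant–pollinator network predicts how much HP it receives.

## Network specialization indices

The interaction matrix has plants in rows, pollinators in columns, weights
`a_ij`, row totals `A_i`, column totals `A_j` and grand total `m`. The
default pipeline binarizes weights (`build_network(..., binarize = TRUE)`)
because the survey data the package mirrors are qualitative
(presence/absence of an interaction); all indices also work on quantitative
counts.

**H2′** standardizes the observed two-dimensional Shannon entropy
`H2 = −Σ p_ij ln p_ij` (`p_ij = a_ij/m`, natural logarithms throughout)
between two bounds with the observed marginals:

* `H2_max` is the entropy of the marginal outer product
  `(A_i/m)(A_j/m)`, i.e. `H(row marginal) + H(column marginal)`. This is
  the exact supremum of the joint entropy, so no heuristic is needed.
* `H2_min` is the minimum entropy over non-negative **integer** matrices
  with the observed marginals. Finding it is a combinatorial problem; the
  package uses a deterministic **multi-start greedy** allocation: for every
  feasible choice of first cell it allocates
  `min(remaining row, remaining column)` there, continues by repeatedly
  allocating the largest such amount (ties broken by lowest row index, then
  lowest column index), and keeps the lowest-entropy completion. The
  multi-start matters: a single largest-first start is provably suboptimal
  — for marginals (4,3) × (3,2,2) it commits 3 to the top-left cell and
  dead-ends at entropy 1.2770, while the optimum `[[0,2,2],[3,0,0]]`
  reaches 1.0790 and is found from a different start. Across every
  enumerated marginal family up to 3×3 with entries 1..6 and totals ≤ 12
  (4822 pairs) the multi-start greedy matches the exhaustive minimum
  (`min_entropy_exact()`), which the test suite re-verifies; global
  optimality is nevertheless not guaranteed in general, so the exhaustive
  reference remains exported.

Then `H2′ = (H2_max − H2)/(H2_max − H2_min)`, defined as 0 when the bounds
coincide, and clamped to [0,1] after two safety adjustments (the observed
matrix itself bounds the minimum from above; the independence product
bounds the joint entropy from above). 0 means interactions follow the
marginals (maximal generalization); 1 means maximal specialization.

**d′** applies the same idea per species: the divergence
`d_i = Σ_j p′_ij ln(p′_ij/q_j)` of partner use `p′_ij = a_ij/A_i` from
availability `q_j = A_j/m` is standardized between `d_max = ln(m/A_i)` and
an integer-allocation minimum (`d_min_heuristic()`: allocate `A_i` grains
proportionally to `q`, repair the rounding grain by grain where it costs
least, then move single grains until no move lowers `d`). A continuous
convention (`d_min = "zero"`) is available because both appear in the
literature; the integer convention is the default so that small-degree
species are not penalized for the impossibility of matching `q` exactly
with few interaction events.

**Species strength** is `Σ_j a_ij/A_j`; over one mode it sums exactly to
the number of species in the other mode, which the tests assert on seeded
random networks. **Closeness centrality** treats the network as an
unweighted two-mode graph (distances via igraph). The `standard` variant
uses the component-corrected form
`((nc−1)/Σd) × ((nc−1)/(n−1))` for a node in a component of `nc` of `n`
nodes, the `harmonic` variant `Σ(1/d)/(n−1)`; isolated nodes score 0.
Published closeness values from the software stacks used in field studies
cannot always be mapped onto a single textbook normalization, so both
variants are provided and neither is claimed to reproduce any particular
published per-species table; downstream, closeness is only a regression
predictor. **Chao1** defaults to the bias-corrected estimator (matching
common estimator software), with the classic form available.

## Pollen-load statistics

Stigmas with `CP + HP = 0` carry no deposition information and are excluded
before species-level statistics (`exclude_empty()`, which reports the
tally); community grain totals pool over all stigmas, where empty ones
contribute zero either way. Means use arithmetic averages over analyzed
stigmas, SE is the sample SD (n−1) over √n, and CV is `100·SD/mean`, in
percent. A CV whose mean is zero is undefined and is stored as `NA`;
`format_species_table()` prints it as 0, the convention of published
summary tables, and both representations are preserved.

The per-species HP proportion defaults to the pooled form
`100·ΣHP/(ΣCP+ΣHP)`, consistent with how community-level shares are always
computed; a per-stigma-mean alternative is available
(`hp_prop_mode = "per_stigma"`) because the raw data behind published
per-species percentages can rarely be re-derived and both readings exist.
Threshold censuses round to the table precision (1 decimal place) and
compare inclusively, so a species tabulated at exactly the threshold counts
as at-or-below.

Flower display areas follow the standard shape formulas: circle `πr²`,
flat rectangle `L·W`, tube additions `+πBD`, legume `L·W + l·w`
(dimensions in mm, areas in mm²).

## CP–HP pattern classification

Per species, on analyzed stigmas only (at least 3):

1. If all HP loads are zero the species is labelled `no_hp` — no
   relationship can be fitted.
2. Otherwise both candidate models are fitted: OLS `HP = b0 + b1·CP` and
   nonlinear least squares `HP = exp(c0 + c1·CP)`.
3. Significance of each fit is an overall F test against the intercept-only
   model at `alpha` (default 0.05, configurable). Only-linear-significant
   gives a linear label (signed by the slope), only-exponential gives an
   exponential label signed by `c1`, both-significant is decided by the
   larger adjusted R², and neither gives `no_pattern`.

Conventions and numerical choices:

* The exponential form `exp(c0 + c1·CP)` supports both increasing and
  decreasing accrual with a single parameterization and produces rate
  coefficients on the small scale typical of published tables. It is fitted
  with Levenberg–Marquardt (`minpack.lm::nlsLM`, objective tolerance 1e-8,
  at most 500 iterations), initialized from the log-linear regression of
  `log(HP+1)` on CP. Non-convergence is returned as a flagged fit and
  treated as non-significant downstream. A constant-HP response
  short-circuits to a flat curve with p = 1.
* The exponential model has two parameters, like the linear model, so its
  adjusted R² uses the same penalty `1 − (1−R²)(n−1)/(n−2)` and the F test
  the same residual degrees of freedom `n−2`; the comparison between the
  models is therefore like for like.
* Exact adjusted-R² ties go to the linear model (parsimony).
* Tabulated output follows the conventional layout: chosen-model statistics
  where a pattern was found, the linear fit's statistics for `no_pattern`
  rows (published tables show exactly this, including negative adjusted
  R²), and slashes (`NA`) for `no_hp` species. The stigma count per row is
  the number collected, not the number analyzed.

The classifier's operating characteristics are measured, not assumed: the
acceptance suite runs 200 seeded replicates per regime at n = 50 stigmas
and requires ≥ 80% correct recovery for the independence, linear and
exponential regimes (with correct sign). Because the decision between two
significant models rests on an adjusted-R² comparison, recovery of the
linear regime depends on count overdispersion: with pure Poisson counts the
exponential model wins the comparison on genuinely linear data roughly a
quarter of the time, while under the realistic negative-binomial
overdispersion of the default generator the linear model wins
decisively. This is a property of the decision rule itself and would apply
equally to any analysis using it.

## Cross-species comparisons

`apply_transforms()` applies the conventional variance-stabilizing
transforms exactly once: log10 for flower size and HP proportion, square
roots for d′, species strength and closeness, and the numeric symmetry
coding bilateral = 1, radial = 2. Species with zero HP have no defined
log10(HP%); they are flagged and excluded from log-using analyses only — no
`+1` offset is added, because an offset changes group means materially at
the percent scale while exclusion reproduces published group statistics
from the corresponding tables. Flower size is log-transformed in group
comparisons as well: the reconstructed group means of the bundled survey
agree with the published ones only under that reading, which settles an
ambiguity in the original methods description. The two-group strategy
comparison (significant vs non-significant CP–HP relationship) uses
untransformed HP percentages, for the same reason.

Standardized regression coefficients are `b·SD(x)/SD(y)`, so a
single-predictor coefficient equals the Pearson correlation and all
coefficients are scale-free; raw coefficients are reported alongside.
Published regression tables of this design sometimes print values far
outside [−1, 1] labelled as standardized coefficients, which is
arithmetically impossible; the package reports both kinds and does not
attempt to match such values. One-way ANOVA uses the classic between/within
decomposition via `lm`/`anova`, refuses to return an F when the residual
sum of squares is exactly zero, and reports per-group n, mean and SE. No
multiple-testing correction is applied across response variables, matching
standard practice in the source literature; p-values are two-sided.

## The synthetic-community generator

The generator's defaults are the study conditions of the survey the
package mirrors: 29 plant species × 45 pollinator species, 494 unique
links, 50 stigmas per species, and a regime mixture of 19 avoidance
species (2 of which receive no HP at all), 6 linear-tolerance and 4
exponential-tolerance species. Everything is driven by one integer seed;
identical config and seed reproduce the dataset bit for bit.

* **Visitation network**: visit counts are Poisson with rates proportional
  to the outer product of lognormal plant attractiveness and pollinator
  activity (SD 0.6 on the log scale); the base rate is calibrated by root
  finding so the expected number of realized links matches the target, and
  the realized network is thinned (or topped up with the highest-rate
  missing links) to hit the target exactly.
* **Deposition regimes**: avoidance draws CP (mean 100) and HP
  (Poisson, mean 1) independently; linear tolerance draws visits
  (mean 10/stigma) and per-visit Poisson deposits of 12 grains split
  90:10 conspecific:heterospecific, so E(HP|CP) is proportional;
  exponential tolerance drives `CP ~ Poisson(a)` and
  `HP ~ Poisson(exp(c0 + c1·a))` from a latent per-stigma attractiveness
  `a ~ Gamma(2, scale 50)` with `c0 = 0.5, c1 = 0.015` (increasing) or
  `c0 = 3, c1 = −0.02` (decreasing). Coupling through the latent rate
  rather than the realized CP keeps HP|CP a stochastic relationship.
* **Overdispersion**: count draws are negative-binomial with size 3 by
  default (Poisson available via `overdispersion = NULL`). The choice is
  grounded in the high per-stigma CVs of field pollen loads (CP CVs in the
  50–200% range), which pure Poisson counts cannot produce at these means.
* **Donor pools**: each plant's HP is spread over 5 co-flowering donors by
  a per-stigma Dirichlet(1)-multinomial, which makes HP donor diversity an
  emergent quantity in the 0–2.5 range at these HP loads.
* **Traits**: lognormal flower sizes (median 250 mm², log-SD 1.6, spanning
  a few mm² to ~10⁴ mm²) and radial symmetry with probability 20/29.

What the generator does **not** emulate: spatial foraging, phenology,
within-season pollinator turnover, correlation between a plant's network
degree and its stigma loads, or pollen carryover dynamics. Passing tests
on synthetic data therefore demonstrate that the pipeline's inference is
correct under the stated statistical structure — not that any particular
field system satisfies that structure.

## Problem sizes and determinism in the test suite

The oracle-equivalence suite enumerates all marginal families up to 3×3
with entries 1..6 and total ≤ 12 — the largest family exhaustively
checkable in interactive time — and every operating-characteristic
simulation uses 100–200 seeded replicates at the survey's sampling depth
(n = 50 stigmas). All randomness flows through explicit integer seeds
(`withr::with_seed`), so the suite and the acceptance script are exactly
reproducible.

## Known limitations

* `H2_min` and `d_min` are heuristics beyond the exhaustively verified
  range; on community-scale networks they are bounded above by the observed
  entropy, so the indices stay in [0,1], but the standardization could in
  principle be slightly conservative.
* The closeness normalization of legacy network software cannot be
  recovered exactly; regression results involving closeness should be read
  with the chosen variant in mind.
* Whether "interactions" in a published network count unique links or
  visitation events is not always stated; the package adopts the
  unique-links reading, which is consistent with the descriptive
  arithmetic it reproduces (for example 494 links over 74 species = 6.7
  links per species).
* Per-species regression statistics from unreleased raw data cannot be
  replicated; equivalence with published per-species tables is claimed at
  the level of the decision rule and of every quantity derivable from the
  printed summaries, not per-species fit statistics.

```{r example, eval = FALSE}
# the full pipeline on a synthetic community
sim <- simulate_community(sim_config(seed = 1))
net <- build_network(sim$edges, binarize = TRUE)
metrics <- network_metrics(net)
summaries <- summarize_species(sim$loads)
classified <- classify_all(sim$loads)
comparison <- summaries |>
  left_join(select(classified, species, pattern), by = "species") |>
  left_join(sim$traits, by = "species") |>
  pattern_group_comparison(c("mean_hp", "flower_size"))
```
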