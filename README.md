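# pollennet

Tools for analysing **heterospecific pollen (HP) deposition** in a plant
community together with the structure of its **bipartite plant–pollinator
network**.

When co-flowering plants share pollinators, stigmas receive not only
conspecific pollen (CP) but also grains from other species (HP), which can
clog stigmas and interfere with fertilization. Communities answer this
pressure with two strategies: *HP avoidance* (floral or behavioural
mechanisms keep HP off stigmas, so HP and CP loads vary independently) and
*HP tolerance* (large HP loads are accepted, producing a systematic CP–HP
relationship). `pollennet` is for pollination ecologists who want to take a
community survey — an interaction edge list, per-stigma pollen counts, and
floral traits — and ask which strategy prevails, and whether network
position or floral phenotype predicts pollen receipt.

## What it computes

**Network metrics** (from scratch, on the qualitative plant × pollinator
matrix with cell totals `a_ij`, marginals `A_i`, `A_j`, grand total `m`):

* **H2′**, network-level specialization: with `p_ij = a_ij/m` and observed
  Shannon entropy `H2 = −Σ p_ij ln p_ij`,
  `H2′ = (H2_max − H2)/(H2_max − H2_min)`, where `H2_max` is the entropy of
  the marginal outer product and `H2_min` the minimum entropy over integer
  matrices with the observed marginals (deterministic multi-start greedy
  allocation, verified against exhaustive enumeration on small problems).
* **d′**, species-level specialization: the Kullback–Leibler divergence of a
  species' partner use `p′_ij = a_ij/A_i` from partner availability
  `q_j = A_j/m`, standardized between its integer-allocation minimum and
  `d_max = ln(m/A_i)`.
* **Species strength** `Σ_j a_ij/A_j` (summed dependencies of the partners),
  **closeness centrality** (standard or harmonic, on the unweighted
  two-mode graph) and **Chao1 sampling completeness**
  (`Ŝ = S_obs + f1²/2f2`, classic or bias-corrected).

**Pollen-load statistics**: per-species means, SEs and coefficients of
variation of CP load, HP load and HP donor diversity over analyzed stigmas
(empty stigmas are excluded, as in field practice), the HP proportion
`HP/(CP+HP) × 100%` (pooled or per-stigma), community totals, flower areas
from shape formulas, and threshold censuses ("what share of species receive
≤10% HP?").

**CP–HP accrual classification**: per species, an OLS linear fit
`HP = b0 + b1·CP` competes with a nonlinear exponential fit
`HP = exp(c0 + c1·CP)`; significance is assessed by overall F tests, and a
species is labelled `increasing_linear`, `increasing/decreasing_exponential`
(winner by adjusted R² when both are significant), `no_pattern` (neither
significant — the avoidance signature), or `no_hp`.

**Cross-species comparisons**: standardized-coefficient multiple regressions
of deposition statistics on floral traits and network metrics (with the
conventional log10/√ transforms), and one-way ANOVAs across pattern groups
and avoidance/tolerance strategy groups.

**Synthetic communities**: a seeded generator
(`sim_config() |> simulate_community()`) producing visitation networks with
a target link count and per-stigma pollen records under explicit deposition
regimes (independent "avoidance", shared-visitation "linear tolerance",
latent-rate "exponential tolerance"), with negative-binomial overdispersion
and Dirichlet-multinomial donor pools — so the whole pipeline is testable
end to end with known ground truth.

The package also bundles the published per-species and community-level
summary tables of a 29-species oceanic-island survey (Yongxing Island,
South China Sea) as `yongxing_survey()` / `yongxing_community()`; the raw
per-stigma data of that study are not publicly deposited.

## Worked example

```r
library(pollennet)
library(dplyr)

# published per-species summaries of the Yongxing Island community survey
survey <- yongxing_survey()
hp_threshold_census(rename(survey, hp_proportion = hp_percent), threshold = 10)
#> # A tibble: 1 × 4
#>   threshold n_species n_at_or_below share_pct
#>       <dbl>     <int>         <int>     <dbl>
#> 1        10        29            22      75.9

# HP avoidance vs tolerance: compare HP% between species with and without a
# significant CP-HP relationship
one_way_anova(survey$hp_percent, strategy_group(survey$pattern))
#> One-way ANOVA: F(1, 27) = 0.972, p = 0.3328
#> # A tibble: 2 × 4
#>   group               n  mean    se
#>   <chr>           <int> <dbl> <dbl>
#> 1 non_significant    19  5.97  2.52
#> 2 significant        10 10.5   4.20

# a seeded synthetic community with the same dimensions as the survey
sim <- simulate_community(sim_config(seed = 1))
net <- build_network(sim$edges, binarize = TRUE)
glance(network_metrics(net))[, c("n_links", "links_per_species", "h2_prime")]
#> # A tibble: 1 × 3
#>   n_links links_per_species h2_prime
#>     <int>             <dbl>    <dbl>
#> 1     494              6.68    0.229

classified <- classify_all(sim$loads)
attr(classified, "tally")
#> # A tibble: 4 × 2
#>   pattern                n_species
#>   <chr>                      <int>
#> 1 increasing_exponential         4
#> 2 increasing_linear              6
#> 3 no_hp                          2
#> 4 no_pattern                     17
```

Reading the output: 22 of the 29 surveyed species (75.9%) receive at most
10% HP — most species keep heterospecific pollen rare. The two strategy
groups differ in mean HP% (10.5% vs 6.0%) but not significantly
(F = 0.972, p = 0.33). The synthetic community reproduces the survey's
dimensions (494 links, 6.7 links per species) with a generalized network
(H2′ ≈ 0.23), and the classifier recovers its ground-truth regime mixture:
19 of 29 species show no CP–HP relationship.

## Package layout

* `R/io.R` — readers/validators for edge lists, stigma tables (long or
  summary form) and trait tables; deterministic report writer.
* `R/entropy.R` — entropy minimisation machinery behind H2′ and d′
  (heuristics plus exhaustive-enumeration references).
* `R/network.R` — `build_network()`, `h2_prime()`, `d_prime()`,
  `species_strength()`, `closeness_centrality()`, `chao1_completeness()`,
  `network_metrics()`.
* `R/summaries.R` — stigma exclusion, per-species and community summaries,
  flower areas, threshold census.
* `R/classify.R` — CP–HP model fits and the pattern decision tree.
* `R/comparative.R` — transforms, standardized regressions, ANOVAs,
  pattern-group comparisons.
* `R/simulate.R` — the synthetic-community generator and metric fixtures.

Fitted objects support `tidy()`/`glance()`; networks and comparisons have
`autoplot()` methods. See `vignettes/heterospecific-pollen.Rmd` for the
methods account.
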