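# hostshift

Host-range shifts in phytophagous insect communities, from per-fruit
emergence records.

Tephritid fruit-fly larvae develop inside fruit, so the number of adults of
each species emerging from a collected fruit measures the plant–insect
interaction directly. When a generalist competitor invades such a
community, resident species may narrow their diets. `hostshift` quantifies
that from a long-term collection of per-fruit records split into a
*before* and an *after* period at the invasion year:

* **Community structure** — is host-plant phylogeny a good predictor of
  who eats what? Four marginal binomial-logit models of the plants × flies
  presence pattern are fitted by generalized estimating equations (GEE)
  and compared with the quasi-likelihood information criterion,

  `QIC = −2Q(β̂) + 2·tr(Ω̂_I V̂_R)`,

  where `Q` is the binomial quasi-likelihood under working independence,
  `Ω̂_I` the independence information and `V̂_R` the robust sandwich
  covariance. The suite is M1 `logit(p_ij) ~ a + b_i` (fly effects),
  M2 `~ a + b_i + c_j` (plus plant effects), M3 `~ a + b_i + c_j + d_ij`
  (fly × plant interaction), and M4: one GEE per fly species, one
  parameter per plant, all plants in a single cluster whose **fixed**
  working correlation is the Brownian-motion tip correlation of the host
  phylogeny; QIC(M4) is the per-fly sum. A model is selected only when the
  runner-up exceeds it by more than 10.

* **Niche breadth and overlap** — bootstrap interaction matrices are built
  by drawing one fruit per plant, dividing each row by the plant's *biotic
  capacity* (mean total flies per fruit over the whole database) and each
  column by its total. Each fly's niche breadth is the Shannon number
  equivalent `D_α = exp(−Σ_j p_ij log p_ij)` and each pair's overlap the
  turnover `T = D_β − 1` (Jost's Shannon beta with two equally weighted
  communities), with means and 2.5%/97.5% quantile CIs over 10,000
  replicates.

A synthetic-data generator (Yule host phylogeny, guild-structured niche
profiles, per-fruit Poisson counts, post-invasion contraction of
generalist diets) reproduces the statistical shape of such a study, so the
whole pipeline runs and is tested without any field data.

## Worked example

```r
library(hostshift)

sim <- simulate_invasion_scenario(seed = 1)   # tree + niches + dataset
run <- run_analysis(sim$dataset, sim$tree,
                    run_config(bootstrap_reps = 10000, seed = 1))

run$qic_table
#> <qic_table> period=before, unit=sample, selected: M4
#> # A tibble: 4 × 7
#>   model_id   qic quasi_lik trace_term n_params note                         rank
#>   <chr>    <dbl>     <dbl>      <dbl>    <int> <chr>                       <int>
#> 1 M1       3498.    -1742.       7.00        7 plain                           4
#> 2 M2       3105.    -1536.      16.5        42 ridge-stabilised                3
#> 3 M3        761.     -339.      41.0       252 ridge-stabilised                2
#> 4 M4        686.     -341.       1.84      252 sum of 7 per-fly fits; rid…     1
```

The presence pattern of the simulated community is phylogenetically
structured (two specialist guilds are confined to clades), and QIC picks
the phylogeny-aware M4 with a margin of ~75 over the free interaction
model M3 — far beyond the support threshold of 10.

```r
run$comparison$alpha
#> # A tibble: 8 × 7
#>   fly_id  richness_before richness_after d_alpha_before d_alpha_after delta_d_alpha ci_disjoint
#>   <chr>             <int>          <int>          <dbl>         <dbl>         <dbl> <lgl>
#> 1 gen1                 14             11           6.65          4.14       -2.52    FALSE
#> 2 gen2                 14             11           9.36          7.09       -2.28    FALSE
#> 3 gen3                 15             10           5.73          3.62       -2.11    FALSE
#> 4 cuc1                  7              7           4.65          4.65        0.00107 FALSE
#> 5 cuc2                  7              7           4.35          4.78        0.426   FALSE
#> 6 cuc3                  7              7           4.54          4.69        0.159   FALSE
#> 7 sol1                  4              3           1.96          1.97        0.0148  FALSE
#> 8 invader               0              8          NA             5.45       NA       FALSE
```

The three resident generalists — which share hosts with the invader —
each lose 2 or more number-equivalent hosts of niche breadth (and 3–5
hosts of richness) after the invasion, while the clade specialists are
essentially unchanged. The invader's pairwise turnover against the
specialists, with which it shares no hosts, is exactly
`1.00 [1.00; 1.00]`:

```r
dplyr::filter(run$comparison$pairs, fly_k == "invader")
#> # A tibble: 7 × 6
#>   fly_i fly_k   turnover_before turnover_after delta_turnover ci_disjoint
#>   <chr> <chr>             <dbl>          <dbl>          <dbl> <lgl>
#> 1 gen1  invader              NA          0.437             NA FALSE
#> 2 gen2  invader              NA          0.565             NA FALSE
#> 3 gen3  invader              NA          0.897             NA FALSE
#> 4 cuc1  invader              NA          1                 NA FALSE
#> 5 cuc2  invader              NA          1                 NA FALSE
#> 6 cuc3  invader              NA          1                 NA FALSE
#> 7 sol1  invader              NA          1                 NA FALSE
```

`autoplot(run$comparison)`, `autoplot(run$qic_table)` and
`autoplot(run$diversity_before)` draw the standard figures;
`tidy()`/`glance()` methods summarise fitted GEE objects. A thin CLI over
the same functions lives in `inst/scripts/hostshift.R`
(`simulate`, `validate`, `fit-structure`, `diversity`, `compare`,
`run-all`).

## The methods vignette

`vignettes/host-range-shifts.Rmd` documents the models and their
assumptions, the observation-unit and cluster choices behind the GEE
suite, the bootstrap and its normalisations, every tunable constant with
its default, what the synthetic generator does and does not emulate, and
known limitations.
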