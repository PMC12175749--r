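# restodiv

Multi-scale, multi-metric, multi-facet diversity analysis for factorial
restoration experiments, from incidence (presence/absence) survey data.

Grassland restoration experiments routinely ask how treatments — here,
nutrient addition crossed with the timing at which an invasive plant
enters the community — change plant diversity. The answer depends on how
diversity is measured: at what spatial scale (a pair of subplots, a whole
treatment, or their ratio), with what abundance weighting (Hill order
q = 0, species richness, versus q = 2, effective number of dominant
species), and for which facet (taxonomic, phylogenetic, functional).
restodiv implements the full pipeline for ecologists analysing such
experiments — and, through its synthetic-experiment generator, for anyone
who wants to study the estimators themselves.

The core is incidence-based Hill-number rarefaction and extrapolation.
From the incidence frequencies $Y_i$ of $T$ sampling units, richness at
$t \le T$ units is the exact expectation
$S(t) = \sum_i [1 - \binom{T-Y_i}{t}/\binom{T}{t}]$, extended past $T$
with the Chao2 estimate of undetected richness; order-2 diversity uses
the ratio-of-expected-moments estimator
$(tU/T)^2 / [tU/T + \tfrac{t(t-1)}{T(T-1)}\sum_i Y_i(Y_i-1)]$. The same
machinery runs on tree branches (mean-PD: effective number of equally
divergent lineages, i.e. effective branch length divided by tree depth)
and on "virtual functional groups" under a distinctness threshold τ
(defaulting to the mean pairwise Gower distance of the pooled
assemblage). Around the estimators sit:

- a data model for plot/subplot surveys with the rare-species
  perimeter-walk pseudo-subplot and treatment-subset filtering;
- phylogeny-informed trait imputation: Abouheif proximities, Moran
  eigenvectors, chained random-forest imputation with out-of-bag restart
  selection;
- Whittaker decomposition (α at 2 subplots, γ at all observed subplots,
  β = γ/α) and late-minus-early invasion effect sizes with bootstrap
  confidence intervals;
- a seeded generator of synthetic factorial experiments (occupancy-based
  incidence with plot-level aggregation, Yule phylogeny, Brownian-motion
  traits with missingness) against which every stage is tested.

Everything is tidyverse-shaped: functions take and return tibbles,
results chain with the pipe, and each result class has `autoplot()`,
`tidy()` and `glance()` methods.

## A worked example

```r
library(restodiv)
library(dplyr)

# a synthetic experiment with the reference design: 12 treatment combos
# x 8 plots x (9 subplots + perimeter walk), 60 species, 10 traits
sim <- simulate_experiment(sim_config(seed = 4), full_factorial = TRUE)

# keep the grasses+forbs-together assembly level: the 2x2 factorial
survey <- filter_analysis_subset(sim$survey)
survey
#> <incidence_matrix> 320 sampling units, 32 plots, 59 species, 1633 detections

# impute missing traits with phylogenetic random forests, then Gower
ev  <- moran_eigenvectors(abouheif_proximity(sim$tree), k = 30)
imp <- impute_traits(sim$traits, ev, n_restarts = 4, seed = 5)
dmat <- gower_distance(imp$traits)

# rarefaction/extrapolation curves for TD, PD, FD at q = 0 and q = 2,
# 95% CIs from 50 bootstrap resamples of the sampling units
curves <- estimate_diversity(survey, tree = sim$tree, dist = dmat,
                             t_max = 120, B = 50, seed = 6)
glance(curves) |> filter(facet == "TD", q == 0)
#> # A tibble: 4 × 8
#>   assemblage      facet     q T_obs observed t_max extrapolated_max ci_width_obs
#>   <chr>           <chr> <dbl> <dbl>    <dbl> <dbl>            <dbl>        <dbl>
#> 1 control.early   TD        0    80       47   120             50.9         7.77
#> 2 control.late    TD        0    80       57   120             59.8         7.55
#> 3 nutrients.early TD        0    80       41   120             45.0         7
#> 4 nutrients.late  TD        0    80       54   120             58.5         6

# alpha (2 subplots), gamma (80 subplots), beta = gamma/alpha,
# then late - early invasion effects per nutrient level
effects <- curves |> scale_estimates() |> invasion_effects(seed = 7)
effects |> filter(facet == "TD", q == 0)
#> # A tibble: 6 × 7
#>   nutrient  facet     q scale delta ci_low ci_high
#>   <chr>     <chr> <dbl> <fct> <dbl>  <dbl>   <dbl>
#> 1 control   TD        0 alpha  5.48   4.54    6.33
#> 2 nutrients TD        0 alpha  7.28   6.35    8.00
#> 3 control   TD        0 gamma 10      6      16.8
#> 4 nutrients TD        0 gamma 13      9      19
#> 5 control   TD        0 beta  -2.41  -2.80   -1.27
#> 6 nutrients TD        0 beta  -3.96  -3.98   -2.35
```

Read: letting the invader in late instead of early adds 5–7 forb species
to a typical pair of subplots and 10–13 species to a whole treatment
(the effect grows with scale), while β falls — rarefied α is so low
under early invasion that the γ/α ratio is inflated there. `autoplot(curves)`, `autoplot(scale_estimates(curves))` and
`autoplot(effects)` draw the corresponding rarefaction panels, scale
panels and effect-size panels.

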