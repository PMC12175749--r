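---
title: "Models and methods behind restodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind restodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restodiv)
library(dplyr)
```

restodiv analyses plot/subplot incidence surveys from factorial grassland
restoration experiments: how do nutrient addition and the timing of an
invader's arrival affect plant diversity, when diversity is measured at
different spatial scales (α, γ, Whittaker β), with different abundance
weightings (Hill orders q = 0 and q = 2), and for different facets
(taxonomic, phylogenetic, functional)? This vignette explains the models
and estimators, the choices made where the design was genuinely open, and
what the synthetic-data generator does and does not emulate.

## The data model

A survey is a set of *sampling units* nested in plots. Each plot carries
nine surveyed subplots (0.25 m²) and one *perimeter-walk* pseudo-subplot:
after the subplots are scored, the whole plot is walked and any forb
missed by the subplots is recorded. The walk unit therefore carries only
walk-exclusive species — a species already seen in a subplot of that plot
is dropped from the walk record (with a warning), which avoids double
counting and matches the inventory intent of the walk. Plots with an empty
walk still receive an all-zero walk unit so every plot contributes the
same number of units. Grasses, surveyed only as a lumped group, are
excluded at ingestion; any positive cover counts as a detection because
all downstream statistics are incidence-based.

The full experiment crosses nutrients × invasion timing × a three-level
seeding-assembly factor; the analysis subset keeps the assembly level in
which grasses and forbs were seeded together, i.e. the 2 × 2 factorial
with 8 plots per combination: 32 plots, 320 sampling units, 80 per
treatment (72 surveyed + 8 walks).

All estimators consume the incidence frequencies of an assemblage: T
sampling units, per-species frequencies $Y_i$ (units in which species $i$
was detected), totals $U = \sum_i Y_i$, uniques $Q_1$ and duplicates
$Q_2$.

## Hill numbers from incidence data

**Richness (q = 0).** For $t \le T$ the package uses the exact
subsampling expectation
$S(t) = \sum_i \left[1 - \binom{T - Y_i}{t}\big/\binom{T}{t}\right]$,
which equals the average richness over all $\binom{T}{t}$ unit subsets
(this identity is what the oracle tests enumerate). For $t > T$ the curve
continues with the Chao2 lower bound on undetected richness,
$\hat Q_0 = \frac{T-1}{T}\frac{Q_1^2}{2 Q_2}$ (with the usual
$Q_1(Q_1-1)/2$ fallback when $Q_2 = 0$, flagged by a constant curve once
uniques are exhausted), via
$S(T) + \hat Q_0\!\left[1 - \left(1 - \frac{Q_1}{Q_1 + T \hat
Q_0}\right)^{t-T}\right]$.

**Effective dominant species (q = 2).** The ratio-of-expected-moments
estimator
$${}^2\!D(t) = \frac{(tU/T)^2}{\,tU/T + \frac{t(t-1)}{T(T-1)}\sum_i
Y_i(Y_i-1)}$$
is nearly unbiased and valid across rarefaction, the observed point and
extrapolation, because both moments are exact hypergeometric expectations
for $t \le T$ and natural polynomial extensions beyond. Incidence-based
q = 2 needs at least two sampling units, which is why the smallest
reporting scale is two subplots.

**Phylogenetic diversity (mean-PD).** The phylogenetic facet is the
effective number of equally divergent lineages: effective total branch
length divided by the tree depth $\bar T$. At q = 0 the branch-length
analogue of $S(t)$ is used, with branch incidences $Y_b$ (units containing
at least one descendant tip) and a Chao2-type correction on the
unique/duplicate branch-length sums for extrapolation. At q = 2 each
branch is weighted $L_b/\bar T$ and carries the per-unit *descendant
counts* $c_{bu}$ (how many of its tips occur in unit $u$): with
$Z_b = \sum_u c_{bu}$ the estimator applies the same moment machinery
through the exact identity
$E[Z_b(t)^2] = \frac{t}{T}\sum_u c_{bu}^2 +
\frac{t(t-1)}{T(T-1)}\left(Z_b^2 - \sum_u c_{bu}^2\right)$.
On an ultrametric tree $\sum_b L_b Z_b = \bar T U$, so the normalization
is automatic: a single lineage yields exactly 1, and a star tree with
equal branch lengths reproduces the taxonomic estimator exactly at every
t — these reductions are tested as exact identities. Descendant-count
abundances (rather than union incidences) are what make the worked
three-species example come out at 2.25 for q = 2; exact agreement with
other published finite-size PD estimators is not claimed.

**Functional diversity (FD under a threshold τ).** Species closer than τ
in trait space partially share "virtual functional groups". With
truncated distances $d_{ij}(\tau) = \min(d_{ij}, \tau)$,
$\nu_{ij} = 1 - d_{ij}(\tau)/\tau$, pooled incidence-based relative
abundances $p_i = Y_i/U$, group abundances $a_i = \sum_j \nu_{ij} p_j$
and weights $v_i = p_i/a_i$. At q = 0 the estimate is
$\mathrm{FD}_0(t) = \sum_i v_i\, \pi^g_i(t)$, where $\pi^g_i(t)$ is the
exact subsampling detection probability of the *group* around species
$i$: the group counts as present in a unit whenever any species within τ
of its anchor occurs there. Using group-level rather than species-level
detection matters at small t — a group is represented by any of its
members, and the species-level plug-in visibly undercounts functional
richness at the 2-subplot α scale. At q = 2 the moment machinery runs on
per-unit group abundances $A_{iu} = \sum_j \nu_{ij} x_{ju}$ (their
second moments need the species co-occurrence counts, which
`to_frequencies()` carries along). Both constructions reduce exactly to
the taxonomic estimators when all interspecific distances reach τ, give 1
for a single species at every size, and give 1 at the observed sample
size when all distances are zero.

τ defaults to the mean distance between two individuals drawn at random
from the pooled assemblage (Rao's quadratic entropy on the incidence
$p_i$), computed once per assemblage at the observed sample size and held
fixed along the curve and across bootstrap replicates, so the whole curve
measures diversity against one yardstick. Extrapolated FD at q = 0 adds
the Chao2 unseen-species estimate weighted by the mean $v$ of the unique
species — the best available proxy for how distinct undetected species
are.

**A note on Hill ordering.** Within a facet, the q = 2 estimate stays at
or below the q = 0 estimate over the rarefied and observed range
(Cauchy–Schwarz at the observed point, verified empirically elsewhere).
In deep extrapolation the two nearly unbiased estimators can cross by
$O(1/T)$ when no uniques remain (richness is capped at $S_{obs}$ while
the q = 2 ratio can overshoot it slightly); this is a small-sample
property of the estimators, not an inconsistency of the underlying
quantities.

## Trait imputation

Traits arrive with missing entries. The imputation pipeline is chained
random-forest regression informed by the phylogeny:

1. Abouheif proximities (nodal-path products of direct-descendant counts,
   no diagonal, no normalization) summarize relatedness without needing
   branch lengths.
2. Moran eigenvectors of the doubly centered proximity matrix (computed
   in the orthogonal complement of the constant vector, so every vector
   is exactly centered even under eigenvalue ties) provide orthogonal
   predictors at decreasing phylogenetic scales; at most
   $\min(30, n-1)$ are used, the cap at $n-1$ because small species
   pools cannot support 30.
3. Each trait is initialized at its mean, then traits are revisited in
   increasing-missingness order, each regressed on the other traits plus
   the eigenvectors; iteration stops when the total change in imputed
   values first increases (the classic stopping rule) or after 10 passes.
4. The whole procedure restarts `n_restarts` times (default 25), varying
   both the seed and the number of eigenvector columns over
   `k_grid = seq(5, 30, 5)`; per trait, the restart with the smallest
   out-of-bag error — normalized RMSE, $\sqrt{\mathrm{OOB\ MSE}}/\mathrm{sd}$
   — wins. Varying both seed and eigenvector count covers the two
   readings of "re-iterating the eigenvector estimation", and the
   per-restart log records which combination was chosen.

Gower dissimilarity (range-normalized mean absolute difference over
traits observed in both species, zero-range traits contributing 0 to
avoid 0/0) turns the completed table into the distance matrix FD needs;
it is cross-checked against an independent implementation in the test
suite.

## Scales and effect sizes

The α scale is the rarefied estimate at two subplots (0.5 m²); the γ
scale is the observed estimate at all units of the treatment (80 in the
reference design, 20 m²); Whittaker's multiplicative β = γ/α measures
among-subplot heterogeneity. Confidence intervals come from a
nonparametric percentile bootstrap over sampling units (50 replicates at
95 % by default): β is formed per replicate as $\gamma_b/\alpha_b$, so
its interval reflects the joint variation of the two scales. Invasion
effects are late-minus-early differences per nutrient level, facet, order
and scale; their intervals difference the two treatments' bootstrap
replicates, paired by seeded random indices. Differencing replicate
distributions (rather than interval endpoints) is the standard and
testable choice where the alternative is ambiguous; the choice is
recorded in the result's `method` attribute rather than asserted as the
only one. The unit bootstrap never resamples unseen species, so
extrapolated-range intervals can undercover — that caveat travels in the
same attribute. Coverage of the rarefied range is checked by simulation
in the test suite (95 % nominal, within ten points at 25 units; with very
few units — around ten — the unit bootstrap visibly undercovers, which is
inherent to resampling so few units).

Degenerate inputs are handled conservatively: an assemblage with no
detections reports 0 with empty intervals instead of failing the run;
identical units give zero-width intervals; an extrapolation request
beyond twice the observed sample size is allowed but warned about.

## The synthetic experiment

The generator exists so that every stage has a fully known truth. It
emulates, under `sim_config()` defaults chosen once as the study
conditions:

- the design: 2 × 2 factorial (optionally crossed with the three-level
  assembly factor), 8 plots per combination, 9 subplots plus a perimeter
  walk per plot;
- a community of 60 species: one dominant focal invader plus 59 natives
  whose base occupancies follow a geometric rank series
  ($0.5 \times 0.93^{\,rank-1}$), the classic dominance profile of
  grassland communities — heterogeneous occupancy is what makes γ-scale
  richness respond to treatments at all;
- invasion timing: invader occupancy 0.95/0.90 (control/nutrients) under
  early invasion against 0.35/0.30 under late; native occupancies
  multiplied by 0.4 (control) or 0.3 (nutrients) under early invasion,
  reflecting strongest suppression where the invader is most dominant
  and nutrients compound it;
- spatial aggregation: a plot × species Normal(0, `plot_sd`²) effect on
  the logit-occupancy scale, shared by all units of a plot. The intercept
  is solved (by quadrature) so the species' marginal across-plot
  occupancy is preserved exactly: a raw logit shift would inflate the
  marginal occupancy of rare species (Jensen's inequality) and turn the
  aggregation knob into an occupancy knob — with the perverse consequence
  that "more aggregation" *lowers* β. Centering makes `plot_sd` govern
  where a species occurs, not how often;
- the perimeter walk: a species missed by a plot's subplots is found on
  the walk with probability
  $0.5 \times [1 - (1 - \pi_{ps})^{9}]$ — the walk can only recover
  species plausibly present somewhere in the plot, with plot presence
  implied by the species' plot-level occupancy. A flat detection rate
  independent of occupancy would stock plot inventories with species the
  treatment had suppressed and erase the very signal the generator must
  carry;
- traits: ten traits evolved by Brownian motion (rate 1) on a Yule tree
  rescaled to depth 1, plus Normal(0, 0.1²) measurement noise, masked
  missing completely at random at 20 % (the mask minimally repaired so
  imputation preconditions hold). Missingness that depends on the trait
  or the species (MAR/MNAR) is out of scope.

What the generator does *not* emulate: temporal dynamics over the
experiment's seven years, seed banks, within-plot spatial coordinates or
dispersal, cover abundances (everything is occupancy-based, as are all
downstream statistics), and real phylogenies with calibrated branch
lengths. Passing recovery tests on synthetic data therefore shows the
estimators recover the truth of *this* data-generating process, not that
the field data satisfy its assumptions.

## Problem sizes used in the checks

The package's own verification runs at sizes chosen to make each claim
sharp: oracle equivalence enumerates all unit subsets for 200 random
assemblages with up to 10 units; sign recovery of the invasion effect
uses 100 simulated experiments at the default conditions; the
aggregation → β check uses 100 paired simulations of a species-rich
(300) assemblage with homogeneous occupancy 0.35, where every species is
reliably detected at the γ scale so aggregation acts on α alone and the
signal cleanly exceeds Monte Carlo noise; the imputation comparison runs
20 replicates of 40 species × 10 traits with 4 restarts. The full
pipeline example in `scripts/acceptance.R` runs all three facets at both
orders with 50 bootstrap replicates out to 120 units.

## A worked run

```{r pipeline, eval = FALSE}
sim <- simulate_experiment(sim_config(seed = 4), full_factorial = TRUE)
survey <- filter_analysis_subset(sim$survey)

ev <- moran_eigenvectors(abouheif_proximity(sim$tree), k = 30)
imp <- impute_traits(sim$traits, ev, n_restarts = 4, seed = 5)
dmat <- gower_distance(imp$traits)

curves <- estimate_diversity(survey, tree = sim$tree, dist = dmat,
                             t_max = 120, B = 50, seed = 6)
autoplot(curves)

scales <- scale_estimates(curves)
effects <- invasion_effects(scales, seed = 7)
autoplot(effects)
```

## Known limitations

- The finite-size FD and PD estimators are this package's constructions
  within the attribute-diversity framework; they satisfy the exact
  reductions above but are not numerically interchangeable with other
  software's finite-size curves.
- The unit bootstrap ignores undetected species; extrapolated-range
  intervals are best read as lower bounds on uncertainty.
- Chao2 is a lower bound: long extrapolations understate richness when
  many species remain undetected.
- β inflation under within-plot aggregation is a small effect once α is
  rarefied from the pooled unit set (most unit pairs span plots); with
  realistic pool sizes it is directional rather than overwhelming, which
  is why the dedicated check uses a species-rich scenario.
- Categorical traits, q = 1, coverage-based standardization and additive
  β partitions are out of scope.
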