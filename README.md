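# occomm

Multi-season, multi-species occupancy modelling for camera-trap surveys of
mammal communities.

Camera traps record whether a species was *detected*, not whether it was
*present*: detection is imperfect, and an unknown number of community
members may never be photographed at all. occomm addresses both problems
for surveys in which a grid of cameras is revisited over several annual
seasons. It is written for ecologists comparing community status between
areas — species richness as the biodiversity measure, colonization and
persistence as the dynamics, trophic-guild and body-mass composition as
the functional summary, and per-species occupancy as a density proxy.

## The models

**Community model** (data-augmented, Dorazio–Royle style). The observed
detection tensor `Y[i, j, t]` (occasions with a detection of species *i*
at camera *j* in season *t*, out of effort `K[j, t]`) is padded with 100
all-zero pseudo-species. For each species slot:

    w_i        ~ Bern(Omega)                                  membership
    z[i,j,1]   ~ Bern(psi1_i · w_i)                           initial occupancy
    z[i,j,t+1] ~ Bern((phi_it · z + gamma_it · (1 − z)) · w_i) Markov dynamics
    y[i,j,t]   ~ Bin(K[j,t], p_it · z[i,j,t])                 observation

with logit-normal species heterogeneity,
`logit(psi1_i) ~ N(mu_psi1, sigma_psi1²)` (and likewise per season for
detection, per transition for colonization/persistence). Marginal
occupancy follows `psi_{t+1} = psi_t·phi + (1 − psi_t)·gamma`. Total
richness is `N = Σ w_i`; community rates are inverse-logits of the
hyper-means.

**Single-species model**: dynamic occupancy with scalar `psi1`,
per-transition `phi_t`/`gamma_t` (Uniform(0,1) priors, conjugate updates)
and site-level random detection intercepts
`logit(p_j) ~ N(alpha0, sigma_a0²)`.

Both are fitted by a bespoke Metropolis-within-Gibbs sampler (C++ core):
exact forward-filtering backward-sampling for the latent occupancy chains,
conjugate Beta updates for `Omega`, random-walk Metropolis with burn-in
adaptation for logit intercepts, conjugate/slice updates for
hyperparameters. The sampler is validated against exact enumeration of the
joint posterior on small instances. Significance between any two
posterior summaries means non-overlapping 95% credible intervals.

## Worked example

Simulate a survey from the generative model (a reduced version of the
108-camera, 3-season, 11-occasion design), rebuild the detection tensor
from the emitted record table, and fit the community model:

```r
library(occomm)

cfg <- survey_scenario("HWS-like")
cfg$J <- 25L; cfg$n_species_true <- 10L      # reduced for the example
survey <- simulate_survey(cfg, seed = 42)
#> <sim_survey> HWS-like: 10 species, 25 cameras, 3 seasons x 11 occasions
#> 366 detection records, 10 species detected

tensor <- build_detection_tensor(filter_community(survey$records),
                                 survey$deployments)
fit <- fit_community(augment_tensor(tensor, 50),
                     mcmc_config(n_chains = 2, n_iter = 1500,
                                 n_burnin = 500, thin = 2, seed = 1))
tidy(fit)
#> # A tibble: 9 × 6
#>   term            estimate    mean conf.low conf.high  rhat
#>   <chr>              <dbl>   <dbl>    <dbl>     <dbl> <dbl>
#> 1 richness[1]      10      10.0    10          10     1.00
#> 2 richness[2]      10      10.0    10          10     1.00
#> 3 richness[3]      10      10.0    10          10     1.00
#> 4 richness_total   10      10.0    10          10.5   1.01
#> 5 Omega             0.176   0.180   0.0919      0.290 1.000
#> 6 colonization[1]   0.0586  0.0682  0.00132     0.153 1.24
#> 7 persistence[1]    0.528   0.533   0.298       0.808 1.000
#> 8 colonization[2]   0.129   0.130   0.0145      0.268 1.09
#> 9 persistence[2]    0.888   0.846   0.451       1.000 1.000
```

All 10 simulated species were detected, so the richness posterior sits on
the truth with a small upper tail for never-detected members; the
colonization and persistence rates bracket the generating hyper-means
(0.1 and 0.6). `autoplot(fit)` draws the per-season richness intervals,
and `glance(fit)` gives a one-row fit summary including the worst
Gelman–Rubin factor.

Composition works directly from species lists. The packaged two-area
Myanmar table reproduces the survey's guild breakdown:

```r
tr <- myanmar_traits()
composition_proportions(tr$species[tr$area == "RYER"],
                        tr[tr$area == "RYER", ], by = "guild")
#> # A tibble: 4 × 3
#>   group           n   pct
#>   <chr>       <int> <dbl>
#> 1 herbivore       9    36
#> 2 carnivore       9    36
#> 3 omnivore        6    24
#> 4 insectivore     1     4
```

`fit_species()`, `compare_species_between_areas()`,
`guild_subset_richness()` and `run_full_analysis()` cover the rest of the
pipeline; see the vignette (`vignettes/occupancy-communities.Rmd`) for the
full methods account.

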