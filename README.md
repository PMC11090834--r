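# micetrans

Tools for separating **social** from **environmental** transmission of the
gut microbiota in RFID-tracked wild rodent populations — for microbial and
behavioural ecologists who have (or simulate) three data streams: a
time-stamped logger detection table, a sample × ASV count table with sample
metadata, and bacterial phenotype annotations (aerotolerance, sporulation)
per genus.

## The analysis

1. **Social network.** Detections are filtered to the nocturnal activity
   window [16:00, 08:00), de-duplicated per minute, and tallied per night:
   a pair is *associated* on a night if detected at the same logger within
   12 h. The lifespan-adjusted simple ratio index is

   `SRI = X / (X + y_AB + y_A + y_B)`

   over nights both mice were known alive (`X` associated nights, `y_AB`
   both observed but not associated, `y_A`/`y_B` only one observed).
2. **Space and habitat.** Gridded kernel utilization distributions per
   mouse; pairwise home-range overlap via the Bhattacharyya coefficient
   `sum(sqrt(p * q))`; 75% core ranges; habitat profiles per core and
   pairwise Bray–Curtis habitat similarity.
3. **Microbiota similarity.** Jaccard (primary), Bray–Curtis and
   shared-ASV-count similarity between samples, with phenotype-restricted
   variants and the boundary transform `(J(n-1) + 0.5)/n` for beta models.
4. **Dyadic Bayesian regression.** One row per pair of samples from
   different mice; `y ~ Beta(mu*phi, (1-mu)*phi)` with
   `logit(mu) = b0 + b_soc*SRI + b_spa*overlap + b_hab*habitat + covariates
   + u[sample_a] + u[sample_b] + v[indiv_a] + v[indiv_b]` — multi-membership
   random intercepts, fitted by a built-in Hamiltonian Monte Carlo sampler
   (no external probabilistic-programming dependency) with split-Rhat /
   bulk-ESS / divergence diagnostics.
5. **Genus importance.** Leave-one-genus-out refits give per-genus
   importance `((CIw_excl - CIw_incl)/CIw_incl)/sqrt(nASV)` for each route,
   regressed on aerotolerance and sporulation with phylogenetic covariance
   control.

A seeded synthetic-world generator (`simulate_world()`,
`simulate_detections()`, `simulate_microbiota()`) produces ground-truthed
data — including a latent-space social process and route-specific microbial
transmission — against which the whole pipeline is validated.

## Worked example

```r
library(micetrans)

cfg <- world_config(n_mice = 30, grid_side = 12, n_loggers = 36,
                    n_nights = 120, n_asv = 150, n_genera = 12,
                    detection_rate = 1, meeting_rate = 1,
                    samples_per_mouse = 1, balanced_phenotypes = TRUE,
                    route_effects = c(social = 5, spatial = 5, habitat = 1),
                    seed = 11)
world      <- simulate_world(cfg)
detections <- simulate_detections(world)
micro      <- simulate_microbiota(world)

filt    <- filter_detections(detections)
sri     <- build_network(filt)
#> SRI network: 30 individuals, mean degree 12.67, mean non-zero SRI 0.092
uds     <- estimate_uds(filt, world$loggers, ud_grid(12), bandwidth = 1.5)
overlap <- overlap_matrix(uds)

jac   <- similarity_matrix(micro$counts, "jaccard")
dyads <- build_dyads(micro$metadata, jac, sri, overlap,
                     habitat_similarity_matrix(
                       lapply(uds, function(u)
                         habitat_profile(core_range(u), survey))))
fit   <- fit_dyadic(dyads, dyadic_spec(seed = 1))

conditional_effect(fit, "sri", c(0, 0.5, 1))
#>   value  mean ci_low ci_high
#> 1   0.0 0.348  0.316   0.382
#> 2   0.5 0.369  0.321   0.419
#> 3   1.0 0.392  0.314   0.474
```

Read: mice that are never seen together are expected to share ~35% of their
ASVs; mice always seen together ~39%, holding overlap, habitat and
covariates at their means (this is a 30-mouse toy world; route slopes are
identified much more sharply in the validation worlds of the test suite —
with the three predictors partially collinear at this scale, single-route
slopes such as the habitat effect can be unstable in isolation).

`predict_expected()` reproduces the headline back-of-envelope: with an
intercept of `qlogis(0.29)` and a social slope of 0.41 on the logit scale,
expected sharing at SRI = 1 is

```r
100 * predict_expected(c(intercept = qlogis(0.29), sri = 0.41), c(sri = 1))
#> [1] 38.09524   # ~38%
```

`mantel_test(sri, overlap)` quantifies how much the social network merely
mirrors space (r = 0.64, p = 0.001 in the toy world above).

## Command line

```sh
inst/cli/micetrans simulate --out world_dir --seed 1
inst/cli/micetrans network  --detections world_dir/detections.csv --out net.csv
inst/cli/micetrans run      --config cfg.json     # full pipeline + manifest
```

See `vignettes/transmission-routes.Rmd` for the model, its assumptions, the
sampler design, and what the synthetic world does and does not emulate.
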