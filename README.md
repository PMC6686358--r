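# spomlab

Stochastic patch occupancy models (SPOMs) for plant metapopulations living
at street tree bases.

In dense cities, the small squares of soil around street trees act as
habitat patches for spontaneous flora, and the trees of one street can be
treated as a metapopulation: each year a patch is either occupied by a
species or empty, empty patches get colonized, occupied ones go extinct.
`spomlab` is for urban ecologists who have (or want to simulate) annual
presence/absence censuses of such patch networks and want to ask *where the
colonists come from*: from neighboring patches within the street (stepwise
spread), or from external sources such as parks, river banks and railway
verges (a rain of propagules).

## The models

Occupancy evolves as a Markov chain. In year *t* an empty patch *i* is
colonized with probability *C_i(t)* and an occupied patch goes extinct with
probability *E_i(t)*. Four model variants differ in how those probabilities
depend on the street's occupancy pattern:

| Model | Colonization | Extinction |
|-------|--------------|------------|
| PRM (propagule rain) | `C` (constant; external source) | `E (1 − C)` |
| LM (Levins) | `1 − exp(−y S_i(t))` | `E (1 − C_i(t))` |
| PRM + R | `C` | `E (1 − C)^R` |
| LM + R | `1 − exp(−y S_i(t))` | `E (1 − C_i(t))^R` |

with connectivity `S_i(t) = Σ_{j≠i} O_j(t) exp(−α d_ij)`, where `d_ij` is
the inter-patch distance in meters, `1/α` the mean dispersal distance, `y`
a street-level colonization scaling and `R ≥ 0` the rescue-effect strength
(`R = 1` recovers the base extinction, so the rescue models nest the base
models).

Each street × species series is fitted by maximum likelihood over its
patch-level annual transitions (survey gaps are dropped), the four models
are compared by AICc, and the best-model labels are aggregated into
proportions per street and per species, which are then related to street
geography and species traits with quasi-binomial logistic regressions.

## Worked example

Simulate one street under the Levins model, then recover the generating
model by AICc:

```r
library(spomlab)

net <- generate_network(n_patches = 150, spacing = 8, jitter = 1,
                        seed = 3, street_id = "S")
sim <- simulate_series(net, model_spec("LM"),
                       spom_params(alpha = 0.1, y = 1, E = 0.2),
                       initial = rbinom(150, 1, 0.3), n_steps = 6, seed = 12)
select_model(sim, net, species = "demo")
#> <selection_result> street 'S', species 'demo': best = LM
#>   model k   loglik    aicc delta_aicc
#> 1    LM 3 -313.171 632.370      0.000
#> 2   PRM 2 -375.084 754.182    121.812
#> 3  LM+R 4 -312.725 633.495      1.125
#> 4 PRM+R 3 -375.084 756.195    123.826
```

The connectivity-driven LM wins by over 120 AICc points against the
constant-colonization PRM, and the rescue variant's extra parameter is not
worth its AICc cost. The fitted parameters (`alpha ≈ 0.097`, `y ≈ 0.93`,
`E ≈ 0.22`) sit close to the generating values.

The package also ships the published street and species summary tables of
the seven-year Bercy district (Paris) tree-base survey and recomputes every
headline quantity from them:

```r
reproduce_published_tables()
#> Recomputed ensemble quantities vs published values:
#>                quantity       value reference pass
#> 1  overall_LM_share_pct  40.0000000   40.0000 TRUE
#> 2        n_combinations 225.0000000  225.0000 TRUE
#> 3     mean_PRM_longterm   0.5750000    0.5700 TRUE
#> 4    mean_PRM_shortterm   0.4285700    0.4300 TRUE
#> 5 slope_PRM_vs_distance  -0.0048045   -0.0048 TRUE
#> 6   slope_LMR_vs_height  -0.0264970   -0.0260 TRUE
#> 7        n_PRMR_overall   0.0000000    0.0000 TRUE
#> All checks pass.
```

Reading the rows: pooling the per-street model percentages over all 225
street × species pairs gives 40% Levins dynamics; species with long-term
persistent seed banks conform to the propagule rain model more often than
short-lived-seed species (mean proportion 0.57 vs 0.43); the PRM proportion
of a street declines with its distance to the nearest green space (logit
slope −0.0048 per meter); and short plants conform to rescue-effect
dynamics more often than tall ones (slope −0.026 per cm of maximum height).

A full synthetic study (15 streets, 1,324 patches, 15 species, surveys
2009–2015 with 2013 missing) runs end to end with:

```r
res <- run_pipeline(study_config(rng_seed = 1), out_dir = "run1")
```

or from the shell via the thin CLI wrapper
`inst/cli/spomlab {simulate|select|pipeline|reproduce-tables}`.

## Documentation

See the methods vignette (`vignettes/spom-methods.Rmd`) for the model
definitions, likelihood and AICc conventions, what the synthetic generator
does and does not emulate, and known limitations (seed banks,
PRM+R identifiability).
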