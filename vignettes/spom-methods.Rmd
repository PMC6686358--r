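---
title: "Patch occupancy models for street tree-base floras: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch occupancy models for street tree-base floras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spomlab)
```

## The problem

Street trees stand in small soil patches that host spontaneous herbaceous
plants. Within one street, those patches form a linear habitat network for
each species: every year a patch is occupied or empty, and the
presence/absence pattern turns over through colonization and extinction.
Two qualitatively different dynamics can produce such turnover. Under
*Levins-type* (stepwise) dynamics, colonists come from occupied patches
nearby, so colonization probability rises with connectivity to the rest of
the street. Under *propagule rain* dynamics, colonists arrive from large
external sources (parks, river banks, railway verges, the soil seed bank),
so colonization probability is the same everywhere regardless of which
patches are currently occupied. Distinguishing the two from annual census
data, street by street and species by species, is the core task this
package automates.

## Model definitions

Occupancy is a Markov chain on patch states. Conditional on the year-*t*
state, patches transition independently: an empty patch *i* is colonized
with probability $C_i(t)$, an occupied one goes extinct with probability
$E_i(t)$.

**Colonization.** The propagule rain model (PRM) sets $C_i(t) = C$, a
constant. The Levins model (LM) sets
$C_i(t) = 1 - \exp(-y\, S_i(t))$ with connectivity
$S_i(t) = \sum_{j \ne i} O_j(t)\, e^{-\alpha d_{ij}}$,
where $O_j(t)$ is the occupancy of patch $j$, $d_{ij}$ the Euclidean
distance in meters, $1/\alpha$ the mean dispersal distance of the species,
and $y$ a street-level scaling. The kernel's printed connectivity formula
is sometimes typeset with the focal patch's occupancy inside the sum; we
use the contributing patch's occupancy $O_j(t)$, the standard form and the
only one that does not make the sum degenerate.

**Extinction.** One formula covers all four variants:
$E_i(t) = E\,(1 - C_i(t))^{R}$. The base models (LM, PRM) fix $R = 1$:
extinction is the intrinsic rate $E$ times the probability the patch was
not colonized that year. The rescue models (LM+R, PRM+R) free $R \ge 0$;
$R = 1$ recovers the base model exactly, which makes the nesting explicit
and lets likelihood-ratio sanity checks work. As printed, larger $R$ means
a smaller extinction probability, i.e. stronger rescue; prose descriptions
sometimes say rescue strengthens as $R \to 0$, but we follow the formula.
Because some descriptions instead call the base models "fixed extinction"
models, a switch `base_extinction = "constant"` replaces $E(1-C_i(t))$ by
plain $E$ for the base models; the default is the $(1-C)$ form as printed.

### Parameters and units

| Parameter | Meaning | Units | Constraint |
|-----------|---------|-------|------------|
| `C` | yearly colonization probability (PRM) | probability | [0, 1] |
| `E` | intrinsic yearly extinction probability | probability | [0, 1] |
| `alpha` | inverse mean dispersal distance (LM) | 1/m | > 0 |
| `y` | colonization scaling of the street (LM) | — | > 0 |
| `R` | rescue strength | — | ≥ 0 |

Boundary values of `C` and `E` are accepted for *simulation* (an absorbing
all-empty street under `C = 0, E = 1` is a useful test case); *fitted*
values are always interior because optimization runs on logit/log scales.

## Likelihood, missing years, AICc

The likelihood factorizes over patch-level transitions between consecutive
*observed* years. A year lost to a survey gap (2013 in the motivating
study) removes the two transitions that touch it: pairs spanning the gap
are dropped rather than marginalized, so all four models are scored on
identical data — exact two-step marginalization would be cheap for the PRM
(patches independent) but not for the LM, and AICc comparison requires a
common dataset. Probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$
inside the likelihood only, to keep logs finite at degenerate parameter
values; the model functions themselves return exact values.

Models are compared with
$\mathrm{AICc} = -2\ln L + 2k + 2k(k+1)/(n-k-1)$, with $k \in \{2,3,4\}$
and $n$ = the number of patch-level transitions, the natural sample size
of the factorized likelihood (the sources do not state the original
software's choice of $n$; patch count or year count would only rescale the
small-sample correction). Exact AICc ties — which occur when a rescue fit
collapses onto its base model — are broken toward fewer parameters, then
lexicographically.

## Optimization

Each model is fitted by Nelder-Mead on transformed scales (logit for `C`,
`E`; log for `alpha`, `y`, `R`) from 8 deterministic starting points
spread over the box logit{0.1, 0.5} × log{1/5, 1/50 m⁻¹} × log{0.1, 2} ×
log{0.5, 2}, convergence tolerance $10^{-8}$ on the log-likelihood. The LM
likelihood can be multimodal in $(\alpha, y)$ — a steep kernel with large
scaling and a flat kernel with small scaling can fit similarly — which is
what the multistart guards against. The procedure is deterministic: no
random restarts, so fits are bit-reproducible.

A series with no colonization events drives $\hat C$ (or $\hat y$) to its
lower bound; such fits are flagged `boundary = TRUE` rather than rejected,
and an all-absent series is refused outright (`select_model` errors: there
is no information to select on).

### PRM+R is not identifiable

Under constant colonization, $E (1-C)^R$ is itself constant, so the
likelihood depends on $(E, R)$ only through $\varphi = E(1-C)^R$: the pair
sits on a one-dimensional ridge and only $C$ and $\varphi$ are estimable.
This is a structural property of the model, not a fitting defect, and it
explains why PRM+R can never beat PRM by AICc on any dataset (identical
maximum likelihood, one more parameter) — consistent with PRM+R never
being selected in the motivating study. Parameter-recovery checks for
PRM+R therefore assess $C$ and $\varphi$.

## The synthetic study generator

`study_config()` defaults describe the stated world the package is tested
against: 15 streets whose patch counts are the published tree-base counts
(31–186 per street, 1,324 total) and whose green-space distances are the
published values; 15 species with the published seed-longevity classes and
maximum heights; yearly surveys 2009–2015 with 2013 blanked. Choices the
sources do not fix were made once, on plausibility, and not tuned:

* **Geometry.** Patches on a line at 8 m spacing with ±1 m uniform jitter
  (plausible street-tree spacing; only distances enter any model).
* **Generating models.** 7 species PRM, 6 LM, 2 LM+R — echoing the
  observed best-model mix (roughly 50/40/10% with PRM+R absent) with the
  rescue species being those with the highest published rescue
  proportions.
* **Generating parameters.** `C = 0.3`, `E = 0.2` (PRM); `alpha = 0.125`
  (mean dispersal one tree-spacing, 8 m), `y = 1`, `E = 0.2` (LM);
  `R = 2` for the rescue species. These give realistic intermediate
  occupancies and visible turnover over six transitions.
* **Initial occupancy.** Bernoulli(0.2) per patch, conditioned on at least
  one occupied patch per street-species pair — the study species were
  selected for prevalence, and an all-absent series carries no
  information.
* **Seeding.** One master seed is expanded into per-(street, species)
  substreams by stable label hashing, so runs are reproducible and adding
  a species does not perturb the others' draws.

What the generator does *not* emulate: soil seed banks (dormant seeds
resurface as false colonizations, biasing real data toward PRM — the
motivating study acknowledges the same limit), observation error
(false absences), patch-area variation, between-street dispersal, and
within-year dynamics. A green selection-recovery test therefore
establishes that the estimator identifies the generating process *of this
idealized world* — not that any particular real street follows that
process.

## Numerical choices

* Likelihood clamp $10^{-12}$; optimizer tolerance $10^{-8}$; AICc tie
  threshold $10^{-9}$ (ties broken toward parsimony).
* Connectivity and the LM likelihood are evaluated with one kernel matrix
  and one matrix product per likelihood call; the test suite verifies the
  vectorized path against an independent loop-based oracle to $10^{-10}$.
* Distances are planar Euclidean; coordinates are assumed projected.

## The ensemble layer

Best-model labels are aggregated into per-street and per-species counts
out of 15 and modeled as grouped binomial responses:
`glm(cbind(successes, 15 - successes) ~ covariate, family = quasibinomial)`.
The weighted-counts convention (not unweighted proportions) is the one
that reproduces the published regression slopes and p-values from the
published tables, which settles the convention question empirically.
Printed percentages are inverted to integer counts by rounding half away
from zero; on all 90 published cells this inversion is exact (re-printing
the count reproduces the cell). The reported $R^2$ is the deviance-based
pseudo-$R^2$ $1 - D_{res}/D_{null}$, which need not equal the "adjusted
R-squared" of the original analysis (definition unstated there); slopes,
not $R^2$, are the reproduction surface. p-values use the quasi-binomial
dispersion with a $t$ reference on $n - 2$ df.

## Known limitations

* No seed-bank state: like the original analysis, the four models treat a
  reappearance from dormant seed as a colonization, inflating PRM support
  on real data.
* `PRM+R` is reported for completeness but cannot win a selection and its
  $(E, R)$ are not separately interpretable (see above).
* At realistic street sizes (~150 patches, 6 annual transitions) the LM
  pair $(\alpha, y)$ is weakly identified and its MLE is right-skewed:
  across simulation replicates the *mean* $\hat y$ overshoots the truth by
  roughly 15–25% (median much closer), even though the optimizer is fully
  converged and the estimator is consistent (the skew collapses to a few
  percent at 600 patches). Interval estimates for $y$ on single streets
  should be treated with corresponding caution.
* Gap years are dropped, not marginalized; with one gap in six intervals
  the information loss is one-third of transitions for the two years
  around the gap.
* The regression layer inherits the small-n caveats of 15-unit
  quasi-binomial GLMs; it reproduces published point estimates but is not
  a substitute for the original full covariate screening (collinearity,
  spatial autocorrelation and nonlinearity diagnostics are out of scope).
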