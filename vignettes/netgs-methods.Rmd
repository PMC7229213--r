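---
title: "Network-based genomic selection: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based genomic selection: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`netgs` predicts growth from marker data by routing the prediction through a
constraint-based metabolic model instead of regressing fresh weight on SNPs
directly. The chain has four mathematical stages, all operating on the same
polytope `P = {v : S v = 0, lb <= v <= ub}` of steady-state flux
distributions.

**Reference FBA.** The reference genotype's flux distribution maximizes the
biomass flux over `P` intersected with two measured flux-ratio constraints:
carboxylation = 2.88 × oxygenation (RuBisCO) and starch synthesis = 2.58 ×
sucrose synthesis. Default bounds are −1000/1000 (reversible) and 0/1000
(irreversible) mmol gDW⁻¹ d⁻¹. Because FBA optima need not be unique, the
package provides flux variability analysis at the pinned optimum and a
parsimonious variant (secondary minimization of total absolute flux) for
when uniqueness matters.

**Genotype flux estimation.** For accession Z, the biomass column of `S` is
replaced by Z's measured composition and the flux distribution is the
minimizer of the reciprocal-weighted distance
`sum_{i in R≠0} [(v_i_ref − v_i)/v_i_ref]^2`, where `R≠0` is the support of
the reference solution — the assumption being that genetic variants modulate
the magnitude of non-blocked reactions rather than opening new routes. Two
constraints tie the solution to data: interval ratio constraints
([0.94, 3.81] and [0.79, 3.37], the measured ratios widened by their
assumed variance) and a biomass flux equal to the accession's fresh weight
expressed in model units.

The fresh-weight rescaling deserves spelling out. Measured weights `M_Z`
are first converted to ratio-scaled biomass fluxes
`(M_Z / M_ref) · v_bio_ref`; these can exceed what an accession's own model
supports, so they are compressed by `(s_model − δ)/s_measurement`, where
`s_model` is the mean of the per-accession biomass maxima (each obtained by
a small LP with a non-negativity constraint on carboxylation),
`s_measurement` the largest ratio-scaled flux, and `δ = 1.1e-4` a safety
margin keeping the largest target strictly inside the feasible range.

**Per-reaction rrBLUP.** Every flux with non-zero reference support is
modelled as `y = 1μ + Zu + e` with `u ~ N(0, σ²_u I)` over column-centred
dosages. REML estimation is exact and fast at panel scale: a single
eigendecomposition of `ZZ'` reduces the profile likelihood to a
one-dimensional search over the variance ratio. Fixed covariates (e.g. the
first ten genotype principal components) are optional and off by default —
the mixed model's fixed part is intercept-only unless the user opts in.

**The netGS projection.** Predicted flux GEBVs `g_i` need not be mass
balanced, so the growth prediction is the biomass entry of the closest
steady-state distribution under the same reciprocal weighting, with the
genotype's biomass column, interval ratios, and `w_bio >= 0`. The biomass
flux itself carries no objective weight even though a biomass flux model
exists — growth is *derived* from the network, not averaged into it.
Optionally only reactions whose cross-validated flux-model accuracy exceeds
a threshold (conventionally the classical-GS accuracy for fresh weight)
keep their objective weight; excluded reactions remain free variables.

**Cross-environment transfer.** For an unseen environment E2 only the
reference genotype requires data: its E2 flux distribution is obtained by
the same reciprocal-weighted projection with the E2 biomass column and the
measured biomass fold-change as target. The component-wise ratios of
exchange fluxes between E2 and E1 then enter the projection of any
accession as two-sided relative bands `w_j = ratio_j · g_j (1 ± ε)` for
`j` in a configurable exchange set `P`. The genotype's biomass column stays
the E1 one. Exchange bands always use the predicted `g_j`, whether or not
reaction `j` passed the accuracy threshold.

**Robustness resampling.** To quantify sensitivity to the particular
reference solution, each non-zero reference flux is resampled uniformly
from `[v(1−e), v(1+e)]`, the sample is projected back onto the constraint
set (ratio equalities slackened two-sidedly by `ε = 1e-4`, biomass pinned),
and the element-wise mean of 50 projections serves as a robustified
reference.

# Tunable parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `carb_oxy`, `starch_sucrose` | 2.88, 2.58 (fixed); [0.94, 3.81], [0.79, 3.37] (interval) | flux ratios | pathway partitioning constraints |
| `eps_band` | 0.05 | relative | half-width of the biomass equality band in the genotype and E2-reference programs |
| `delta` | 1.1e-4 | flux units | safety margin in the fresh-weight rescaling |
| `e` | user-set | relative | robustness sampling half-width |
| `eps` (robustness) | 1e-4 | flux units | slack on ratio equalities |
| `eps` (exchange bands) | 0.05 | relative | cross-environment transfer tolerance |
| `maf_threshold` | 0.05 | allele frequency | marker filter |
| `n_folds`, `n_repeats` | 3, 50 | — | cross-validation plan |
| zero-flux tolerance | 1e-9 | flux units | defines `R≠0`; reciprocal weights are unstable below it |

The biomass band: the data constraint is conceptually an equality
`v_bio = target`, feasible only approximately once the biomass column
changes per accession. It is implemented as a symmetric relative band
±`eps_band`, and on infeasibility the band widens multiplicatively (×2, at
most 3 times, each widening logged as a warning) before a hard error. A
configuration switch (`pin_zero`) fixes reactions outside `R≠0` to zero
instead of leaving them free; free is the default since those reactions
carry no objective weight.

# Numerical choices

*Quadratic programs* are solved with the dual active-set method of
`quadprog`. That method requires a strictly positive-definite Hessian,
while reactions outside the weighted set have zero curvature; they receive
a negligible ridge toward zero (relative weight 1e-8 of the smallest
reciprocal weight), which doubles as a deterministic tie-break among
equivalent optima. Degenerate vertices (more active constraints than
variables, common in small fully-determined networks) make the active-set
method report spurious inconsistency; the backend then retries with a
graded relaxation of the inequality right-hand sides (1e-9, then 1e-7 —
far below the 1e-6 reporting tolerance) and, if the rejection persists,
decides feasibility honestly with an LP phase-1 check. Redundant equality
rows (mass-consistent networks always have them) are removed by QR
factorization before either solver sees the system.

*Linear programs* (FBA, pFBA, FVA, biomass maxima) are solved by a dense
two-phase tableau simplex implemented in the package, with Dantzig pricing
and a switch to Bland's rule after a stall budget so that degenerate
problems cannot cycle. pFBA splits fluxes into positive and negative parts.
The test suite cross-checks both solvers against independent brute-force
oracles: vertex enumeration for LPs and dense KKT solves over enumerated
active sets for QPs, agreeing to 1e-6 on randomized networks.

*rrBLUP* profiles the REML likelihood over `log λ` on [−18, 18] with
Brent's method (tolerance 1e-9). With a user-fixed shrinkage the effects
reduce to the closed-form ridge solution, which the tests verify to 1e-8.
Missing dosages are mean-imputed per marker (logged); constant flux columns
are dropped from modelling and passed through predictions as constants.

*Determinism.* Every stochastic operation takes a mandatory seed; there are
no wall-clock defaults. Rerunning any pipeline stage with the same
configuration reproduces identical artifacts (checksummed in the manifest).

# What the synthetic data emulate — and what they do not

`make_toy_model("minimal")` is a deterministic 8-reaction photosynthesis
cartoon: photon/CO2/nitrate imports, a carboxylation–oxygenation pair
consuming photon + CO2 with different carbon yields, starch and sucrose
synthesis from a shared triose pool, and a biomass reaction consuming
starch, sucrose and nitrate. Its FBA optimum is hand-checkable
(CO2-limited; `v_bio = 60·(2·2.88 + 1)/((2.88 + 1)(2.58 + 1)) ≈ 29.2`).
`make_toy_model("standard")` decorates the same backbone with randomized
mass-consistent structure — intermediate chains, capacity-limited parallel
routes, amino-acid synthesis with an export valve, a water exchange — until
it has 20–40 reactions, retrying seeds until the reference FBA and the
E2-reference projection are both feasible.

`simulate_panel()` draws biallelic markers with allele frequencies uniform
on [0.1, 0.9] (so the 5% MAF filter is non-trivial), Gaussian QTL effects
split between one fresh-weight trait and two composition tilts
(starch-vs-sucrose partitioning, nitrate coefficient), and builds
accession-specific biomass compositions and fresh weights at configurable
heritabilities in two environments (E2 defaults: biomass scale 0.7,
nitrogen-poorer composition, emulating a low-nitrogen treatment). Tilt
amplitude defaults to 4% per standard deviation, which keeps every
simulated starch:sucrose ratio inside the feasibility interval
[0.79, 3.37]. Ground-truth flux matrices are produced by running the
genotype flux estimation itself on the generated compositions and weights.

What passing tests on these panels shows: the estimation-projection
machinery is exact where exactness is provable, the statistical engine
recovers known heritability structure, and netGS's growth GEBVs track
classical GS on purely additive panels. What it does not show: performance
on real metabolic networks (hundreds of reactions, gene–protein–reaction
structure, compartments), under linkage disequilibrium and population
structure, or with non-additive genetics — none of which the generators
simulate.

One structural caveat surfaced during design: in a fully coupled toy
network, imposing exchange bands with *different* fold-changes on several
exchanges simultaneously is infeasible — the stoichiometry forces their
ratios to agree with the biomass composition. Real-size networks have
escape routes (overflow metabolism, export reactions) that relax this.
The pipeline therefore defaults to the carbon-transfer configuration
(`P = {CO2 exchange}`) on toy networks; richer exchange sets are
configurable and work on networks with overflow valves.

# Evaluation design

Repeated stratified 3-fold cross-validation (shuffled round-robin folds,
sizes differing by at most one, deterministic per seed) scores each
pipeline by the Pearson correlation between measured fresh weight and
prediction in the held-out fold; records aggregate mean and s.d. over all
evaluations, with failed evaluations recorded as missing and excluded from
means. Two leakage modes are exposed: `"paper"` estimates accession fluxes
once on the full panel before cross-validation (training-fold biomass
compositions inform test-fold flux targets only through the shared scaling
constants), `"strict"` re-estimates fluxes per training fold. The default
is `"paper"`; the test suite exercises both.

Problem sizes in the test suite are chosen to make sampling error small
relative to the asserted margins: oracle comparisons use ≥20 randomized
≤6-reaction networks (where enumeration is exhaustive), statistical
recovery uses n = 200 accessions × 500 markers with 20 replicates per
heritability level, and the end-to-end comparison uses 20 simulated panels
of 200 accessions.

# Known limitations

- The support-restriction assumption (only `R≠0` reactions are weighted)
  means genuinely novel routes in a genotype are invisible to the method.
- The reciprocal weighting is undefined for reference fluxes at zero and
  unstable just above the zero tolerance; such reactions are dropped from
  objectives with a warning.
- The ε band on the biomass equality is a design interpretation: the
  equality is relaxed symmetrically by ±5% relative, chosen so that the
  feasible set stays non-empty across simulated panels; the widening
  policy makes the relaxation explicit in logs rather than silent.
- Exchange-band transfer assumes environmental shifts act through import
  capacities; regulatory effects that re-route internal fluxes at equal
  exchange rates are not representable.
- The simplex and QP backends are dense and targeted at networks up to a
  few hundred reactions; genome-scale models would need sparse solvers.
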