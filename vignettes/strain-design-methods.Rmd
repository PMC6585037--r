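---
title: "Growth-coupled strain design: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled strain design: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coupledesign)
```

## The problem

Metabolic engineering aims to force a microbe to excrete a product of
interest. A *growth-coupled* design makes product formation a side effect of
growth, so that selection for fitness also selects for production. Given a
constraint-based metabolic model — the steady-state system

$$S\,v = 0,\qquad l \le v \le u$$

over $m$ metabolites and $n$ reactions — the task is to find sets of
reaction knockouts under which every remaining way to grow also produces.
`coupledesign` implements the two families of algorithms used for this task
and the screening pipeline that makes their outputs comparable:

* **Constrained minimal cut sets (cMCS)**: enumerate the smallest reaction
  sets whose removal makes an *undesired* (target) flux space infeasible
  while a *desired* space (growth under the environment) stays feasible.
* **Multi-objective evolutionary search (SPEA2)**: evolve knockout sets
  against two simulation-based objectives.

## Phenotype simulation

`fba()` maximizes one flux (usually biomass) by LP. Because FBA optima are
degenerate, all reported metrics come from two well-defined refinements:
`pfba()` fixes the optimum and minimizes total absolute flux on the
split-reversible model (the "predicted phenotype"), and `fva()` reports
per-reaction flux ranges at a fraction of the optimum.

Growth coupling is classified by `classify_coupling()`:

* **strong** — the LP minimum of the product flux over the *whole* mutant
  flux space is at least $p_{min}$ (and growth of at least $b_{min}$ remains
  possible). Minimizing by LP is equivalent to the "for all flux vectors"
  quantifier because the flux space is a polyhedron.
* **weak** — the product minimum is only positive once growth is demanded
  ($v_b \ge b_{min}$).

Both thresholds default to $\varepsilon = 10^{-4}$, small enough not to
discard designs with low but genuine production. A pedagogically useful
fact reproduced by the tests: in the packaged TOY-B network the knockout
`{R_2}` is only weakly coupled, but becomes strongly coupled once the
maintenance drain carries a fixed positive demand — an inhomogeneous
constraint is what forces flux at zero growth.

## Target and desired spaces

A target space is a set of inequality rows $T v \ge b$ read jointly with
the model constraints. Three formulations are provided
(`build_target_space()`):

| formulation | blocks | rows |
|---|---|---|
| `MCSe` | low-yield phenotypes at bounded uptake with maintenance demand | $y_{min} v_s - v_p \ge 0$, $v_s \le s_{max}$, $v_{atp} \ge m$ |
| `MCSf` | low-yield phenotypes at *fixed* uptake | $y_{min} v_s - v_p \ge 0$, $v_s = s_{max}$ |
| `MCSw` | near-zero production at growth $\ge F \cdot b_{max}$ | $v_p \le \varepsilon$, $v_b \ge F\,b_{max}$ |

Design choices here:

* The yield ratio $v_p / v_s \le y_{min}$ is not LP-representable and is
  linearized as $y_{min} v_s - v_p \ge 0$, valid because the accompanying
  substrate rows keep $v_s > 0$.
* All rows are canonicalized to "$\ge$"; the fixed substrate of `MCSf`
  becomes an opposing inequality pair.
* Substrate terms are expressed on the uptake magnitude: a BiGG-style
  exchange (negative uptake flux) is detected by its negative lower bound
  and sign-flipped; toy-style source reactions run positive.
* `MCSw` carries no explicit substrate row: the fixed uptake of the studied
  condition lives in the model bounds/environment, which the enumeration
  respects anyway (see below).

`validate_target_space()` enforces the *origin rule*: if $b \le 0$ in every
row and the bounds admit $v = 0$, the origin of the flux cone lies inside
the undesired space. No knockout can remove the zero flux vector, so such
problems (e.g. "block low production" with a non-fixed substrate and no
coupling component) are rejected before enumeration, and the brute-force
oracle confirms that no cut set of any size exists.

## The dual system and k-shortest enumeration

Enumeration works on a dual linear system in which reactions and
metabolites switch roles: one free variable $u$ per metabolite, a
nonnegative pair $v_j, h_j$ per reaction, one nonnegative $w$ per target
row, with row $j$ reading

$$S_{\cdot j}^\top u - T_{\cdot j}^\top w + v_j - h_j \;\{\ge 0
\text{ (irreversible)}, = 0 \text{ (reversible)}\},\qquad b^\top w \ge c.$$

A feasible point is exactly a Farkas certificate of target infeasibility
*outside* the support of $v, h$: knocking out the support blocks the
target. Shortest supports are found by MILP — binaries on the $v/h$ blocks,
support-size minimization, and an exclusion row per incumbent — so cut sets
emerge in non-decreasing size until the system is exhausted.

Numerical and structural choices:

* **Witness scaling.** The strict inequality $b^\top w > 0$ of the cone
  formulation is implemented as $b^\top w \ge 1$; any positive constant
  yields the same supports because the dual is a cone.
* **Sign conventions.** With targets written as $T v \ge b$, the correct
  certificate carries $-T^\top w$ in the reaction rows and $b^\top w > 0$
  in the witness; this is the variant implemented and it is pinned down by
  property tests (every feasible dual support blocks the target LP).
* **Bounded duality.** Knockout semantics and the oracle act on the
  *bounded* flux polyhedron, not the cone, so every engaged finite bound
  (upper bounds, positive lower bounds such as maintenance ATP) is appended
  to the target block as an extra $w$ row. Without this, bound-driven
  blockings would be missed and exact oracle equality would fail.
* **Indicators.** One binary per reaction bounds both $v_j$ and $h_j$
  ($v_j, h_j \le M z_j$, $M = 10^4$ after witness scaling). This encodes
  "the two certificate directions of a reaction count once", subsumes the
  pairwise mutual-exclusion constraints of split formulations, and posts
  exclusion cuts directly on merged supports.
* **Minimality.** At MILP optimality supports are already minimal (a
  blocking proper subset would be a cheaper solution), but each incumbent
  is still LP-verified and greedily reduced (`verify_minimality()`) before
  the exclusion cut is posted — a cheap guard against numerical drift.
* **Branch and bound.** The LP relaxation of a big-M support minimization
  is weak ($z \approx v/M$), so the solver treats such tiny fractional
  values as genuinely fractional (integrality tolerance $10^{-9}$) and
  relies on diving plus incumbent pruning. At the desk scale this package
  targets (tens of reactions) trees stay small; network compression for
  genome-scale models is deliberately out of scope.

`constrain_mcs()` keeps the cut sets under which the desired space — the
environment rows plus a growth demand $v_b \ge b_{min} > 0$ — remains
feasible. A zero growth demand is rejected because it would never discard
lethal sets.

## Evolutionary search

`run_ea()` implements SPEA2: strength/raw/density fitness, an archive of
nondominated candidates with distance-based truncation, binary-tournament
mating, uniform set crossover and add/remove/replace mutation. Two fitness
schemes mirror the two design philosophies:

* **EAw** — objectives (max growth $Z$, product flux of the parsimonious
  phenotype at $Z$). The second objective is read from pFBA rather than an
  arbitrary FBA vertex, because the analysis layer itself treats pFBA as
  the predicted phenotype.
* **EAm** — objectives (max growth $Z$, FVA minimum of the product at
  $v_b = Z$), with an acceptance test: the product minimum at $v_b \ge Z/2$
  must be positive (threshold: the activity tolerance $10^{-6}$; no
  numeric value is prescribed for the strict "> 0").

Published settings are kept as defaults where stated: at most 20 deletions
per candidate, $10^5$ objective evaluations, 10 repeated runs. Population
and archive sizes (100), mutation (0.8) and crossover (0.5) rates are
unstated hyperparameters chosen per common SPEA2 practice and exposed in
the configuration; the test suite scales population/budget down (20/2000)
to fit its runtime budget, which the toy landscapes tolerate easily.
Candidates producing infeasible LPs score $(0,0)$ rather than raising —
robustness matters more than diagnostics inside a heuristic loop. The
knockout pool excludes exchange reactions, the biomass pseudo-reaction and
the maintenance drain: those are environmental or accounting fluxes, not
genetic targets. With a fixed seed a run is bit-reproducible.

## Screening and analytics

`filter_strategies()` applies three criteria in order, recording the first
failure: environmental feasibility; mutant growth at least 1% of the
wild-type's; and the growth-coupling test — FVA minimum of the product
positive at 90% of the mutant's maximum growth. "Positive" means above the
activity tolerance $10^{-6}$, not above $\varepsilon = 10^{-4}$: the
latter is the coupling-definition threshold, while the filter demands only
non-zero flux.

Metrics (`build_report()`): production robustness at 1% and 90% growth,
biomass-product coupled yield $BPCY = v_b v_p / v_s$, product/substrate
carbon yield (carbon counts parsed from metabolite formulas, with an
explicit table taking precedence), coupling class, pathway activity
distributions

$$d_j(v, p) = \frac{\sum_i p_{ji}\,|\mathrm{sgn}(v_i)|}{\sum_i p_{ji}}$$

with the sign function evaluated at the activity tolerance, mean
pathway-activity differences from the wild-type, and knockout/knockout-pair
frequency tables. Summary statistics are mean, min and max per metric (the
exact summary statistic is not prescribed anywhere, so the report emits all
three).

## Synthetic fixtures: what a green test establishes

The toy networks are *constructed* counterexamples, not biology: TOY-B has
exactly one product-free and one co-producing route to growth, so every
algorithmic claim about it (which sets are cut sets, which knockout couples,
what pFBA picks) can be verified by hand, and those hand values are frozen
into the tests. TOY-C adds two product-free bypasses — one with a 2:1
stoichiometric gain — so that no knockout pair forces production and the
unique BPCY-optimal strategy is a specific triple; recovering it is a
meaningful search problem. The random-network generator emits layered
source→intermediates→sinks networks (≤ 14 reactions, optional
reversibility, occasional coefficient-2 bypasses) regenerated until growth
and production are achievable; it emulates the *structure* of
growth-coupling problems, not genome-scale redundancy, compartments, GPR
structure or cofactor chemistry. A green oracle-equivalence suite therefore
establishes algorithmic correctness at desk scale — it says nothing about
solver performance or biological fidelity on genome-scale reconstructions,
which need commercial MILP solvers and are outside this package's scope.

## Numerical conventions

* solver feasibility $10^{-9}$; activity ("flux is nonzero") $10^{-6}$;
  coupling thresholds $\varepsilon = 10^{-4}$.
* optimum fixing in pFBA uses a relative slack of $10^{-8}$ — tight enough
  that the pFBA biomass matches the FBA optimum to well under $10^{-6}$
  relative, loose enough never to make the fixing row infeasible for the
  same arithmetic that produced the optimum.
* knockouts zero bounds instead of deleting columns, keeping indices stable
  across the pipeline; environments override bounds for exactly the listed
  reactions.
* FBA ties are broken by the simplex pivot order (deterministic for a given
  model), and all derived metrics use pFBA/FVA values that do not depend on
  the tie.

## Known limitations

* The built-in dense simplex and branch-and-bound are scoped to toy/desk
  scale (tens of reactions); genome-scale enumeration requires an external
  MILP solver and network compression, both out of scope.
* Gene-protein-reaction rules are not modelled: strategies are reaction
  deletions, not gene deletions.
* The SBML reader covers Level 3 + FBC and the Level 2 kinetic-law bound
  convention; exotic dialects (species references by metaid, local
  parameter shadowing) are not handled.
* MOMA/ROOM-style mutant predictors are intentionally absent; the pipeline
  defines mutant phenotypes through pFBA and FVA only.
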