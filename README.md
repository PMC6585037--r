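# coupledesign

Computational strain design for growth-coupled product synthesis, in R.

Metabolic engineers want mutants that *cannot grow without producing*: when
product formation is coupled to growth, adaptive evolution works for the
engineer instead of against them. Starting from a constraint-based metabolic
model — the steady-state flux space `S v = 0, l ≤ v ≤ u` — this package
generates reaction-knockout strategies by the two standard routes and then
screens and compares them with one consistent analysis pipeline:

* **Constrained minimal cut sets (cMCS).** An undesired flux space
  `T v ≥ b` (e.g. "low product yield while taking up substrate") is blocked
  by knocking out a minimal reaction set, while a desired space (growth
  under the environment) must stay feasible. Enumeration runs on the dual
  (transposed/extended) system, where feasible points are Farkas
  certificates of target infeasibility and their supports are cut sets;
  a k-shortest MILP with exclusion cuts returns them in non-decreasing
  size. Three target formulations are built in: `MCSe` (yield cut at
  bounded uptake plus maintenance-ATP demand), `MCSf` (yield cut at fixed
  uptake) and `MCSw` (near-zero production blocked only above a growth
  fraction).
* **Multi-objective evolutionary search (SPEA2)** over knockout sets, with
  the `EAw` scheme (max growth, product flux of the parsimonious phenotype)
  and the `EAm` scheme (max growth, FVA minimum of product at maximum
  growth, with a production-at-half-growth acceptance test).

Phenotypes are simulated by FBA, parsimonious FBA and flux variability
analysis; strategies are filtered (feasibility, ≥ 1 % of wild-type growth,
non-zero production at 90 % of mutant growth) and characterized by
production robustness, biomass-product coupled yield
`BPCY = v_b · v_p / v_s`, carbon yield, strong/weak coupling class, pathway
activity distributions and knockout frequencies.

Everything is validated against packaged ground truth: three hand-analysable
toy networks, a seeded random-network generator, and brute-force oracles
(exhaustive subset enumeration, exhaustive knockout search) that the MILP
and the evolutionary algorithm must reproduce exactly. No external solver is
needed: the package ships a small dense bounded-variable simplex and
branch-and-bound kernel scoped to these desk-scale problems.

## Worked example

TOY-B is a branched network in which growth (drain of `D`) can run through a
product-free route (`R_2: A → D`) or a co-producing route
(`R_1: A → B`, `R_3: B → D + P`). Which knockouts force production?

```r
library(coupledesign)
model <- toy_network("TOY-B")

# block "no production while growing at ≥ 10 % of the wild-type maximum"
target  <- build_target_space(model, formulation_params(
  "MCSw", product = "R_p", biomass = "R_bio", eps = 1e-4, F = 0.1))
desired <- build_desired_space(model, environment_spec(R_s = c(0, 10)),
                               min_biomass = 1e-4)
res <- enumerate_mcs(model, target, desired = desired, max_size = 3)
for (cs in res$cutsets) print(cs)
#> <cut_set> {R_2} size=1 minimal=TRUE constrained=TRUE
```

The enumeration also finds `{R_s}` and `{R_bio}` as minimal cut sets, but
both abolish growth, so constraining against the desired space leaves only
`{R_2}`: with the product-free route gone, every unit of growth co-produces
one unit of `P`. The coupling is weak — at zero growth nothing forces
production — until the maintenance drain carries a fixed demand:

```r
classify_coupling(model, "R_2", "R_p")
#> <coupling_class> weak (min p free=0, min p at b>=0.0001: 1e-04)
classify_coupling(toy_network("TOY-B", maintenance_lb = 1), "R_2", "R_p")
#> <coupling_class> strong (min p free=1, min p at b>=0.0001: 1.0001)
```

The report layer quantifies the mutant (fluxes in mmol/gDW/h; growth is the
drain flux of the toy biomass metabolite):

```r
crit <- filter_criteria("R_p")
rep  <- build_report(model, list("R_2"), crit, "R_s",
                     carbon = c(R_p = 4, R_s = 6))
rep$reports[, c("strategy", "max_growth", "robustness_90", "bpcy",
                "carbon_yield", "coupling")]
#>   strategy max_growth robustness_90 bpcy carbon_yield coupling
#> 1      R_2         10      8.999991   10    0.6666667     weak
```

Maximum growth stays at 10, the mutant must produce at least ~9 when growing
at 90 % of its maximum (robustness), BPCY is `10·10/10 = 10`, and with a
C4 product from a C6 substrate the carbon yield is `(10·4)/(10·6) = 2/3`.

The same analysis runs end to end from a YAML configuration, including the
SPEA2 search:

```r
run_pipeline(system.file("extdata", "toyb_pipeline.yaml",
                         package = "coupledesign"),
             out_dir = "toyb_run")
```

which writes per-formulation `strategies.tsv`, `kept.tsv`/`rejected.tsv`
(with the first failed criterion per rejection), `report.tsv`,
`summary.tsv` and a reproducibility manifest. A CLI shim is installed at
`system.file("scripts", "coupledesign", package = "coupledesign")` with
subcommands `run`, `enumerate-mcs`, `ea-optimize`, `filter`, `analyze` and
`make-fixtures`.

## Scope

Built and tested at toy/desk scale (≤ ~20 reactions). Genome-scale
enumeration needs commercial MILP solvers and network compression, and
gene-level (GPR) deletions are out of scope; see the methods vignette
(`vignettes/strain-design-methods.Rmd`) for the full list of design
decisions and limitations.
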