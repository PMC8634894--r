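# actnet — executable activity-network models of cell signalling

`actnet` is an R toolkit for building and interrogating *executable* models
of cell-signalling networks of the kind used to study cell-fate decisions —
for example the switch between the chondrocyte master regulators SOX9
(permanent, articular cartilage) and RUNX2 (transient, hypertrophic
cartilage that templates bone).  It is aimed at systems biologists who want
to simulate, screen and formally query a signalling network without writing
ODEs or learning a model checker.

## The formalism

A model is a directed graph.  Each node carries a discrete **activity
level**, an integer in `[0, levels]` (default 100), read as a concentration
on an arbitrary scale or as the percentage of active molecules.  Each edge
is an activation or inhibition with one rate parameter *k* and a kinetic
scenario; with activities normalised to `a = level/levels`:

| scenario | rate law            | use                                        |
|----------|---------------------|--------------------------------------------|
| 1        | `R = k·a[E]`        | regulator-limited kinetics                 |
| 2        | `R = k·a[E]·avail(S)` | substrate-limited kinetics (availability = target's inactive fraction for activations, active fraction for inhibitions) |
| 3        | `R = k·a[E1]·a[E2]` | AND gates: both regulators required        |

*k* = 1.0 encodes "fast" (post-translational) and 0.1 "slow"
(transcription/translation); time units are abstract, so only steady-state
(attractor) results are meaningful.  The deterministic event-driven
simulator advances one node by ±1 per event — the node whose timeout
`t_last + (1/levels)/|net rate|` is earliest — which discretely approximates
the underlying rate equations; an independent continuous-integration oracle
(`ode_oracle()`) is included to verify that.  Attractors are fixed points,
small limit cycles (reported as time-weighted mean levels), or the all-zero
Null state.

On top of the simulator:

* **Boolean translation** (`parse_boolean_rules()`, `boolean_to_network()`):
  OR branches become independent additive edges, binary ANDs scenario-3
  edges, NOT literals inhibitions; every node gets a self-inhibition so
  activity decays without upstream input; dual expression/PTM proteins
  expand into the three-node `_prot`/`_PTM` pattern.
* **Monte Carlo fate screens** (`monte_carlo_fates()`,
  `single_perturbation_screen()`, `pairwise_switch_screen()`): uniform
  random initialisation, attractor classification, knockout (clamp 0) and
  constitutive activation (clamp 100) perturbations, binomial 99% CIs.
* **Bounded reachability** (`check_persist()`, `check_reach()`):
  CTL-style queries — `A[] p` (persist), `A<> p` / `E<> p` (reach) — over
  the deterministic dynamics, with optional *delayed interventions*
  ("clamp IGF to 100 at some unspecified later event") enumerated over a
  finite set of timing choices.
* **Model I/O**: a documented JSON model format
  (`inst/extdata/model-format.md`), SIF and GraphML export, bundled motifs
  (`motif()`), a seeded random-network generator, and a CLI (`run_cli()`).

## Worked example

The canonical additive-OR motif: a hub activated independently by four
sources (k = 0.444 each, balanced against a fast self-inhibition k = 1.0).
With one source fully active, the net rate at level `L` is
`0.444 − L/100`, so the hub rises to 44, overshoots to 45, and oscillates —
a period-2 limit cycle whose time-weighted mean 44.4 is reported as **44**:

```r
library(actnet)
ras <- motif("ras_motif")
ras <- apply_clamps(ras, list(Wnt = 100, BMP = 0, FGFR1 = 0, FGFR3 = 0))
find_attractor(ras)
#> <actnet_attractor> limit_cycle (period 2)
#>   events to reach: 44
#>   active nodes: Wnt=100, Ras=44
```

A Monte Carlo fate screen on the bundled tri-stable mutual-inhibition
fixture (masters `X` and `Y`, classifier `X+`: X ≥ 60 & Y < 20, `Y+`
symmetric, `Null`: all zero):

```r
fd <- monte_carlo_fates(motif("mini_chondro"), 10000, seed = 1,
                        default_classifier("X", "Y"))
fd
#> <fate_distribution> n = 10000
#>        fate count proportion ci_halfwidth     ratio
#>          X+  4300     0.4300  0.012752306        NA
#>          Y+  4375     0.4375  0.012778132        NA
#>        Null  1325     0.1325  0.008732926        NA
#>       other     0     0.0000  0.000000000        NA
#>  unresolved     0     0.0000  0.000000000        NA
#>       X+/Y+    NA         NA  0.054364946 0.9828571
```

Each row is a fate class with its count over the 10,000 random
initialisations, the proportion, and the 99% Wald CI half-width; the last
row is the ratio of the two master fates with a delta-method CI.  The same
run is reproducible from `(model, n, seed)` alone.

From the shell, the same analyses:

```sh
Rscript -e 'actnet::run_cli()' attractor --fixture ras_motif \
    --clamp Wnt=100,BMP=0,FGFR1=0,FGFR3=0
Rscript -e 'actnet::run_cli()' fates --fixture mini_chondro \
    --n 10000 --seed 1 --classifier X:Y --out fates.csv
Rscript -e 'actnet::run_cli()' check --fixture delayed_switch \
    --property "E<> T >= 60" --intervene IGF=100@200
```

## Layout

* `R/`, `src/` — implementation (R surface, Rcpp event engine + oracle)
* `inst/extdata/models/` — bundled motif model files
* `inst/extdata/model-format.md` — the model file format
* `vignettes/activity-networks.Rmd` — semantics, numerics and design choices
* `tests/testthat/` — unit, property and acceptance tests
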