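---
title: "Activity-network models: semantics, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-network models: semantics, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actnet)
```

## The model class

`actnet` works with *activity networks*: directed graphs whose nodes are
molecular species (ligands, kinases, transcription factors, mRNAs) carrying a
discrete activity level — an integer between 0 and `levels`, 100 by default —
and whose edges are signed interactions, each governed by a single rate
parameter $k$ and one of three kinetic scenarios.  A level of 30/100 reads as
"30% of this kinase population is active" or as a concentration on an
arbitrary scale; the formalism deliberately does not distinguish.

With activities normalised to $\hat a = \mathrm{level}/\mathrm{levels} \in
[0,1]$, an edge's rate of occurrence is

* scenario 1: $R = k\,\hat a_E$ — depends only on the upstream regulator;
* scenario 2: $R = k\,\hat a_E\,\mathrm{avail}(S)$ — also on the target
  substrate's availability;
* scenario 3: $R = k\,\hat a_{E_1}\hat a_{E_2}$ — AND kinetics: two
  regulators, both required.

The net rate of a node is the sum over activating in-edges minus the sum over
inhibiting in-edges.  Time units are abstract: the class constants
$k = 1.0$ ("fast", post-translational events) and $k = 0.1$ ("slow",
transcription/translation) encode only that signalling outruns gene
expression, never real minutes.  All analyses here therefore concern
steady-state behaviour — attractors — not time-bound predictions.

### The scenario-2 availability convention

The scenario-2 rate law multiplies the regulator's activity by "the
substrate".  Read literally this is ambiguous: the pool an activation
consumes is the *inactive* fraction of the target, while an inhibition
consumes the *active* fraction.  `actnet` adopts exactly that convention,
$\mathrm{avail}(S) = 1 - \hat a_S$ for activations and $\hat a_S$ for
inhibitions, for two reasons: a fully active target can then no longer be
activated (the substrate pool is exhausted), and a fully inactive target can
no longer be inhibited.  The alternative (always using $\hat a_S$) would make
activation of a silent target impossible through scenario 2 alone.  This is a
genuinely open reading; it is recorded here as the package's choice.

## Event-driven simulation semantics

The simulator advances the network one unit step at a time.  Every unclamped
node $v$ with net rate $\rho_v \neq 0$ owns a timeout

$$ t_v = t_{\mathrm{last}}(v) + \frac{1/\mathrm{levels}_v}{|\rho_v|}, $$

where $t_{\mathrm{last}}(v)$ is the time of $v$'s previous update (its clock
reset).  The earliest timeout fires; the node moves by $\mathrm{sign}(\rho_v)$;
every timeout is then recomputed from the new state (the "change in
conditions" rule).  The $1/\mathrm{levels}$ factor makes the discrete system
track the normalised rate equations $d\hat a/dt = \rho(\hat a)$: a node whose
net rate is constant crosses one level in exactly the time the continuous
system would.

Numerical and semantic choices, all deliberate:

* **Tie-break.** Simultaneous timeouts are resolved by node declaration
  order.  Determinism demands a total order; declaration order is the only
  one the user controls directly.
* **Stale timeouts.** If a recomputed timeout lies in the past (a node's
  conditions changed long after its clock reset), the event fires
  immediately at the current time.  This mirrors the underlying
  timed-automata semantics, where the node's clock keeps running while it
  waits.
* **Saturation.** A node pushed against 0 or its top level by its net rate
  schedules no event until the sign flips; clamped nodes never schedule
  events but still drive downstream rates.
* **Quiescence.** No schedulable node means a fixed point.  The all-zero
  fixed point is reported as the distinguished `null` attractor.
* **Cycle detection and confirmation.** The dynamics around a non-integer
  stable fixed point is a small oscillation (typically ±1).  A candidate
  cycle opens when the integer activity vector recurs, and is *confirmed*
  only after one further full period replays with identical states and
  identical event spacings.  The confirmation step guards against transient
  coincidences of the activity vector at different clock phases, which the
  bare recurrence test cannot distinguish.
* **Reported cycle levels.** For a limit cycle the reported level is the
  time-weighted mean activity over one period, rounded to the nearest
  integer with ties rounded *down*.  For a one-node oscillation around a
  fixed point $\hat a^*$, the time weights are inversely proportional to the
  local net rate, and the weighted mean works out to exactly
  $\mathrm{levels}\cdot\hat a^*$ (to first order) — e.g. the additive-hub
  worked example oscillates between 44 and 45 with mean 44.4 and reports 44.
* **Event budget.** `max_events` defaults to
  $10 \cdot \mathrm{levels} \cdot n_{\mathrm{nodes}}$.  Exhausting it yields
  an `unresolved` attractor, never an exception, and `unresolved` is carried
  through fate tables as its own class rather than being folded into Null.

### Fidelity to the continuous dynamics

`ode_oracle()` integrates $d\hat a/dt = \rho(\hat a)$ by projected explicit
Euler (step $10^{-3}$, convergence when $\max_v |d\hat a_v/dt| < 10^{-9}$,
both configurable).  The step is small against the fastest time constant in
the class system (1 for $k = 1$), and since Euler's fixed points are exactly
the rate equations' fixed points, the step size does not bias the reported
equilibrium — it only has to be stable, and convergence is declared on the
residual, not on step-to-step movement.  The oracle shares no code with the
event-driven engine, so the two can check each other: on networks with a
unique stable fixed point, discrete reported levels match
$\mathrm{round}(\mathrm{levels}\cdot\hat a^*)$ within one level.  The match
is exact at saturated or integer equilibria and degrades only where several
coupled nodes oscillate at very low levels (1–3), where one level is a large
relative error; the one-level tolerance absorbs this.

## Boolean translation

`boolean_to_network()` converts Boolean/additive rule models:

* each OR branch becomes an independent edge, so OR is additive and
  non-exclusive — several active sources activate faster;
* a binary AND becomes one scenario-3 edge (n-ary ANDs must be nested
  explicitly through intermediate nodes; an AND over a negated literal is
  rejected, because scenario 3 multiplies activities and cannot express
  $1-\hat a$);
* a NOT literal becomes an inhibition edge;
* every non-constant node receives exactly one self-inhibition loop with the
  $k$ of its reaction class, making activity decay to 0 absent upstream
  activation — the explicit counterpart of the Boolean convention that an
  unactivated node reverts to 0.

An edge's class (hence its $k$ scale) is taken from its *regulator's*
reaction class — a gene-expression-class source drives a slow edge — with
slow dominating for scenario-3 pairs.  This is the reading that makes the
dual-regulation split well defined: when a protein must be both expressed and
post-translationally modified (`@dual`), its slow influences are rewired to a
`_prot` node, its fast influences to a `_PTM` node, and the protein itself is
activated solely by the scenario-3 conjunction of the two.  OR-branch weights
(e.g. the 0.444 used when one hub is fed by four balanced sources) are
treated strictly as input data: the package does not invent a balancing
formula, because none is specified by the class system itself.

Constant inputs are expressed as clamps (`@const(v)` in rule files), which
unifies three ideas under one mechanism: dummy nodes with fixed activity
used to encode piecewise kinetics, in-silico knockouts (clamp 0), and
constitutive activation (clamp full scale).

## Monte Carlo screens

`monte_carlo_fates()` draws every unclamped node uniformly on
$\{0,\dots,\mathrm{levels}\}$, simulates to the attractor and classifies it.
Per-run seeds are derived from one master seed by a counter-based splitter
(`derive_seed`), so screens are reproducible run-by-run and order-independent.
Confidence half-widths use the Wald normal approximation
$z_{(1+c)/2}\sqrt{\hat p(1-\hat p)/n}$ — at $n = 10^6$ and 99% confidence
this reproduces the conventional printed ± columns after two-decimal
rounding — and the between-fates ratio carries a first-order delta-method CI,
flagged approximate.  Baseline and perturbed screens use independent derived
streams (no common-random-number coupling); deviations are therefore
conservative by up to the sum of the two half-widths.

## Bounded reachability instead of full model checking

The deterministic core makes classical branching-time queries collapse: with
no intervention, "always" and "possibly" coincide and one simulation decides
them.  The only nondeterminism the package models is the *timing* of a
delayed clamp (e.g. adding a growth factor at an unspecified later moment).
`check_reach()` therefore enumerates one deterministic run per choice in a
finite set of event indices $\{0, 1, \dots, K, \mathrm{never}\}$ ($K$
defaults to 200): *possible* holds if some branch visits a satisfying state
(witness returned), *guaranteed* if all do.  Verdicts are three-valued — a
truncated branch that never satisfied the predicate yields `unknown`, because
a bounded horizon cannot certify an infinite-behaviour claim; persistence is
certified up to the attractor plus one full period.  If the model goes
quiescent before the chosen event index, the clamp is applied at that
quiescent point and the run continues: "after $n$ events" is read as "no
earlier than", since a quiescent model still experiences wall-clock time.
This enumeration reproduces the qualitative finding pattern of interest —
"reachable only with later addition" — without a model-checker dependency,
at the price of not exploring interleavings the deterministic core cannot
produce anyway.

## What the synthetic fixtures do and do not establish

The package ships motifs exercised by every module (`motif()`), a seeded
random-network generator, and the continuous oracle.  Two fixtures deserve
comment:

* `mini_chondro` is an original 12-node mutual-inhibition network — two
  master regulators, each sustained by a cooperative feedback loop through a
  branch activator, ignited by slowly decaying signal nodes and read out by
  downstream markers.  Its parameters were chosen once, for qualitative
  structure: a cooperative activation threshold high enough that a
  substantial fraction of uniform random starts collapses to Null, strong
  mutual inhibition (k = 4) for winner-take-all exclusivity, and
  switchability by pairwise clamps.  A green tri-stability test establishes
  that the simulator and screens reproduce that *designed* structure — three
  attractor classes, mutual exclusivity, clamp-induced switches — not that
  any real chondrocyte network has three fates, nor the fate proportions of
  any full-scale tissue model, which depend on a topology this package does
  not ship.
* `delayed_switch` realises the delayed-intervention pattern: a fast
  transient (`PRE`) that lets a blocker latch if the input is added too
  early, and a slow permissive gate that closes if it is added too late.
  It demonstrates the reachability layer's semantics on a network where the
  correct answer is known by construction.

The random generator draws k only from the two class constants and never
creates clamped nodes, so the all-zero state is always quiescent; real
curated networks additionally contain balanced hand-tuned weights and
constant dummy inputs, which the generator deliberately does not emulate.

## Known limitations

* No stochastic update mode: the engine is deterministic by design, and
  nondeterminism enters only through enumerated intervention timings.
* Scenario 3 is strictly binary; wider conjunctions are the user's job, by
  nesting.
* Cycle reporting assumes the attractor cycle is short relative to the event
  budget; pathological long cycles surface as `unresolved`.
* The CLI accepts a JSON configuration file (flags win); no YAML dialect is
  supported.
* GraphML/SIF exports are one-way; the JSON dialect is the only import
  format.
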