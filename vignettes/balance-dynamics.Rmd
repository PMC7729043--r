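---
title: "Coevolving opinions and signed ties: model, observables and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolving opinions and signed ties: model, observables and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`socialbalance` simulates a society of `N` agents with binary opinions
`s_i ∈ {−1, +1}` connected by an undirected network whose links carry
signs `J_ij ∈ {−1, +1}` (friendly or hostile; unlinked pairs have
`J_ij = 0`). The microstate `(s, J)` evolves to reduce a global
social-stress function

    H(s, J) = − Σ_(i,j) J_ij s_i s_j  −  g Σ_(i,j,k) J_ij J_jk J_ki
              + (h/2) Σ_(i,j) (1 − J_ij),

where the first sum runs once over each linked pair, the second once
over each closed triangle, and the third again over linked pairs. The
three terms encode, in order: homophily (friends prefer agreeing,
enemies disagreeing), Heider triadic balance (triangles whose sign
product is negative carry tension), and an optional exogenous
pro-social field that penalizes hostile links. The sum conventions are
normative for this package: counting pairs or triangles with different
multiplicities would merely rescale `g`, `h` and the temperature, so
all documented parameter values assume once-per-pair and
once-per-triangle sums.

Key model assumptions worth keeping in mind:

* one binary opinion dimension; no opinion strength or multiple topics;
* undirected, unweighted, single-layer relations;
* agents implicitly "know" the global stress change of their local
  moves — the dynamics is a relaxation of a global objective, not a
  boundedly rational local rule;
* the same temperature governs opinion and link volatility.

## Dynamics

Updates follow a Metropolis scheme. One **time step** consists of
`round(n·N)` single-opinion updates (a uniformly random agent proposes
to flip `s_i`) followed by one link update (a uniformly random link
proposes to flip its sign). A proposal with stress change `ΔH ≤ 0` is
always accepted; otherwise it is accepted with probability
`exp(−ΔH/T)`. The social temperature `T > 0` sets how often
stress-increasing changes happen; `g ≥ 0` weighs balance against
homophily; the rate parameter `n` (default 1) controls how many opinion
attempts occur per link attempt. For `n·N < 1` the package performs a
single opinion attempt with probability `n·N` per step, and a
`fast_links` switch moves the link update ahead of the opinion attempts
for the regime where ties change faster than minds.

With rewiring probability `p > 0`, a link update instead proposes a
compound move: delete a uniformly random link and create one between a
uniformly random currently-unlinked pair, with sign drawn according to
`rewiring_mode` (`"random_sign"`: ±1 equiprobably; `"homophilious"`:
+1 exactly when the endpoints agree). The compound move is accepted or
rejected as a single Metropolis proposal on its exact `ΔH`, so the link
count is conserved and, at fixed topology (`p = 0`), the chain
satisfies detailed balance with respect to `exp(−H/T)`. The test suite
checks this exactly on the complete triad, where the empirical state
distribution over all 64 microstates is compared with the enumerated
Boltzmann weights.

All stress changes are evaluated incrementally (an opinion flip touches
only incident links; a link flip touches only the endpoints' opinions
and common neighbours), with an exact full recomputation at the end of
every run guarding the bookkeeping. When `g` and `h` are integers the
arithmetic is exact in floating point, which is what makes the
small-instance enumeration oracles bit-exact.

## Topologies and initial conditions

The generators define the study conditions and are first-class, tested
code:

* `ring_lattice(N, k)` — every agent linked to its `k/2` nearest
  neighbours per side; requires even `k < N`.
* `small_world(N, k, epsilon)` — each lattice link independently with
  probability `epsilon` has one uniformly chosen endpoint reattached to
  a uniform non-neighbour; proposals that would create self-links,
  duplicates or disconnect the graph are rejected and resampled (up to
  100 attempts, then the link is left in place). Link count and mean
  degree are conserved exactly; only connectivity is enforced —
  degree-1 nodes may occur.
* `complete_network(N)` — for worked examples and enumeration.
* `randomize_state(net, p_plus, p_up)` — i.i.d. link signs (+1 with
  probability `p_plus`) and opinions (+1 with probability `p_up`).
  Defaults are ½/½, the equiprobable random initial condition of the
  reference experiments; they are overridable because equilibration
  speed depends visibly on the initial fraction of friendly ties.

What the generator does *not* emulate: degree heterogeneity beyond
small-world rewiring (no scale-free tails), clustering patterns of real
social networks, communities built into the topology, or any empirical
sign/opinion correlations. Passing tests therefore demonstrate
properties of the model under idealized topologies, not claims about
any observed society.

## Observables

* **Triangle census and balance index** — `triangle_census()` counts
  balanced (`n₊`) and unbalanced (`n₋`) triangles once each;
  `balance_f()` returns `f = (n₊ − n₋)/(n₊ + n₋) ∈ [−1, 1]`. On a
  triangle-free topology `f` is undefined and returned as `NA` with a
  warning — deliberately not 0, which would misread such graphs as
  maximally frustrated.
* **Relative stress** — `relative_stress()` returns `e_f = H/|H_gs|`
  where `H_gs = −(E + g·N_Δ)` is the exact ground state of the
  topology (every edge, triangle and field term is minimized
  simultaneously by the all-friendly, all-aligned configuration).
  `e_f ≥ −1` always, with equality exactly at zero remaining tension.
* **Opinion alignment** — `m = |Σ s_i|/N ∈ [0, 1]`.
* **Positive clusters** — components of the positive-link subgraph
  (isolated agents are singletons; sizes sum to `N`).
* **Signed partition and echo chambers** — see below.

A soft expectation, monitored in tests rather than enforced: stationary
states in practice have `f ≥ 0`; negative stationary `f` would signal
something badly wrong with the dynamics.

## The frustration-minimizing partition

`signed_partition()` minimizes the signed-blockmodel objective — the
number of positive links between clusters plus negative links within
them — over partitions with a free number of clusters. The minimum of
this objective over all partitions is the line index of balance, and
the objective is NP-hard, so the package uses a heuristic:

1. **node-move passes**: in random order, move single agents to the
   neighbouring (or a fresh singleton) cluster that most reduces
   frustration, iterated to a local optimum;
2. **merge rounds**: repeatedly merge disjoint cluster pairs whose
   inter-cluster links have a positive sign surplus (each such merge
   strictly lowers the objective), in descending-gain order;
3. alternate 1 and 2 until neither improves, and keep the best of
   `restarts` initializations — one seeded by the positive-link
   components, one by singletons, the rest by uniform random labels.

The merge phase matters: node moves alone systematically under-merge on
large balanced states (single-agent moves cannot fuse two mutually
friendly clusters in one step), which fragments clusters and truncates
echo-chamber sizes. With `exhaustive = TRUE` (N ≤ 10) all set
partitions are enumerated instead; the test suite uses this oracle to
verify that the heuristic never reports a value below the true minimum
and matches it on at least 90% of random signed graphs.

**Echo chambers** are the clusters of this partition whose members all
hold one opinion; mixed clusters contribute none, and singletons count
as (trivially like-minded) chambers of size 1. They are computed from
the partition, not from raw positive components — the two reports are
returned side by side, since positive components answer "who can
cooperate?" while echo chambers answer "who agrees inside a friendly
bubble?". Negative-cluster refinements of the partition are
deliberately out of scope. By default all chambers per run are
aggregated into the size distribution; a `largest_only` flag restricts
reports to the per-run maximum.

## Stationarity and convergence time

Runs stop by a sliding-window rule on the stress: at each step the
means of `H` over the two trailing non-overlapping windows of
`W = kN/10` steps are compared, and the run is converged at the first
step where they differ by less than `tol = 0.5`, guarded against slow
monotone drift by also requiring the mean over the third-trailing
window to lie within `2·tol`. Both `W` and `tol` are arguments. After
convergence the run continues for one further window, over which the
stationary observables are averaged; runs that exhaust `max_steps`
(default `50·kN`) are censored — their trailing window still yields
stationary averages, but `tau` is reported as `NA` and censored runs
are excluded from convergence-time means, with a warning.

The convergence time `τ = t_conv/(kN)` is reported in units of `kN`
time steps, the scale on which the whole link set updates a few times.
Two caveats, both visible in the test suite's numbers:

* an `H`-based plateau rule keeps counting while rare jammed-state
  escapes still lower `H` after `f` and `m` have effectively plateaued,
  so it is a conservative (long) reading of equilibration at low `T`;
* at high `T` the rule can fire during the approach to equilibrium
  (window means of a noisy `H` agree by chance), so high-temperature
  stationary observables are averaged over a window that may slightly
  precede full relaxation. Tightening `tol` per experiment (as the
  external-field tests do) is the intended remedy when late, slow
  observables such as consensus formation are the quantity of interest.

## Experiment drivers and problem sizes

`phase_diagram_scan()`, `hysteresis_sweep()`, `external_field_scan()`
and `convergence_time_experiment()` wrap the runner with per-cell
realization loops, bit-reproducible under a single seed. The hysteresis
protocol carries the final state of each temperature into the next as
the initial state, runs a fixed `5·kN` steps per temperature (no
convergence stopping) and measures over the trailing window, upward
then downward.

The package's own choices of problem size for its shipped checks: the
phase-diagram cells run `N = 400` with 50 realizations, convergence
times `N = 200, k = 10` with 100 realizations, hysteresis `N = 50,
k = 30` with 8, and cluster-structure sweeps 100 realizations — sizes
at which every headline phenomenon (fragmentation at high `k`/low `T`,
spanning cooperation at high `T`, hysteresis at high `k`, field-driven
consensus) is clearly resolved on a single CPU. Realization counts an
order of magnitude larger would shrink error bars but change none of
the qualitative structure.

## Numerical choices and degenerate inputs

* `ΔH = 0` proposals are accepted deterministically.
* Metropolis acceptance caches `exp(−d/T)` for integer `d ≤ 512`;
  non-integer `ΔH` (non-integer `g` or `h`) falls back to `exp()`.
* Uniform link selection uses an indexable edge registry with O(1)
  swap-delete, so rewiring keeps selection uniform over the *current*
  link set.
* Rewiring picks the new pair among pairs unlinked *before* the move
  (the deleted pair is excluded); on dense graphs with no free pair the
  move is abandoned as rejected.
* Triangle-free topologies are legal everywhere: the balance term is
  inert (verified by seed-identical runs at different `g`), `f` is
  `NA`, and the Hamiltonian reduces to homophily plus field.
* Agents with no links flip freely (`ΔH = 0`); empty networks are
  rejected where an observable would be undefined.
* `exhaustive_minimum()` is guarded to `N + E ≤ 20` (≈10⁶ stress
  evaluations).

## Known limitations

* The partition heuristic is a local search; on large frustrated states
  it can overestimate the line index (never underestimate it).
* τ is criterion-dependent; compare values across settings only under
  the same `W`, `tol` and measurement convention.
* Weighted/directed ties, multi-layer networks, multi-dimensional
  opinions and distinct opinion/link temperatures are out of scope.
* The max-size statistics of cluster reports (largest echo chamber
  across many runs) are extreme-value quantities with heavy tails;
  expect large seed-to-seed variation.
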