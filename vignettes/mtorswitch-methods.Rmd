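---
title: "Methods: rule expansion, simulation, and bifurcation protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule expansion, simulation, and bifurcation protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how `mtorswitch` turns its rule-based model of the
AMPK–MTORC1–ULK1 network into numbers: the rule semantics, the numerical
settings, and the judgement calls made where more than one reasonable
design existed. It states no empirical result beyond what the test suite
and the acceptance script compute.

## The model and its assumptions

Seven molecule types are tracked at site resolution: rapamycin\*
(FKBP1A-bound rapamycin, one binding site), AMPK\* (binding site for ULK1;
a lumped serine/threonine site `ST` that ULK1 phosphorylates; the
kinase-domain site `T172`), MTOR (`HEAT` repeats binding RPTOR, the `FRB`
domain binding rapamycin\*), RPTOR (`WD40` for MTOR, `RNC` for EIF4EBP1,
an unstructured `ulk1` region, phosphosites `S792` and the lumped
three-state `S855_S859`), ULK1 (`straptor` and `stampk` regions,
phosphosites `S317`, `S758`, `S778`), and the two reporter substrates
EIF4EBP1 and AMBRA1. Key mechanistic assumptions baked into the 29 rules:

* MTOR is an active kinase only while bound to RPTOR; rapamycin\* and
  RPTOR binding to MTOR are mutually exclusive (each binding rule requires
  the other site to be free).
* ULK1 is an active kinase when phosphorylated at S317 and S778 and free
  of RPTOR. The rules encode activity exactly as printed in the model
  specification: they test `straptor` freedom plus S317\~P and S778\~P,
  and do **not** additionally require S758\~0, although prose descriptions
  of ULK1 regulation sometimes add that condition. We kept the executable
  rules authoritative; the network census (below) confirms this reading.
* Kinase–substrate reactions between free proteins (ULK1→AMBRA1,
  ULK1→AMPK, AMPK→RPTOR) are modelled as pseudo-second-order mass action,
  i.e. substrate-limited Michaelis–Menten far from saturation.
* Dephosphorylation is by constitutively active, unregulated phosphatases:
  first order with a common rate `u0 = 1e-2/s` (the system's characteristic
  response time, 100 s), except RPTOR S792 (`u1 = 1e-3/s`, shielding of
  pS792 by 14-3-3 binding) and the AMPK feedback sites
  (`u2 = 1e-4/s`, making the negative feedback slow).
* The inputs AMPK\* and rapamycin\* are fixed totals with no synthesis or
  decay (outside drift mode): their upstream regulation is out of scope.

Three transcription-variant spellings of the lumped RPTOR site
(`S855_S859`, `S855_Ser859`, `S855-9`) appear in printed rules; the parser
canonicalises all of them to `S855_S859`.

### The T172 site

The printed AMPK molecule type omits T172, yet several rules test
`T172~P`. Since every AMPK copy in the model *is* AMPK\* (the
kinase-domain-phosphorylated form), we declare T172 explicitly and pin it
to `P` in the seed species; no rule modifies it. The printed rules then
apply verbatim and the unreachable `T172~0` branch never enters the
network.

### Redundant-looking rules are kept

Two rules dephosphorylate RPTOR S792 (rates `u1` and `u0`); both are kept,
so the effective rate is `u1 + u0`. Likewise a fully phosphorylated
RPTOR–ULK1 complex matches both the unconditional (`d3`) and the
phosphorylation-gated (`d3max`) dissociation rule; both fire, total rate
`d3 + d3max`. This is standard independent-rule semantics, and the rule
and network censuses only close with both members present.

## Network expansion semantics

Expansion seeds the network with the seven unmodified monomers (AMPK with
T172\~P) at their nominal copy numbers and applies every directed rule
(bidirectional rules count once per direction) to every matching species
tuple, adding novel products until closure; a second deterministic pass
then enumerates one unidirectional reaction per (directed rule, ordered
reactant tuple, product multiset). Choices that matter:

* **Structural expansion.** Reactions are generated independently of rate
  values; the AMPK→RPTOR rule (`p9`, nominally 0) contributes its species
  and reactions at rate 0. This is what reaction-network generators do,
  and the published census — 173 species, 6,581 reactions, reproduced
  exactly by the engine and asserted in the tests — closes only under this
  convention (5,476 of the reactions are p9-generated).
* **Rates.** Each reaction's rate value is rate constant × statistical
  factor × embedding multiplicity. The statistical factors (2 on the first
  phosphorylation and the last dephosphorylation step of the doubly
  phosphorylatable S855/S859 site) are written in the rules themselves.
  Every complex in this model contains at most one molecule of each type,
  so embedding multiplicities are provably 1; a regression test asserts
  this so that future rule edits cannot silently double-count.
* **Identity.** Reactions identical in reactants and products but arising
  from different rules are kept distinct (e.g. the two S792
  dephosphorylation routes); this is how the published reaction count is
  defined.
* **Canonical labels.** Molecules are ordered by iterative sorted
  refinement over (type, site states, bonded-neighbour keys); remaining
  ties — true automorphisms — fall back to exhaustive permutation, taking
  the lexicographically smallest serialisation. A permutation oracle in
  the test suite checks label invariance exhaustively.

## ODE integration

Mass-action fluxes and the analytic Jacobian are assembled in C++ from the
reaction table and handed to deSolve's `vode` (BDF) integrator as native
callbacks, with `rtol = 1e-8`, `atol = 1e-6` copies/cell. These mirror the
tight tolerances of the CVODE-class solvers customarily used on such
networks; the tolerance-robustness test verifies that halving them moves
endpoint observables by less than `1e-4`. Steady states are found by
integrating geometrically growing time chunks until
`max |dx/dt| / max(1, x) < 1e-10` (cap `1e7 s`). Observables are linear
functionals of the state: phosphorylated fractions of AMBRA1, EIF4EBP1,
and the individual ULK1/RPTOR sites (the lumped S855/S859 site reports
occupancy, counting the singly phosphorylated state as one half).

Stress application follows step-input semantics: from the unstressed
steady state (AMPK\* = 30,000 copies/cell, no rapamycin\*), input totals
are reset at t = 0 by adding or removing copies of the free unmodified
monomer only, leaving every other species untouched.

## Slow-drift bifurcation protocol

A sweep augments the network with a zeroth-order source of the input
monomer (up) or a first-order sink removing the input molecule wherever it
occurs (down), so the input drifts slowly while the fast network tracks a
quasi-static attractor. The drift rate defaults to traversing the range in
5,000 characteristic response times (`5000/u0 = 5e5 s`), tying "slow" to
the system's own time scale; a self-consistency test checks that halving
the drift rate moves branch values by under 1%. Down sweeps decay the
input exponentially and are truncated at 1/1000 of the upper end. Rate
constants can be drifted too, via a linear ramp applied inside the
compiled right-hand side.

Analysis thresholds, all configurable:

* **Bistability** (hysteresis): up- and down-sweep branches of the
  AMBRA1-P fraction differing by more than 0.2 on a common input grid.
* **Oscillation in a sweep**: turning-point detection with prominence
  0.01 on the AMBRA1-P fraction; an oscillatory window needs at least 3
  prominent maxima spanning at least 2% of the sweep range (so a single
  switching transient with brief ringing does not count), is bounded by
  the span of committed extrema, and is padded by one median inter-peak
  spacing because the first recorded peak lags the true onset by about one
  drifted period. The first committed extremum — the endpoint of the
  starting branch's monotone drift — is discarded.
* **Limit cycle at fixed inputs**: successive 40 h windows, first half of
  each discarded, until two consecutive windows agree in amplitude within
  5% (oscillating if peak-to-trough amplitude of the AMBRA1-P fraction
  exceeds 0.01) or the amplitude collapses with stable window means
  (steady). The period is the mean interval between upward midline
  crossings; below amplitude 0.05 crossing detection is unreliable and the
  autocorrelation peak is used instead. Phase durations split each period
  at AMBRA1-P fraction 0.5 (autophagy phase above, translation phase
  below; the two sum to the period by construction).

Two-parameter regime maps repeat one-dimensional sweeps of the first input
over a grid of the second parameter (for rate constants such as `p9`, the
network is re-rated without re-expansion). Feedback-model maps classify
cells from an up-sweep's oscillation window; no-feedback maps from an
up/down pair's hysteresis.

Known artefacts of the drift method, shared by any quasi-static protocol:
attractors are found but unstable objects are invisible; passage through a
subcritical Hopf point shows bifurcation delay (the trajectory clings to
the weakly unstable focus), so envelope boundaries on the sweep can
overshoot the true bifurcation point by several percent of the range; and
bifurcation point locations are only resolved to the local inter-peak
spacing, so they are reported as bracketing intervals, not points.

## Response-pattern classification and robustness

The canonical stress response is translation at low input, an oscillatory
window at intermediate input, autophagy at high input. `classify_response`
runs an up drift sweep over the full scan range (AMPK\* 0–1e6 copies/cell
at zero rapamycin\*, or rapamycin\* 0–1e5 at AMPK\* = 3e4) and requires a
non-degenerate oscillation window with the AMBRA1-P fraction below 0.5
everywhere more than 2% of the range below the window and above 0.5
everywhere above it. Because a drift sweep cannot resolve a window
narrower than a few drifted cycle periods, a sweep with no window is
re-examined by fixed-input limit-cycle probes at five inputs bracketing
the translation-to-autophagy transition, each started from the swept state
(the state of the slowly stressed system at that input). Without this
hybrid step, narrow windows containing slow (period ~1e4–3e4 s) cycles are
misclassified as abrupt switches.

`robustness_range` walks the 17-multiplier grid `10^(n/4)`, n = −8..8,
outward from the nominal value, stopping at the first non-canonical
multiplier in each direction (points beyond a failure are not evaluated;
the bar is contiguous and contains the nominal by construction), and
requires canonicity on both scans. Classifications are memoised by
(parameter, multiplier), making the full 22-parameter protocol
restartable; the quick mode uses the subset n ∈ {−8, −3, 0, 3, 8}.

One boundary deserves note. On the AMPK\* scan, the canonical pattern
survives the feedback-strength constant `p6` up to 10 times its nominal
value and fails at 10^(5/4): at `p6 = 1e-5` the model has a genuine stable
relaxation cycle (amplitude ≈ 0.8 in the AMBRA1-P fraction, stationary
over 400 h of simulation). Published accounts of this boundary disagree
with each other at exactly the 10^(3/4)–10^(4/4) step; we report the bound
our classifier computes. On the rapamycin\* scan the same variant responds
gradedly, with no cycle found by fixed-input probes, so the two scans
bound the p6 bar differently.

## Fixture models and what the tests show

The engine is validated on five toy rule systems with closed-form expected
networks (a reversible dimer; a 2 × 3 phosphoform lattice; an A–B–C
scaffold; two ligands competing for one site; and a required-unbound
exclusivity motif mirroring the rapamycin\*/RPTOR competition for MTOR),
against brute-force oracles for embedding counts and label invariance, and
against the published census of the full model. These fixtures exercise
every rule construct the model uses — nothing more. Passing them shows
the symbolic machinery is correct for this model family; it says nothing
about biological realism, which rests entirely on the rules and the
nominal parameters, and those are order-of-magnitude estimates by
construction (all rate constants carry a single significant digit).

Problem sizes used in the shipped tests were chosen to probe each
qualitative claim at the smallest scale that exhibits it: stress
time-courses of 10–20 h, sweeps of 2,000 output points over 5e5 s of model
time, 40-cell regime maps over five `p9` values, and the quick robustness
subset (p4, p6, u0, u2); the full 22 × 17 × 2 protocol runs offline via
`full_sensitivity()`.

## Known limitations

* Deterministic mass action only; stochastic (SSA) simulation is out of
  scope, although copy numbers (1e4–1e6) are large enough that intrinsic
  noise mainly matters for oscillation synchrony, not for the bifurcation
  structure.
* No continuation: unstable steady states and unstable limit cycles are
  not computed, and bifurcation points carry grid-interval uncertainty.
* The BNGL dialect covers exactly the constructs this model family needs
  (binding with required-free context, state change, mass action); it is
  not a general-purpose compiler.
* Input down-drift is exponential, so sweeps cannot terminate exactly at
  zero input; they stop at 0.1% of the upper range end.
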