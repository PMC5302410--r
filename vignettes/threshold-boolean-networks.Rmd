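---
title: "Signed-threshold Boolean networks and ensemble activity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed-threshold Boolean networks and ensemble activity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carenet)
```

## The model

`carenet` simulates deterministic Boolean networks of the Kauffman type in
which every node carries a binary state (0 = low activity, 1 = high
activity) and every directed edge carries a sign: `+1` for activation, `-1`
for inhibition. Nodes are partitioned into *control* nodes — external inputs
such as hormone supplies, never targeted by an edge and frozen for the
duration of a run — and *internal* nodes, which evolve.

All internal nodes update synchronously. For a node with `n` regulators of
which `m` are inhibitory, the signed input sum `r = sum_j s_j w_j` ranges
over `[-m, n - m]`, and the node switches on exactly when `r` strictly
exceeds the midpoint of that range, `n/2 - m`. The strict inequality is a
modelling commitment, not an accident: for a node with two activators and
exactly one of them active, `r` sits precisely on the midpoint, and the
convention is that such a node stays off — both activators are required.
Two consequences deserve emphasis:

* a node with a single inhibitory regulator is *on* whenever its inhibitor
  is off (`r = 0 > -1/2`), giving inhibitors a default-on target;
* an internal node with no regulators falls to 0 after one step and stays
  there, because `r = 0` never strictly exceeds its threshold of 0.

Why synchronous? The update rule is defined from the *current* values of all
regulators, and the worked truth tables for single nodes are stated the same
way; we read "updated sequentially" as "iterated over time steps". An
asynchronous scheme would change only `synchronous_step()` and the compiled
transition map, so the choice is localised if it ever needs revisiting.

### Numerical choices

The threshold comparison is performed as `2*r > n - 2*m` in integer
arithmetic — exactly equivalent to the rational comparison and immune to
floating-point ties. Basin weights are dyadic rationals `I(F)/2^k` and are
exact in double precision, so the suite asserts `sum(weights) == 1` with
`identical()`, not with a tolerance. Attractors are identified by the
lexicographically minimal rotation of their full-state integer encodings
(all nodes, declaration order), which makes attractor identity independent
of the entry point into the cycle and makes cross-control-state
deduplication well defined. Ties cannot occur in the rotation order because
distinct rotations of a minimal cycle are distinct sequences.

## Attractors, basins and ensemble averaging

Because assays of cambium gene expression cannot supply initial conditions,
behaviour is summarised over *all* `2^N_int` initial conditions for each
control state. Every trajectory ends in a steady state or a limit cycle;
each final state `F` receives the weight `p(F) = I(F)/2^N_int`, the fraction
of initial conditions that reach it, under the hard-wired assumption that
all initial conditions are equiprobable.

Node importance in a final state is its *activity*: the fraction of cycle
steps with the node on (0 or 1 for steady states). The basin-weighted mean
of activities over the final states of a control state equals the arithmetic
mean over all initial conditions — an identity the test suite checks against
brute-force per-initial-condition simulation.

The two proliferation reporters WOX4 and HB8 are combined by the quadratic
mean `sqrt((a^2 + b^2)/2)`. The alternative non-root reading `(a^2 + b^2)/2`
is selectable via `combine = "meansq"`; the root form is the default because
it preserves scale (`a = b = x` yields `x`), which keeps the combined score
comparable with the individual reporter activities and with the activity
bins below.

Combined activities are classified into four equal-width bins — none
`[0, 0.25)`, low `[0.25, 0.5)`, medium `[0.5, 0.75)`, high `[0.75, 1]`. As
written in prose the bins would exclude the endpoints 0 and 1; since every
control state must land in some bin, we close the bins below and close the
top bin at 1.

### The enumeration engine

For each control state the full synchronous transition map over the free
internal bits is materialised once in compiled code, and attractors with
their basins are resolved by functional-graph traversal: each state is
visited a bounded number of times, so one control state of the bundled
30-node network (2^24 states) enumerates in about a second, and the full
64-control-state scan in about a minute on one CPU. A pure-R
per-initial-condition path (`method = "simulate"`) is retained as an
independent oracle and is compared state-for-state against the compiled
engine on randomly generated networks in the test suite. Enumeration
refuses state spaces above `2^cap_bits` (default 28) to keep memory bounded.

Permanently clamped internal nodes are removed from the enumerated bits:
their initial value is their clamp value, so the reduced space contains
exactly one representative per equivalence class of trajectories, and basin
weights are normalised over the reduced denominator. For permanent clamps
this leaves every ensemble average unchanged while halving the state space
per clamp; time-windowed overrides are therefore allowed only in
single-trajectory simulation, where "final state" remains well defined
after the last window expires.

## Perturbation protocols

Knockout and constitutive alleles are permanent clamps to 0 and 1. The
hormone-response protocol fixes one control node at 1 or 0 while all other
free controls range over every assignment; the reporter's basin-weighted
average activity is averaged *unweighted* over those assignments (the model
offers no justification for weighting control states unequally). The
two-hormone interaction table evaluates the four on/off combinations under a
fully fixed background. A structural consequence used as a test invariant:
if a knocked-out node is a cut vertex separating hormone from reporter, the
on and off arms coincide exactly.

## Association analysis

Relationships between inputs, node activities and the combined proliferation
score are tested with Pearson's chi-squared test of independence on binned
data: activities are cut into four equal-width bins (same endpoint
convention as above), binary controls pass through as two categories.
Expected counts use the standard row-by-column marginal products; a
uniform-expectation goodness-of-fit mode exists behind
`expected = "uniform"` for comparison, but the marginal form is the default
because it is what the test of independence prescribes. Degenerate tables
(fewer than two non-empty rows or columns after dropping empty categories)
are reported as inconclusive rather than erroring, and no multiple-testing
correction is applied — decisions are per test at the 0.05 level.

When independence is rejected, a direction is attached by a deliberately
conservative heuristic: the mean bin index of the first variable,
conditional on each level of the second, must be *strictly* monotone across
levels; anything else — including a single tie — is reported as
`indeterminate`. The unit of observation defaults to one final state
(unweighted) when either variable is a node activity and one control state
otherwise; basin-weighted counts (`weight = "basin"`) are exposed because
the choice is not dictated by the model.

## The bundled cambium network

`load_carenet()` returns the 30-node cambium-regulation model: six hormonal
inputs (CK0, IAA0, BR, GA, TDIF, ETHL) and 24 internal nodes spanning the
cytokinin, auxin, ethylene, brassinosteroid and TDIF/PXY signalling blocks,
with WOX4 and HB8 as proliferation reporters. The wiring shipped in
`inst/extdata/carenet.net` is a *provisional* transcription from the prose
description of the signalling blocks; the authoritative per-node rule
tables were not available for transcription. The file is pure data, so
refining the wiring is a one-line-per-edge edit with no code changes. Two
placements are flagged in the file as least constrained by prose (the HB8
regulator set and the endocytosis wiring), and one candidate edge noted in
prose but absent from the transcribed list (WRKY inhibiting CKX) is left as
a comment.

This provenance matters when interpreting emergent quantities: attractor
counts, bin occupancies and association directions computed on the bundled
wiring are properties of this transcription, and the strict-monotonicity
direction heuristic in particular returns `indeterminate` for pairs where
the published analysis reported a sign. The wiring-independent machinery —
update rule, enumeration, weighting, perturbation and test calibration — is
validated separately on random and hand-built fixtures.

## What the synthetic generator does and does not emulate

`random_threshold_network()` draws networks with a chosen control/internal
split, Poisson in-degrees and a fixed inhibition probability, sampling
regulators without replacement so validity is guaranteed by construction.
It emulates the *structural envelope* the engine must handle (sparse signed
digraphs with inputs), not biological topology: no degree heterogeneity
beyond Poisson, no motif enrichment, no autoregulation bias. Passing the
oracle-equivalence and conservation properties on these fixtures
establishes correctness of the computation, not realism of any particular
biological wiring.

## Problem sizes used by the test suite

Truth-table equivalence runs 200 random regulator sets with up to 8
regulators against a literal re-implementation of the rule;
engine-vs-simulation equivalence runs 50 random networks with 2–8 internal
nodes; the weighted-mean identity uses 4-internal-node fixtures where all
16 initial conditions can be simulated directly; chi-squared calibration
uses 400 independence-sampled tables of 240 observations. The
cambium-specific checks run the full 64-control-state scan (2^30 state
evaluations in total) and two knockout response profiles; together the
suite completes in a few minutes on one CPU.

## Known limitations

* The bundled wiring is provisional (see above); quantitative results on it
  should be treated as conditional.
* Only synchronous deterministic dynamics are implemented; asynchronous or
  stochastic schemes are out of scope.
* Initial conditions are equiprobable by construction; non-uniform priors
  over initial states are not supported.
* The direction heuristic is ordinal and conservative; it is not a
  substitute for a trend test.
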