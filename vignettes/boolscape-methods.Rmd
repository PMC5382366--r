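---
title: "Methods: weighted-sum Boolean landscapes and reversion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted-sum Boolean landscapes and reversion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolscape)
```

## The model

`boolscape` models a regulatory network as N binary nodes coupled through a
signed weighted connectivity matrix $M$ and a per-context basal vector $b$.
Entry $M_{ij}$ is the influence of node $j$ on node $i$; $b_i$ is the drift
node $i$ feels with no incoming signal, and it is the lever through which
biological contexts differ: a "disease" context raises or lowers basal
entries relative to "normal" to encode mutations, copy-number changes or
constitutive pathway activity. One synchronous step computes the weighted
sum $w = M v^t + b$ and sets

$$
v_i^{t+1} =
\begin{cases}
1 & w_i > 0\\
v_i^t & w_i = 0\\
0 & w_i < 0.
\end{cases}
$$

The zero-holds branch matters: it makes unregulated nodes with zero basal
level genuine switches whose value is set by the initial state, which is
how the model represents epigenetically bistable components.

Because the dynamics are deterministic on a finite state space, every
trajectory ends in an attractor — a fixed point or a cycle — and the
fraction of initial states reaching each attractor (its basin) is the
model's notion of how much of phenotype space a cell state commands.

## Landscape estimation

`build_landscape()` supports two modes. *Exhaustive* mode enumerates all
$2^f$ states over the $f$ free (unpinned) nodes, capped at $2^{20}$ by
default; it is the ground truth used throughout the tests. *Sampled* mode
draws initial states uniformly and independently over the free nodes — a
plain Monte-Carlo estimate of basin measure, so duplicate draws are
deliberately not deduplicated and a seed is mandatory.

Internally both modes advance all trajectories as one state matrix.
Deterministic dynamics let identical states merge (their counts are
summed), and any state already known to lie on an attractor absorbs its
trajectory's count immediately, so the active set usually collapses within
a few times the typical transient length. When the active set stops
shrinking, the survivors are (or feed) unregistered cycles and are resolved
by exact single-trajectory cycle detection with a visited-state hash.
Attractor cycles are canonicalized by rotating to the lexicographically
smallest state, so the same attractor always hashes to the same id
regardless of entry phase.

Numerical choices:

* Weighted sums are rounded to 12 decimals before the sign test, so
  integer-weight networks behave exactly like integer arithmetic while
  real-valued weights remain admissible.
* The transient cap is 10,000 steps and configurable; exceeding it raises
  a loud error rather than silently truncating. Observed transients on
  networks of a few dozen nodes are orders of magnitude shorter.
* States are encoded as exact doubles (valid to N = 53); networks larger
  than the exhaustive cap must use sampled mode.

### Asynchronous check

Synchronous point attractors are fixed points of the node-wise update map
and are therefore invariant under any update order; `check_async()`
verifies this identity directly (a flag would mean an internal bug) and
additionally runs random-order asynchronous trajectories — one uniformly
chosen node updated per micro-step — and reports the fraction absorbed by
the synchronous point-attractor set. Random-order single-node updating is
one of several possible asynchronous schemes; fully general schedules are
out of scope, and cyclic synchronous attractors are not expected to be
conserved.

## The scoring system

Each attractor is scored against a configurable rubric of phenotype
aspects (by convention proliferation, EMT, stemness). An aspect is a set
of weighted rules *(marker node, desired activity, weight)*; the aspect's
cancer-proximity score (CPS) is the weighted satisfaction fraction

$$\mathrm{CPS}_a = \frac{\sum_r w_r\,(1 - |{\rm act}(m_r) - d_r|)}{\sum_r w_r} \in [0, 1],$$

where a cyclic attractor's marker activity is its mean over the cycle
states (the natural time-average; point attractors reduce to exact
satisfaction). The landscape CPS vector is the basin-weighted mean of the
attractor rows, $S = s^\top b / b_{\rm total}$, and the scalar
**normal-like score** is its dot product with the aspect weights. High
scores are normal-like, low scores cancer-proximate; the maximum is the
sum of the aspect weights.

The shipped default rubric (`default_scoring_config()`) encodes the
conventional eight colorectal markers: proliferation favours CyclinE and
CyclinD off with p21 on, EMT favours Snail/SLUG/MMP off with E-cadherin
on, and stemness penalizes Snail. Caspase-3 carries no rule, so the
normal-like optimum never requires switching apoptosis on — cell-cycle
arrest is deliberately weighted above apoptosis induction. This rubric is
a documented reconstruction, not ground truth: the exact marker-to-score
table is a modelling decision the user can and should revisit per network,
which is why scoring is entirely config-driven.

Aspect weights default to the integer triple (6, 4, 1). `fit_weights()`
re-derives such weights from data: it scores every candidate integer
weight vector on a grid (default $\{0..10\}^3$) against an externally
supplied malignancy ranking of mutation profiles and returns the vector
maximizing Kendall's tau, breaking ties by smaller weight sum and then
lexicographically. An exhaustive integer grid was chosen over continuous
optimization because the weights are meant to be small integers and the
search doubles as its own audit trail. Candidate scores are rounded to 12
decimals first so CPS rows that tie exactly are seen as tied rather than
ordered by floating-point noise.

## Perturbation scans and synergy

`single_scan()` rebuilds and rescores the landscape for every (node,
mode) combination against one shared baseline (same mode, sample count and
seed, so sampled-mode deltas are differences of estimates on a common
footing). Reversion targets are the perturbations with positive score
change. Restore rows are only generated where the context basal actually
differs from normal, since restoring an unchanged entry is the identity.

`double_scan()` compares the joint score increase $\Delta_{AB}$ of an
unordered pair against the sum of the single increases. With the relative
band (default), a pair is synergistic when
$\Delta_{AB} > (\Delta_A + \Delta_B)(1 + \tau)$, antagonistic below
$(\Delta_A+\Delta_B)(1-\tau)$, and additive inside the band. The default
tolerance $\tau = 0.2$ reflects the typical ~20% spread of increased
scores observed across pair perturbations in this class of model; an
absolute band is available because "similar within 20%" is ambiguous
between the two readings, and exhaustive-mode tests use $\tau = 0$ where
the definitions hold exactly. When candidates are given as bare node
names, each node's pair mode defaults to its better-performing single
mode; candidates whose single delta is negative are kept but reported.

## Functional motif extraction

A functional motif is defined behaviourally, not topologically: the
minimal node set whose state fixation suppresses a reversion target's
improvement. `extract_motif()` implements the greedy procedure: with
fixed set $F$, every candidate node and both fixed values 0 and 1 are
tried (the choice of value is part of the search because the direction of
suppression is not known a priori), the target's delta is recomputed with
$F$ in both the baseline and the perturbed landscape, and the
(node, value) minimizing the residual delta is appended. Termination is
at $\varepsilon = 0.1$ of the original delta by default — "small enough to
neglect" made concrete — or when no candidate reduces the residual.
Tie-breaks are deterministic: smaller residual, then node name, then
value 0 before 1, so identical inputs always give identical member order.

`activity_profile()` summarizes a landscape as basin-weighted mean node
activities; `motif_stability()` compares the profile before and after a
reversion perturbation and classifies each motif node as *stable*
(activity within 0.1 of 0 or 1), *responsive* (within [0.4, 0.6]) or
*intermediate*. The bands operationalize "robustly frozen" versus
"fluctuating around one half" and are configurable.

## Robustness along mutation sequences

`robustness_trajectory()` rebuilds the landscape at every prefix of an
ordered mutation sequence and records three metrics: attractor count, the
mean basin fraction of the five largest attractors (ties broken by
canonical id; fewer than five are averaged and flagged), and the
normal-like score. Fewer attractors with larger major basins mark a
landscape that external signals can barely move — the operational meaning
of robustness here. The canonical colorectal mutation order is input
data, not a constant baked into the package: sequences are ordinary
profile files. `sequence_ensemble()` draws random node orders without
replacement; under the score-decreasing rule each node's pin value is
chosen greedily as the one lowering the current cumulative score more
(ties pin to 0). Greedy per-step choice does not guarantee a globally
non-increasing score on arbitrary networks, so the ensemble reports
trajectories rather than asserting monotonicity.

## Synthetic fixtures and what passing tests show

`generate_network()` draws random signed digraphs with integer weights in
[-2, 2], role annotations, and normal/disease contexts differing in a
random basal subset. Input nodes receive no incoming edges — their state
belongs to the environment, which is what makes response sweeps
meaningful. Random fixtures emulate the *mechanics* of real regulatory
networks (signed weighted influence, basal drift, context contrast); they
do not emulate degree distributions, pathway modularity or literature-
derived logic, so passing the oracle tests demonstrates correctness of
the algorithms, not biological validity of any particular network.

The curated fixtures each isolate one mechanism with a hand-enumerable
state space: a mutual-inhibition toggle (two point attractors plus one
cycle), a redundant-branch pair (synergy exactly at $\tau = 0$), disjoint
pathways (exact additivity), a linear chain (the greedy motif must return
exactly the relay), a saturated feedback loop whose restoration moves
activities from 1 to 0.5, a 12-node scoring network whose two equal basin
halves carry CPS rows (1,1,1) and (0,0,0) — scalar score exactly 5.5
under weights (6,4,1) — and a switch-bank whose pinning sequence halves
the attractor count at each step. The weight-recovery profile set was
constructed geometrically: the three CPS-row difference vectors define a
cone of weight vectors that order the profiles correctly, and the cone
was chosen so its minimal integer point on the grid is exactly (6,4,1).
Expected outputs for the curated fixtures live in
`inst/extdata/oracles/` and are regenerated by
`scripts/regenerate_oracles.R`, never edited by hand.

Test problem sizes are 4-14 nodes with exhaustive enumeration as oracle
and 20,000-sample Monte-Carlo landscapes; at these sizes the whole suite
runs in about a minute. Per-attractor agreement is asserted at three
binomial standard errors; across the ~150 basin comparisons of the random
cohort an individual excursion slightly beyond 3 sigma is expected
statistics rather than a defect, which is why the comparison seeds are
fixed in the tests.

## Known limitations

* The full state-transition graph is never materialized; transient
  structure (Garden-of-Eden states, transient lengths per basin) is not
  reported.
* Asynchronous support is limited to the fixed-point identity check and
  random-order trajectories; general update schedules and probabilistic
  Boolean extensions are out of scope.
* CPS for cyclic attractors uses time-averaged marker activity; other
  summaries (e.g. worst-case over the cycle) are defensible and would
  change scores on oscillatory landscapes.
* The default scoring rubric is a reconstruction; conclusions about any
  real network should be checked against a rubric curated for it.
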