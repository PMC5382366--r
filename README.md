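# boolscape

Quantitative attractor-landscape analysis and reversion-target discovery
for weighted-sum Boolean models of regulatory networks.

## The problem

Logical (Boolean) models are a workhorse for reasoning about cell-fate
decisions in signalling and gene-regulatory networks: each molecule is on
or off, and the long-run behaviour of the network is captured by its
*attractors* — fixed points or cycles — and their *basins of attraction*.
In cancer systems biology a central question is whether a malignant
attractor landscape can be steered back toward a normal one by
intervening on a small number of nodes ("cancer reversion"), and which
node sets lock the malignant landscape in place. Answering it needs a
*quantitative* readout of how normal a landscape is, not just a catalogue
of attractors.

`boolscape` is for modellers who have (or generate) such a network and
want that quantitative pipeline end to end: landscape construction,
phenotype scoring, systematic perturbation scans, synergy classification,
functional-motif extraction, and robustness tracking along mutation
sequences.

## The model in brief

A network is $N$ binary nodes with a signed weighted connectivity matrix
$M$ ($M_{ij}$: influence of node $j$ on node $i$) and one basal vector
$b$ per biological context. States update synchronously through the
weighted sum $w = M v^t + b$:

$$v_i^{t+1} = 1 \text{ if } w_i > 0,\quad v_i^t \text{ if } w_i = 0,\quad 0 \text{ if } w_i < 0.$$

Mutations and interventions are pins (clamp a node to 0/1), basal shifts,
or restoration of a node's basal level to its normal-context value.

Each attractor is scored against a configurable rubric of phenotype
aspects (proliferation, EMT, stemness by default): an aspect's
cancer-proximity score (CPS) is the weighted fraction of its marker rules
the attractor satisfies, cyclic attractors using time-averaged marker
activity. Basin-weighting the attractor CPS rows gives the landscape CPS
vector $S = s^\top b/b_{\rm total}$, and the scalar **normal-like score**
is $\sum_a w_a S_a$ with integer aspect weights (default 6, 4, 1). High
is normal-like. Reversion targets are perturbations that raise it; a
functional motif is the minimal node set whose fixation suppresses a
target's improvement; robustness along a mutation sequence is tracked as
attractor count and mean basin of the five major attractors.

## Worked example

The package ships a small synthetic colon-pathway-flavoured toy network
(14 nodes; inputs EGF/Wnt/DNA damage, the eight conventional phenotype
markers) and a default scoring rubric:

```r
library(boolscape)

net <- read_network(system.file("extdata", "networks",
                                "toy_colon_synthetic.json",
                                package = "boolscape"))
cfg <- default_scoring_config()

ls <- build_landscape(net, "disease", mode = "exhaustive")
glance(ls)
#>   n_attractors n_point point_basin_coverage top5_mean_basin total_samples
#> 1           42      42                    1           0.106         16384

score_landscape(ls, cfg, net)
#> <bn_score> normal-like score: 3.40625
#>   aspect CPS: proliferation=0.2031, EMT=0.4375, stemness=0.4375
```

The disease context lands at 3.41 of a maximum 11: proliferation rules
are mostly violated (CPS 0.20), EMT and stemness partially (0.44). A
systematic scan then asks which single interventions push the landscape
back up:

```r
scan <- single_scan(net, "disease", cfg, mode = "exhaustive")
reversion_targets(scan)
#>    node      mode    baseline score delta n_attractors
#>  1 p21       pin1        3.41  7.44 4.03            66
#>  2 p53       pin1        3.41  7.06 3.66            60
#>  3 KRAS      pin0        3.41  7    3.59            14
#>  4 CyclinD   pin0        3.41  6.69 3.28            22
#>  5 Snail     pin0        3.41  6.22 2.81            20
#>  ...
#> 10 p53       restore     3.41  4.22 0.812           36
#> 15 APC       restore     3.41  3.72 0.312           26
```

Activating p21, activating p53 or silencing hyperactive KRAS roughly
doubles the normal-like score — the model's candidate reversion targets.
From here, `double_scan()` classifies target pairs as
synergistic/additive/antagonistic, `extract_motif()` finds the node sets
whose fixation blocks a target, and `robustness_trajectory()` tracks
landscape robustness while mutations accumulate. Every result is a tibble
(or has `tidy()`/`glance()` methods) and plots via `autoplot()`.

A command-line interface wraps the same functions
(`exec/boolscape attractors|score|perturb-scan|perturb-pairs|motifs|robustness|response|generate-network|check-async`),
writing TSV/JSON outputs plus a provenance record per run.

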