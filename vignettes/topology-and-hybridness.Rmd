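---
title: "Network topology and the abundance of hybrid E/M phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network topology and the abundance of hybrid E/M phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnhybrid)
```

## The question

Cells navigating the epithelial–mesenchymal spectrum can occupy hybrid
states that co-express epithelial and mesenchymal markers; these states
are disproportionately associated with metastatic competence. The
regulatory networks behind the transition are signed directed graphs —
transcription factors and microRNAs activating and inhibiting one
another — and a recurring empirical observation is that a network's
*wiring alone*, before any kinetic detail, biases how much probability
mass its dynamics place on hybrid states. `grnhybrid` packages the full
chain of that analysis: simulate a topology under two complementary
formalisms, score the emitted steady states on an E/M axis, summarize
the hybrid mass ("hybridness"), and correlate it with purely
topological metrics across perturbation and randomization ensembles.

## State ensembles from a topology

### Random-parameter ODE ensemble

Each node level $X_i$ obeys

$$\frac{dX_i}{dt} \;=\; P_i \prod_{j \to i} H^S\!\big(X_j;\,
Y^0_{ji}, n_{ji}, \lambda_{ji}\big) \;-\; D_i X_i,$$

where the shifted Hill factor
$H^S(x) = \lambda + (1-\lambda)\,/\,\big(1 + (x/x^0)^n\big)$
equals 1 in the regulator's absence and saturates at the fold change
$\lambda$ ($\lambda < 1$ inhibition, $\lambda > 1$ activation). Multiple
regulators act multiplicatively on the production rate — the standard
assumption of random-circuit-perturbation modeling, and the only
composition rule implemented.

Since kinetic parameters for these circuits are largely unmeasured, the
engine characterizes the *topology* by sampling thousands of parameter
sets from broad ranges (per node: production $P \in [1, 100]$
conc/time, degradation $D \in [0.1, 1]$ /time; per edge: integer Hill
coefficient $n \in \{1..6\}$, threshold $Y^0$ spanning $[0.02, 1.98]$
times the median unregulated level $\tilde P / \tilde D \approx 91.8$,
activating fold change uniform on $[1, 100]$, inhibitory fold change
the *reciprocal* of a uniform draw on $[1, 100]$). The reciprocal
sampling mirrors how fold changes are specified on the fold scale in
the RACIPE tradition; sampling the inhibitory $\lambda$ uniformly on
$[0.01, 1]$ instead concentrates mass on weak repression and all but
eliminates bistability of a mutual-inhibition toggle, which is
inconsistent with the well-established behaviour of that motif. A
truncated-Gaussian option (mid-range mean, range/4 SD) exists because
ensemble modeling is sometimes specified that way; uniform is the
default.

Integration is forward Euler with step `dt = 0.1` time units, organized
as up to 20 windows of 50 time units; a trajectory converges when no
node moves by more than `cutoff = 1.0` concentration units across a
window. The same 1.0 is the tolerance for merging near-identical stable
states within a parameter set — multistability is then the fraction of
parameter sets retaining more than one distinct state. Initial
conditions are uniform on $[0,\ 1.5\,P_i/D_i]$, the attainable span of
unregulated expression. Non-finite trajectories are recorded as
non-converged, never fatal.

Converged levels are z-scored per node across the whole ensemble and
binarized at $Z > 0$; no log-transform is applied by default (a `log2`
option exists for parity studies with pipelines that do transform).
Because the ensemble pools very different parameter sets, the raw-level
z-score splits at the arithmetic mean of a right-skewed distribution;
absolute hybridness values are therefore not comparable across
binarization conventions, but all the correlational analyses in this
package compare variants under one fixed convention.

### Asynchronous threshold Boolean engine

The parameter-free counterpart updates one uniformly chosen node per
step:

$$S_i(t+1) = \begin{cases} 1 & \sum_j J_{ij}\,\sigma_j(t) > 0 \\
0 & \sum_j J_{ij}\,\sigma_j(t) < 0 \\ S_i(t) & \text{otherwise,}
\end{cases}$$

with $J_{ij}$ the signed (optionally weighted) edge $j \to i$. Under
the default `ising` convention $\sigma_j = 2S_j - 1 \in \{-1, +1\}$,
matching the spin formalism this update rule descends from; the
`literal01` flag uses $\sigma_j = S_j$ instead. The two genuinely
disagree — e.g. `literal01` makes the all-zero state a fixed point of
any mutual-inhibition pair — so both are exposed and neither silently
substitutes for the other. Runs stop at a fixed point (state invariant
under every single-node update) or after `max_steps = 1000` updates;
only fixed points enter phenotype distributions, cyclic attractors are
deliberately not catalogued. Frequencies are fractions of converged
runs, and the weighted-edge variant (weights uniform on (0,1), signs
kept) flows through the identical code path.

Both engines repeat the whole simulation (default three times with
consecutive derived seeds) and average the resulting distributions
pointwise before renormalizing — averaging at the distribution level,
with metric-level averaging left to the caller.

### Signal nodes

Nodes with no incoming edge from another node (a pure self-loop does
not count as an input) are treated as upstream signals: they carry no
phenotype information and are trimmed from reported state strings. A
perturbation sweep trims by the *wild-type* signal set for every
variant, so that deleting a node's only input does not change the state
space being compared. Frustration, by contrast, is always evaluated on
the full state including signal nodes, because their outgoing edges
count in the edge total.

## Scoring states

Nodes are split into epithelial and mesenchymal groups by hierarchical
clustering (Euclidean distance between correlation-matrix rows,
complete linkage, cut at two). Cluster *identity* is not decidable from
dynamics alone; `anchors` lets any node of known biochemical class name
the clusters, and without anchors the package labels the cluster of the
lexicographically first node E with an explicit warning. The EMT score
of a binary state is the mean E-bit minus the mean M-bit; a state is
hybrid when $|\text{score}| \le 0.5$ (boundary inclusive), and
hybridness is the summed frequency of hybrid states. Hybridness is
invariant under swapping the two cluster labels, so unanchored
partitions are safe for it.

Distribution changes are measured by the Jensen–Shannon divergence in
bits (union support, absent states at zero, $0 \log 0 := 0$); cohesion
by the J metric, the strict upper-triangle sum of the node–node Pearson
correlation matrix. Frustration of a state counts edges whose sign
conflicts with the spin product of their endpoints
($\text{sign}(J)\,\sigma_u \sigma_v = -1$, bits mapped $0 \mapsto -1$);
network frustration reports min/mean/max over distinct steady states,
the mean unweighted by default ("states" weighted equally) with a
frequency-weighted option.

## Topology-only metrics

Feedback loops are simple directed cycles, enumerated exhaustively by
DFS in canonical rotation; self-loops are length-1 cycles. Enumeration
is exponential in the worst case, so networks above 30 nodes default to
a length cap of 10 edges (always overridable). A loop is positive with
an even number of inhibitions. Weighted censuses weight each loop by
its edge count (length), the reading adopted for "weighting a loop by
its participating edges"; the reciprocal reading (1/length) sits behind
`weight_mode = "inv_length"` since the two cannot be distinguished from
correlation directions alone. Predicted frustration is the count of
negative loops of length at most six — short loops dominate dynamical
conflict, and the cutoff keeps the metric computable on large networks.

The influence matrix averages signed adjacency powers, each normalized
elementwise by the corresponding power of the unsigned pattern matrix,
over path lengths $1..l_{max}$ (default 10 — long enough for paths to
traverse the networks analyzed here, and config-exposed because no
canonical value exists). Mutual influence products $I_{ij} I_{ji}$
over unordered pairs, summed by sign, give the effective
positive/negative loop strengths. HiLoop censuses count interconnected
positive-loop motifs as *instances* (not binary presence) so the metric
grades with network size: triples of PFLs through a common node
(Type-I), a central PFL with two edge-disjoint satellite PFLs through
distinct nodes (Type-II), and mutual inhibition with a self-activation
(MISSA; a relaxed mode accepts any other PFL through either node in
place of the self-activation, the looser phrasing sometimes used for
this motif).

Inconsistency — the minimum sign flips to make every undirected cycle
positive — is estimated greedily: among edges on currently negative
cycles, flip the one covering the most of them, preferring flips that
strictly shrink the negative-cycle count (ties: fewest positive cycles
disturbed, then edge order), recomputing after each flip. The default
cycle space is the fundamental-cycle basis of a spanning forest: a
signed graph is balanced exactly when every basis cycle is positive, so
the zero/nonzero decision is exact and the chord of any negative
fundamental cycle always offers a strictly improving flip, guaranteeing
termination. The all-simple-cycles space (capped at length 10)
reproduces the enumerative procedure more literally; a
revisited-configuration guard converts pathological oscillation into an
error rather than a silent loop. The greedy count is an upper bound on
the exact frustration index; the test-suite brute-forces tiny networks
to confirm the bound and the exactness of the balance decision.

## Synthetic networks

Real EMP topologies share a signature: two groups of nodes (epithelial
and mesenchymal programs) with mostly activating edges within a group
and inhibiting edges across — "two teams". `generate_team_grn` builds
exactly that (and is therefore balanced: PFL fraction 1);
`tune_loop_composition` then hill-climbs single-edge sign flips toward
any target PFL fraction, never worsening the objective. The fully
random generator (`generate_random_grn`) controls size, density, sign
mix and the number of input-only nodes but deliberately reproduces no
degree-distribution or modularity structure beyond that; conclusions
from it speak to density- and sign-matched graphs, not to curated
biology. Equally, passing the packaged checks on these ensembles shows
the *machinery and directionality* on controlled structure — it does
not certify effect sizes on real transcriptional networks.

The `emt_core` fixture is a synthetic reconstruction of the canonical
4-node miR200/ZEB/GRHL2/SNAIL core circuit (mutual inhibitions
miR200–ZEB and ZEB–GRHL2, SNAIL inhibiting miR200 and activating ZEB,
ZEB self-activation, SNAIL as upstream signal). It is documented as a
reconstruction, not a transcription of any published supplementary
figure.

## The experiments

`perturbation_sweep` simulates a wild type and its $2E$ single-edge
variants (each edge deleted, each edge sign-flipped), holding the
wild-type node partition and signal set fixed across variants so that
hybridness and JSD are comparable; `correlation_report` then computes
Spearman correlations of every metric against hybridness (average
ranks under ties, two-sided p, significance marked at $p < 0.05$ with
no multiple-testing correction, matching the conventions of the
analyses this package operationalizes; constant columns are reported
as missing, never as zero). `randomization_percentile` places the wild
type's topology metric within degree-preserving sign-conserving
double-edge-swap randomizations using the midpoint tie rule. Note that
very small dense circuits can admit *no* legal swap — the 4-node core
circuit is such a case — and then randomization raises an error rather
than fabricating a null.

`directionality_experiment` ties it together on synthetic ground
truth: two-team 8-node/16-edge networks tuned across the PFL-fraction
range, simulated with the Boolean engine, scored against their built-in
team partition. Networks tuned so deep into negative loops that no
Boolean fixed point survives are dropped — their phenotype distribution
is undefined, a real limitation of fixed-point-only analysis. On such
ensembles hybridness falls with PFL fraction and rises with mean
steady-state frustration; the frustration coupling is the strong one
(rank correlation around +0.7 at the sizes below), the loop-composition
coupling consistent but weak (around −0.2), echoing the observation
that loop counts are coarser predictors than frustration-based
metrics.

## Problem sizes and reproducibility

The packaged tests and the acceptance script favour many small,
seedable problems over few large ones: ODE sweeps of the 4-node core
circuit run 400–500 parameter sets × 20 initial conditions (single
repeat), the Boolean experiments 3,000–30,000 initial conditions per
network, the directionality ensemble 40 tuned 8-node networks, and all
brute-force oracles stay at or below 8 nodes where exhaustive
enumeration is exact. These sizes were chosen so the full chain stays
interactive on one CPU; the engine defaults (10,000 sets × 100 ICs ×
3 repeats; 100,000 Boolean ICs) remain the reference settings for
production runs. Every stochastic step takes an explicit seed, repeats
derive consecutive seeds from it, and identical invocations are
bit-identical end to end.

## Known limitations

* Greedy inconsistency is an upper bound; exact frustration-index
  solvers (ILP) are out of scope at these network sizes.
* Only fixed points enter Boolean phenotype distributions; oscillatory
  attractors are invisible to hybridness as defined here.
* The correlational design cannot separate cause from correlate, and
  absolute hybridness values depend on the binarization convention.
* Cluster-based E/M partitioning can produce biologically mixed
  clusters on large curated networks; anchoring on known markers is the
  sanctioned remedy.

```{r example, eval = FALSE}
# a compact end-to-end run
emt <- make_fixture("emt_core")
tab <- perturbation_sweep(emt, engine = "ode",
                          config = ode_config(n_sets = 500, n_ics = 20,
                                              repeats = 1),
                          seed = 1,
                          anchors = c(miR200 = "E", ZEB = "M"))
correlation_report(tab)
```
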