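---
title: "Functional cartography of dynamic network communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional cartography of dynamic network communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcarto)
```

# The problem

A brain (or any multivariate system) measured under many conditions
yields one functional connectivity matrix per condition: nodes are
regions, weights are Fisher-z-transformed Pearson correlations between
the regions' (residualized) time series. The scientific question is not
what the community structure of any single condition looks like, but how
the community structure *reconfigures* across the condition battery, and
what dynamic role each predefined node-set — a "cognitive system" such as
default-mode or fronto-parietal — plays in that reconfiguration: does it
stay together, does it dissolve, does it recruit outsiders?

`funcarto` implements this analysis end to end: multislice community
detection over the stack of condition networks, summarization of a
partition ensemble as a module allegiance matrix, recruitment and
integration coefficients at region and system level, a size-preserving
permutation null, and a nine-role classification. A planted-partition
generator makes every stage testable against ground truth.

# The model

## Multislice modularity

The condition networks are treated as slices of one multilayer network
with categorical interslice coupling: node $j$ in slice $s$ is connected
to node $j$ in *every* other slice $r \ne s$ with weight $\omega$ (no
temporal ordering — conditions are categories, not a time course). A
partition $g$ assigns a community label $g_{is}$ to each (node, slice)
pair, and its quality is

$$Q = \frac{1}{2\mu} \sum_{ijsr} \Big[ \big(A_{ijs} - \gamma_s
V_{ijs}\big)\,\delta_{sr} + \delta_{ij}\,\omega \Big]\,
\delta(g_{is}, g_{jr}),$$

with the Newman–Girvan null $V_{ijs} = k_{is} k_{js} / (2 m_s)$ inside
each slice, $k_{js}$ the intraslice strength, $m_s$ the slice total, and
$2\mu$ the total (intraslice plus coupling) edge weight. $\gamma_s$
controls community size within a slice; $\omega$ controls label
persistence across slices. `multislice_modularity()` is a pure
evaluation of this sum; `louvain_once()` maximizes it.

Because $Q$ is linear in the co-assignment indicators, the whole
multilayer problem is ordinary modularity maximization on the dense
supra-modularity matrix $B$ whose diagonal blocks are
$A_{\cdot\cdot s} - \gamma_s V_{\cdot\cdot s}$ and whose off-diagonal
blocks carry $\omega$ on the node diagonal. The generalized Louvain
heuristic operates directly on $B$: phase one moves (node, slice)
supra-nodes greedily in a seed-shuffled order (ties broken by lowest
community index, moves accepted above a $10^{-10}$ gain threshold);
phase two sums $B$ over community blocks — which automatically carries
every super-node's coupling contributions — and recurses. Each run is
deterministic given its seed; `run_ensemble()` derives per-run seeds
from a master seed and keeps *all* partitions, because the allegiance
matrix is defined over the full ensemble, not a consensus.

## Allegiance, flexibility, coefficients

With $O$ optimizations and $T$ slices, the module allegiance matrix is

$$P_{ij} = \frac{1}{OT} \sum_{o=1}^{O} \sum_{t=1}^{T}
\mathbb{1}\!\left[g^{(o)}_{it} = g^{(o)}_{jt}\right],$$

the probability that two nodes share a community across the battery.
Flexibility is the proportion of consecutive slice transitions in which
a node changes label, $f_i = \#\{t: g_{i,t} \ne g_{i,t+1}\}/(T-1)$,
averaged over runs for an ensemble. Consecutive-transition counting in
input slice order is the convention adopted here; under categorical
coupling the slice order is nominal, but the statistic is the
established one and is reported in input order for reproducibility.

Region coefficients with respect to the region's own system $S$
($n_S = |S|$, $N$ nodes total):

$$R_i^S = \frac{1}{n_S}\sum_{j \in S} P_{ij}, \qquad
I_i^S = \frac{1}{N-n_S}\sum_{j \notin S} P_{ij},$$

and system coefficients

$$R_S = \frac{1}{n_S^2}\sum_{i \in S}\sum_{j \in S} P_{ij}, \qquad
I_{S_k S_l} = \frac{1}{n_{S_k} n_{S_l}} \sum_{i \in S_k}\sum_{j \in S_l}
P_{ij}, \qquad
I_S = \frac{1}{n_S (N - n_S)}\sum_{i \in S}\sum_{j \notin S} P_{ij}.$$

The recruitment sums are written over the full ranges and therefore
include the diagonal $P_{ii} = 1$; that is how `funcarto` computes them
by default. Whether the diagonal belongs in the average is a genuine
convention choice — it puts a floor of $1/n_S$ under every system's
recruitment — so `include_self = FALSE` (CLI `--exclude-self`) provides
the diagonal-free variant. All results in this package's tests use the
literal (diagonal-included) form. Two exact identities follow from the
definitions and are asserted in the test suite: per node,
$n_S R_i^S + (N-n_S) I_i^S = \sum_j P_{ij}$, and $I_S$ is the
size-weighted average of the pairwise $I_{S_k S_l}$.

## Null model and roles

Observed coefficients are calibrated against a permutation null that
shuffles the node-to-system assignment uniformly at random, preserving
the number and sizes of systems, and recomputes $R_S$, $I_S$ and the
pairwise integrations on the same allegiance matrix (default 1000
replicates; percentile 2.5/97.5 bands, `stats::quantile` defaults). Each
axis is trichotomized against its band: recruitment below/inside/above
maps to *ephemeral* / *unstable* / *stable*, integration to *loner* /
*connector* / *integrator*; the role is the pair. Pairwise integration
edges are flagged `stronger` / `weaker` / `ns` by strict comparison
against the same percentile band of their null pairwise distribution,
whose location is the mean allegiance between size-matched random
node-sets. The replicate count, the percentile construction and the
strictness convention (a value exactly on the band edge is not
significant) are package choices; only the 95% level itself is fixed by
the method.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 1 | intraslice resolution; >1 favors smaller communities |
| `omega` | 0.45 (detection CLI) | categorical coupling; larger values suppress label changes across slices |
| `n_runs` | 100 | Louvain restarts per ensemble |
| `n_perm` | 1000 | permutation replicates for the null bands |
| `window_len` | 11 | rest windowing length in samples; 300 samples yield 27 full windows |
| `sign_policy` | `truncate_negative` | negative Fisher-z weights are set to 0 before detection |

$\gamma = 1$, $\omega = 0.45$ are the operating point shipped as CLI
defaults for `detect`. The Newman–Girvan null is undefined for signed
strengths, so negative weights are truncated by default; `keep` passes
them through for users who supply their own signed-safe resolution.
`grid_search()` scans $(\gamma, \omega)$ and records, per grid point,
the mean and standard deviation of flexibility across nodes, mean
pairwise z-Rand partition similarity across runs and across slices, mean
community count and mean quality; `select_parameters()` picks the point
that maximizes the flexibility standard deviation, breaking near-ties
(within 1% of the maximum) toward high similarity across runs and low
similarity across slices. The z-Rand statistic is the pair-counting Rand
coefficient standardized under the hypergeometric null that fixes both
partitions' group sizes; comparisons with zero null variance are
reported as 0 and flagged degenerate.

# The synthetic generator

`planted_scenario()` defines the study conditions under which the
pipeline is validated: a ground-truth system map (default four systems
of eight nodes), `n_slices = 8` condition slices, and per slice each
node keeps its system's community with probability `1 - flip_prob`
(default 0.1) or defects to another system. Edge weights are Gaussian:
mean `mu_in = 0.8` within slice-communities, `mu_out = 0.2` between,
noise `sigma = 0.1`. The weight scale mirrors strong versus weak
Fisher-z coupling; the contrast-to-noise ratio (0.6/0.1) makes planted
structure clearly but not trivially recoverable at desk scale, and the
slice count is large enough for flexibility to be a meaningful
proportion while keeping a full 100-run ensemble in seconds. Weights
are symmetrized by averaging and the diagonal forced to zero, mirroring
correlation-matrix structure; flips are i.i.d. across nodes and slices
(no temporal autocorrelation), the simplest model consistent with
categorical coupling; negative weight draws are passed through to the
network's sign policy, the single authority for sign handling.

`generate_timeseries()` emulates the upstream stage: per-condition
multivariate normal samples with correlation `rho_in` within systems and
`rho_out` between (identity diagonal), with automatic shrinkage of
`rho_in` if the block covariance is not positive semi-definite.

What the generator does *not* emulate: hemodynamics, scanner noise,
motion, spatial autocorrelation, heavy-tailed weight distributions, or
any temporal dependence between conditions. Passing tests therefore
demonstrate that the algorithms are correct and that the statistical
machinery (null bands, role grid) behaves as designed on data whose
generative structure is known — not that real neuroimaging data meet the
generator's assumptions.

## Planted roles and why their design is constrained

`generate_role_scenario()` plants a known role for one designated
system. Two structural facts, both consequences of the method itself,
dictated its design; they are worth recording because they apply to real
analyses as well.

**Coupling hides transient disengagement.** The coupling term
$\delta_{ij}\omega$ has no null-model penalty, so for *any*
$\omega > 0$ a node whose edges vanish in one slice is still pulled into
whichever community its other-slice replicas occupy — attaching a
zero-strength node costs nothing intraslice and earns $\omega$ per
replica. A system planted to scatter into singletons is therefore
detected as fully stable unless coupling is switched off. Allegiance,
recruitment and integration are defined on per-slice co-occurrence and
need no cross-slice label alignment, so the role pipeline detects with
$\omega = 0$; flexibility, which does need alignment, is reported from
coupled runs instead.

**The permutation null is anchored at the global mean allegiance.** For
a random size-$n$ pseudo-system, the expected integration equals the
mean off-diagonal allegiance $\bar P$. A designated block that merges
with one of $K-1$ partner systems per slice attains cross-system
allegiance at most $1/(K-1)$ — and if all systems are equally sized and
coherent, $\bar P$ itself sits at or above $1/(K-1)$, because the
designated system's own cross cells plus the other systems' near-unit
within-block cells dominate the average. In that regime a planted
integrator can *never* clear the 97.5th percentile: the role is
structurally unidentifiable. Writing $u$ for the probability that a
background node is engaged, $d$ for the designated size, $m$ for the
background system size, the identifiability margin
$1/(K-1) - \bar P(u, d, m)$ is maximized by (i) a designated system
small relative to the background systems, (ii) moderate background
disengagement, and (iii) fully engaged merge partners. The role-scenario
defaults — $d = 8$, three background systems of 16, background
disengagement rate 0.35, merges re-engaging the partner block, connector
merge rate 0.7 (which centers its integration on $\bar P$ by the same
identity) — come from this closed-form analysis. Conversely,
ephemerality is identifiable only when $d$ exceeds the number of
systems: by pigeonhole every permuted pseudo-system then contains
same-system pairs with high allegiance, holding the null floor above a
truly scattered system.

In role scenarios, background deviations are therefore modeled as
transient *decoupling* (the node disengages entirely for a slice: its
edges carry only noise around zero and its planted label is a singleton)
rather than defection into another system. Defection manufactures
exactly the diffuse between-system allegiance that swamps the
integrator's signal; decoupling removes it while still degrading
within-system coherence.

# Numerical choices

* Louvain move tolerance $10^{-10}$ absolute on $\Delta Q$; quality
  comparisons in tests at $10^{-9}$.
* Ties in the greedy move go to the lowest community index after a
  seed-shuffled visitation order, so runs are bit-reproducible given the
  seed. Per-run seeds derive from the master seed via one draw of
  `sample.int`, and are recorded in ensembles and manifests.
* Fisher z clips $|r|$ at $1 - 10^{-7}$, keeping perfect correlations
  finite; the z diagonal is set to 0 (self-weights carry no community
  information). Zero-variance series yield zero correlations with a
  warning rather than `NA` propagation.
* Rest windowing drops trailing samples that do not fill a window
  (300 samples at window 11 → 27 windows, 3 dropped).
* Empty slices get an all-zero null matrix with a warning; a design
  matrix with deficient rank is handled by pivoted least squares (the
  residual projection is unique) with a warning.
* Readers reject asymmetry above `symmetrize_tol` (default $10^{-6}$),
  silently accept below `tol` ($10^{-10}$), and symmetrize with a
  warning in between. All writers emit 17 significant digits so
  write/read round-trips are bit-exact for doubles.

# Problem sizes used in validation

The test suite and acceptance script run at desk scale, chosen so the
full suite completes in minutes: exhaustive-oracle instances use
$N = 4, T = 2$ (all 4140 partitions of the 8 supra-nodes enumerated —
an exact global optimum for the Louvain comparison), recovery and
headline-analog fixtures use $4 \times 8$ nodes over 8 slices with
100-run ensembles, and role scenarios use $N = 56$ over 8 slices with
50-run ensembles and 1000-replicate nulls over 10 master seeds per
role. The full-scale analysis the package targets (hundreds of regions,
dozens of conditions, $100$ optimizations, $0$–$10$ parameter grids) is
the same code path; only sizes change.

# Known limitations

* The Louvain heuristic is greedy: on degenerate quality landscapes
  different seeds return different near-optimal partitions. That is by
  design — the allegiance matrix integrates over the ensemble — but
  single-run outputs should not be over-interpreted.
* The Newman–Girvan null is undefined for signed networks; truncation
  discards anticorrelation structure. Signed-null variants are out of
  scope.
* Categorical coupling makes flexibility insensitive to slice order and,
  as discussed, masks transient single-slice disengagement for
  $\omega > 0$.
* The permutation null preserves system count and sizes but not any
  spatial or hierarchical structure among systems.
* Group-level (multi-subject) aggregation is limited to computing
  coefficients per subject and averaging externally; no mixed-effects
  machinery is provided.
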