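---
title: "Methods: temporal phenotyping by topology and pseudo-time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal phenotyping by topology and pseudo-time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phenotraj` reconstructs disease-progression pathways from record-level
encounter data by two independent routes: a topological network whose
spanning tree is read as a set of trajectories, and bootstrapped
pseudo-time-series fitted with an autoregressive hidden Markov model.
This vignette documents the models, the parameters that matter, the
numerical conventions, and the design choices that were genuinely open —
together with what the synthetic generators can and cannot tell you
about behaviour on real data.

## 1. The topology arm

### Model

Each encounter is a feature vector (here: age in years, smoking habit,
HbA1c in mmol/mol, BMI in kg/m², systolic blood pressure in mm Hg, total
cholesterol and triglycerides in mg/dL), first rescaled per feature to a
symmetric `[-1, 1]` range (`x' = 2(x - min)/(max - min) - 1`). Binary
features fall out of the same formula as {−1, +1}; constant features are
passed through at 0 with a log line, since they carry no geometry.

The network is the classic Mapper construction:

1. a metric on encounters — cosine distance for clinical features
   (scale-free after normalisation), Euclidean in benchmark mode;
2. two lens functions — the projection onto the first right singular
   vector of the column-centred feature matrix (dominant variation) and
   L∞ centrality `max_j d(i, j)` (distance to the most remote point),
   or, in benchmark mode, the two observed variables themselves;
3. an overlapping cover: per lens dimension, `n` closed intervals of
   length `l = R/(n - (n-1)g)` stepped by `l(1-g)` over the lens range
   `R`, so adjacent intervals overlap by exactly the gain `g` and their
   union is exactly the range; the 2-D bins are the `n²` products;
4. single-linkage clustering within each bin;
5. one node per cluster, an edge wherever two clusters share an
   encounter, annotated with the shared set.

### Within-bin cluster count: adaptive by default

How many clusters to cut per bin is the construction's geometric scale.
Cutting the dendrogram at a *fixed* count k (`cluster_mode = "fixed_k"`)
is well defined and supported, but it shatters sparse bins into
singleton nodes: single linkage peels off the most isolated points one
by one, every sparse corner of the data becomes a handful of
disconnected specks, and the resulting network is never fully connected
— which defeats both community detection and trajectory mining. The
default (`cluster_mode = "histogram"`) therefore sets the cut height
adaptively per bin: the single-linkage merge heights plus the bin
diameter are histogrammed into `clusters_per_bin` bins, and the
dendrogram is cut at the first empty histogram bin — the first gap in
the linkage spectrum, the natural boundary between within-cluster and
between-cluster merge scales. Bins without such a gap stay one cluster.
This is the behaviour of the reference Mapper implementations used in
practice, it reproduces connected networks of a few dozen nodes on
benchmark data, and `clusters_per_bin` keeps its role as the geometric
scale: larger values resolve finer gaps and yield more clusters.

### Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `metric` | cosine | scale-free similarity of normalised clinical profiles |
| `lens_pair` | svd+linf | variance direction × outlyingness; `raw2d` for 2-variable benchmarks |
| `num_intervals` | 7 | resolution per lens dimension; 5–10 is the useful range at cohort scale |
| `gain` | 0.6 | overlap fraction in (0,1); higher gain = more edges, never fewer |
| `clusters_per_bin` | 8 | geometric scale (histogram resolution of the linkage-gap cut) |

Boundary points belong to every interval that contains them (closed
intervals), which preserves connectivity; the top interval's upper bound
is clamped to the exact lens maximum to keep floating-point round-off
from shaving off the extreme row.

### Communities, spanning tree, trajectories

Sub-phenotypes are communities maximising unweighted modularity
`Q = Σ_c (e_c/m − (d_c/2m)²)`. Networks with ≤ 16 nodes are solved to
the certified global optimum (integer programming via igraph); larger
networks use a deterministic multi-start local search — greedy
agglomeration alternated with single-node moves (including splits to a
fresh singleton), restarted from one deterministic and many seeded
random starts with the best partition kept — and the result is flagged
approximate. The restart count adapts to graph size. On 10-node random
graphs this search matched exhaustive enumeration on every instance we
tested (100/100), but it remains a heuristic.

Progression trajectories come from a minimum spanning tree over the
network: Kruskal's algorithm with fully deterministic tie-breaks (edges
ordered by weight, then smaller node id, then larger). Cohort mode
weights an edge by the mean time-since-first-visit (days) of its shared
encounters, so the tree follows temporally early connections; benchmark
mode weights by node-index distance, since ids assigned in bin-traversal
order encode topological proximity when the lenses are monotone.

Reading trajectories off the tree is automated by two rules
(`mine_trajectories()`):

* **Root** — the node holding the most *first* observations (each
  subject's or sequence's earliest encounter): the cluster where
  follow-up starts. Rooting at the node with minimal mean time is also
  available (`extract_trajectories()` default) but is fragile: a tiny
  node of a few early observations — including early arrivals in an
  *advanced* disease state — can claim the root.
* **Termini** — a leaf counts as a progression endpoint only if its
  mean time exceeds the component's average node mean time and it holds
  at least `min_share` (default 0.5 %) of the observations. A spanning
  tree over a two-dimensional point cloud always has incidental interior
  leaves; an endpoint should be *late* and *supported*, not an early
  side-pocket of the starting region or a three-encounter artefact.

Each subject's encounters are resolved to single nodes (the containing
node whose other members are nearest on average; ties to the lower id),
ordered by time, and collapsed so consecutive repeats count once. The
subject is assigned to the mined trajectory with the highest Jaccard
similarity on node *sets* — order and dwell times are deliberately
ignored at this step, matching how the mined trajectories themselves are
plain node sequences. Ties go to the lower trajectory index.

## 2. The pseudo-time arm

Each bootstrap iteration samples `sample_size` encounters uniformly
without replacement (default `min(200, n)`: large enough to span the
label classes, small enough that the complete-graph spanning tree stays
cheap), builds the complete cosine-distance graph, takes its minimum
spanning tree, draws a start uniformly among sampled label-0 rows and an
end among label-1 rows, and returns the unique tree path between them.
Iteration *i* of an ensemble uses seed `base_seed + i`, so any subset of
the ensemble is reproducible from the base seed alone; iterations whose
subsamples miss a label class (bounded retries) are skipped and counted.

The series feed an order-1 autoregressive Gaussian HMM: hidden state
`z_t` follows a Markov chain `(π, A)`; the first observation of a
sequence is `N(μ0_k, diag σ0²_k)` and later ones
`N(c_k + Φ_k x_{t−1}, diag σ²_k)`. Inference uses the scaled forward
(-backward) recursion — exact on a chain. EM updates are closed form:
responsibility-weighted least squares for `(c_k, Φ_k)` per output
dimension (diagonal noise), weighted moments for variances, `π` and `A`.

Numerical conventions: variances floored at 1e−6, a 1e−8 ridge on the
weighted normal equations, restarts whose states lose all responsibility
mass (< 1e−6 everywhere) are discarded with a warning, and the
log-likelihood trace is non-decreasing up to 1e−8 by construction.
Initialisation is k-means on the pooled observations for the state
means, uniform `π`, sticky `A = 0.8 I + 0.2/K`, `Φ = 0`; 5 restarts by
default, best final log-likelihood wins. Fitted states are relabelled by
ascending first component of `μ0` for identifiability. `K` defaults to 5
— the scale suggested by the topology's community structure — but is an
ordinary parameter; no automatic selection over `K` is attempted.
Viterbi decoding breaks ties toward the lower state index.

## 3. The synthetic generators

### Five-state benchmark

`benchmark_spec()` encodes the validation design: 750 sequences × 10
steps = 7,500 observations of `(X, Y)` from a five-state AR-HMM. The
transition matrix is hand-coded — state 1 persists at 0.8 and can branch
anywhere; states 2 and 3 persist at 0.8 and fall to their endpoint at
0.1; states 4 and 5 are absorbing — and every sequence starts in
state 1. Splitting the 7,500 observations into many short sequences
(not one long chain) is essential: with two absorbing states a single
long chain would collapse into absorption and the transient states
would vanish from the data.

The emission means are free parameters of the design (only their
ordering and separation matter to any test): the defaults place the
states on two monotone arms meeting at the origin — 1:(0,0) → 2:(3,0) →
4:(6,0) along X, and 1:(0,0) → 3:(0,3) → 5:(0,6) along Y — with unit
noise, so adjacent states are ~3 SD apart (distinct but overlapping)
and each observed variable is monotone along one progression branch,
which is also what makes node-index spanning-tree weights meaningful.
AR coefficient 0.2 with intercepts `c_k = (1 − 0.2) μ_k` keeps each
state's stationary mean at its nominal position.

### Cohort generator

`generate_mosaic_like_cohort()` emulates a multi-year T2DM follow-up
registry at the scale of ~924 subjects / ~13,600 encounters:
Poisson-sized visit sequences (mean ≈ 14.7 visits), gamma-distributed
inter-visit gaps (~280 days), seven features drifting along a latent
per-subject progression rate, and a complication label that switches
0→1 at a latent onset time for ~45 % of subjects and never reverts —
so label prevalence rises with follow-up, the property the pseudo-time
endpoints rely on. Progressors drift faster, which couples the label to
the feature geometry.

What the generators do *not* emulate: missing data and irregular
measurement panels, coding errors, treatment feedback (features
responding to intervention), informative visit timing, non-monotone
staging, or cohort heterogeneity beyond a scalar progression rate.
Passing tests on these generators demonstrates the machinery —
coverage, connectivity, exactness of inference, recovery of known
dynamics — not clinical validity on any particular registry.

## 4. Testing conventions and problem sizes

All stochastic tests fix their seeds. Oracles are independent of the
code paths they check: exhaustive enumeration over set partitions for
modularity (n ≤ 8, plus the integer-programming optimum at n = 10),
enumeration over edge subsets for spanning trees (n ≤ 8), exhaustive
hidden-path enumeration for the HMM likelihood (K ≤ 3, length ≤ 6), and
closed-form AR(1)/OLS identities for the single-state model. The
end-to-end benchmark property (trajectories from majority-state-1 nodes
to absorbing-state nodes on the top-ranked connected topology) is
asserted over three generator seeds with a 3 × 3 × 2 parameter grid;
EM recovery uses 200 sequences of length 20; the pseudo-time contract
runs the full 1000-series ensemble on the full-size synthetic cohort.
These sizes were chosen as the smallest that exercise the claims
convincingly on a single core.

## 5. Known limitations

* Exact modularity is limited to 16 nodes; beyond that the partition is
  a well-tested heuristic, flagged `approximate`.
* The encounter-to-node resolution rule (nearest co-members) and the
  terminal-leaf rules are reasonable conventions, not identified by any
  likelihood; alternatives (e.g. resolving to the largest containing
  node) would change individual assignments at the margin.
* Single-linkage chains happily through density bridges; topologies on
  strongly overlapping phenotypes can fuse pathways that model-based
  clustering would separate.
* The AR-HMM assumes diagonal Gaussian noise and order-1 dynamics;
  correlated noise or longer memory is absorbed into the transition
  structure rather than modelled.
* Pseudo-time-series treat the label as ground truth for trajectory
  endpoints; label noise propagates directly into the fitted dynamics.
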