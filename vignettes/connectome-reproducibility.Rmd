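---
title: "Methods: test-retest reproducibility of weighted structural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest reproducibility of weighted structural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`connrep` quantifies how reproducible probabilistic-tractography
structural networks and their graph metrics are across repeated scans of
the same subjects. This vignette is the package's account of the
underlying model and of the methodological choices baked into the
implementation — what is computed, under which conventions, and why.

## 1. Input model

The pipeline starts from connectivity matrices, not images. A *scan* is
a symmetric `n × n` matrix of connection probabilities `P_ij ∈ [0, 1]`
with zero diagonal; a *cohort* is a subjects × sessions collection of
scans over a shared node set. Everything upstream (diffusion
acquisition, tractography, parcellation, registration) is out of scope;
`symmetrize()` is provided for the one step at the boundary, averaging
the two directed probabilities of each region pair
(`(P_{i→j} + P_{j→i})/2` per unordered pair).

## 2. Group-level connectivity thresholding

Spurious low-probability edges are removed by a *group* rule: edge
(i, j) is deleted when

```
mean(P_ij) + 2 · sd(P_ij) < τ
```

with the mean and the sample (n−1) standard deviation taken across
scans, and strict inequality — a tie retains the edge. Under the
**common** strategy the statistic pools all scans from both sessions,
so every subject and session shares one mask: identical edge positions
and identical sparsity by construction. Under the **separate** strategy
the rule is evaluated per session; the session masks, and hence the
sparsity, may differ slightly. Sparsity is the retained fraction of the
`n(n−1)/2` possible edges of a simple undirected graph (3003 at
n = 78). The default sweep τ = 0.01 … 0.10 in 0.0025 steps (37
thresholds) spans the range where such networks move from roughly a
third of edges retained down to a few percent.

The sd denominator (n−1) and the tie-breaking direction are
conventions; both are stated here because they shift masks for edges
sitting exactly at the rule boundary. The sweep includes its endpoint
when the range is an integer multiple of the step within 1e−9, so
`0.01 + 36 × 0.0025 = 0.10` is included despite floating-point
representation.

## 3. Weighted network metrics and their conventions

Weights are the connectivity probabilities themselves (`w_ij = P_ij`
after masking), and connection *lengths* are their reciprocals,
`ℓ_ij = 1/w_ij`. On top of all-pairs shortest path lengths `d_ij`
(Dijkstra, via igraph):

* `E_glob = (1/(n(n−1))) Σ_{i≠j} 1/d_ij`, with `1/∞ = 0`, so
  disconnected pairs contribute zero naturally;
* `L_w` = mean `d_ij` over *connected* ordered pairs. Disconnected
  pairs are excluded rather than imputed, and `n_connected_pairs` is
  reported alongside so the exclusion is never silent. A network with
  no connected pair has `L_w = NA`;
* `C_w`: Onnela-style clustering,
  `C_i = (1/(k_i(k_i−1))) Σ (w_ij w_ih w_jh)^{1/3}` over ordered
  neighbor pairs, `C_i = 0` for degree < 2, averaged over all nodes;
* `E_loc`: mean nodal efficiency of the neighbor-induced subgraph,
  `(1/(k_i(k_i−1))) Σ_{j≠h∈N_i} (w_ij w_ih / d_jh(N_i))^{1/3}`, where
  `d_jh(N_i)` is computed *within* the induced subgraph.

Two deliberate deviations from some toolbox defaults:

1. **No max-weight rescaling** inside `C_w` (and `E_loc`). Rescaling by
   the maximum weight would destroy the exact linear scale covariance
   `E_glob(cW) = c E_glob(W)`, `C_w(cW) = c C_w(W)`,
   `E_loc(cW) = c E_loc(W)`, `L_w(cW) = L_w(W)/c`, which is the
   property that makes cost normalization interpretable: dividing
   weights by the total cost `Σ w` rescales every metric by that
   subject-specific constant and nothing else. The test suite asserts
   this covariance to 1e−9 relative.
2. **Subgraph distances by Floyd–Warshall in compiled code.** The full
   network uses Dijkstra through igraph; the neighbor-induced subgraphs
   of `E_loc` are small and dense enough (degree-sized) that a compiled
   O(k³) Floyd–Warshall per node is faster than per-subgraph graph
   construction, and it is the innermost loop of the 37-threshold
   sweep. The independent test oracle routes subgraph distances through
   igraph instead, so the two code paths check each other.

On weights in [0, 1] without rescaling, `E_glob ≤ 1` and `C_w ≤ 1`;
with cost normalization the weights sum to 1 and absolute magnitudes
change by the subject's total cost, while ratios between conditions are
preserved.

## 4. Reproducibility statistics

For a subjects × sessions table of any quantity:

* `CV_ws` = 100 × mean over subjects of the per-subject sd across
  sessions, divided by the grand mean;
* `CV_bs` = 100 × mean over sessions of the per-session sd across
  subjects, divided by the grand mean;
* ICC(A,1) (two-way, absolute agreement, single measures):
  `(MS_R − MS_E) / (MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E))` from the
  two-way ANOVA mean squares. Negative estimates are reported
  untruncated; classification (poor < 0.5 ≤ moderate < 0.75 ≤ good
  < 0.9 ≤ excellent) is applied afterward, with left-closed boundary
  ownership as written.

CVs are scale-invariant but not shift-invariant; they are meaningful
here because connectivity and the four metrics are positive ratio-scale
quantities. Edges whose value is zero across the entire cohort have an
undefined CV/ICC and are reported as `NA` and counted, not dropped
silently.

One estimator property worth stating explicitly: with k sessions, the
sample sd has expectation `c4(k)` times the population sd
(`c4(2) = √(2/π) ≈ 0.798`), so with two sessions `CV_ws` systematically
estimates about 80% of the population within-subject CV. The package
reports the estimator exactly as defined (it is the field's standard
definition); `theoretical_reliability()` documents the bias so
parameter-recovery comparisons can account for it.

Edge-wise reproducibility applies the three statistics independently to
every upper-triangle edge (vectorized), and edges are binned by
cohort-mean connectivity into half-open bins `[b, b + 0.01)` from 0 to
0.3 plus one overflow bin — 31 groups at the defaults; starting the
grid at 0.01 instead reproduces the 30-group variant some reports use.
Matrix similarity is the mean Pearson correlation of vectorized upper
triangles, within subjects (across session pairs) and between subjects
(per session, averaged over both sessions; averaging across sessions
rather than using session 1 only is a choice, exposed by computing per
session internally).

## 5. Integration over sparsity

Because metric values depend on the threshold, each metric is
summarized across the sweep by the trapezoidal integral of its
metric-versus-sparsity curve, divided by the sparsity range. The
normalization makes the summary a sparsity-weighted *mean*, on the same
scale as the per-threshold values and comparable between subjects whose
sparsity ranges differ slightly — which is exactly the situation the
separate strategy creates; the raw integral is available via
`normalize = FALSE`. Curves are sorted by sparsity; two thresholds
yielding the same mask produce duplicate sparsity points, collapsed by
averaging the metric. Under the separate strategy each session is
integrated on its own sparsity grid.

## 6. The synthetic cohort generator

No public tractography test-retest matrices accompany this design, so
the generator is a first-class module emulating the study conditions:
30 subjects × 2 sessions, 78 nodes, and a connectivity distribution
with ~80% of edges below 0.01.

Construction, deterministic given the seed: nodes get fixed uniform
positions in the unit cube; the population template is
`T_ij = base_scale · exp(−decay_rate · dist(i, j))` (exponential decay
is a modeling choice — the empirical observation is only that
short-range edges are stronger); each subject multiplies each edge by
`exp(b)`, `b ~ N(0, (σ_b g_ij)²)`, each session by `exp(e)`,
`e ~ N(0, (σ_w g_ij)²)`; values are clipped at `clip_max`. The noise
scale `g_ij = (median(T)/T_ij)^noise_scaling`, clamped to [0.2, 5],
makes weak edges noisier — mirroring the streamline-count origin of
tractography noise, where low-probability connections rest on few
streamlines. Because `g` multiplies both variance components equally,
the per-edge ICC is flat across connectivity levels while both CVs fall
with connectivity, the pattern real cohorts show; and because `g = 1`
at the median template edge, the *median* per-edge CV_ws, CV_bs and ICC
still match the homogeneous lognormal closed forms of
`theoretical_reliability()` (a monotone reparameterization preserves
the median).

Defaults and why: `decay_rate = 9`, `base_scale = 0.5` were tuned once
so that ~80% of edges fall below 0.01 at 78 nodes, then frozen;
`σ_b = 0.3 > σ_w = 0.1` (log-scale, dimensionless) encode that
between-subject variation exceeds scan-rescan variation, giving an
expected edge ICC of 0.9; `noise_scaling = 0.3` spans roughly a 5× CV
ratio between the weakest and strongest edges; `clip_max = 1` keeps
values probabilities. With these settings clipping is virtually absent;
pushing `base_scale` toward 1 would clip strong edges and invalidate
the closed forms.

What the generator does *not* emulate: spatial correlation of subject
effects across edges, anatomically structured parcel sizes or
hemispheric symmetry, registration or motion artifacts, and any
distributional shape beyond lognormal. Passing tests on synthetic
cohorts therefore validate the *statistical machinery* — thresholding,
metrics, estimators, integration — not the anatomical realism of any
particular dataset.

## 7. Pipeline, determinism, and problem sizes

`run_full_analysis()` chains the stages (simulate/load → masks →
metrics per scan × threshold × strategy × normalization → edge
reliability and bins → similarity → integrated summaries) and, given an
output directory, writes TSV/JSON tables plus a manifest with MD5
checksums; numeric text output uses 12 significant digits so reruns are
byte-identical. Any stage failure aborts with the stage name and leaves
a `FAILED` marker. Scans are independent at every threshold, so results
do not depend on evaluation order.

The test suite exercises unit properties on small graphs (≤ 12 nodes)
against brute-force oracles (Floyd–Warshall all-pairs distances,
exhaustive triangle enumeration, first-principles ANOVA sums of
squares), and end-to-end behavior on cohorts at the full study design
(78 nodes, 30 × 2) for single-cohort checks, with 10-seed replications
for the qualitative claims (CV falling across connectivity bins;
separate-strategy degradation of integrated cost-normalized `C_w` and
`E_loc`). These sizes are the package's chosen balance between
statistical resolution and a test suite that runs in a few minutes.

## 8. Known limitations

* The connectivity-threshold family is the only thresholding
  implemented; fixed-density thresholding and binary networks are out
  of scope.
* `CV_ws` with two sessions carries the `c4(2)` small-sample bias noted
  above; comparisons against population CVs should expect it.
* The closed-form oracle breaks down under heavy clipping or log-sds
  beyond ~0.5.
* Only the four global metrics are computed; nodal metric
  reproducibility, small-worldness, and long-term/inter-site designs
  are not addressed.
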