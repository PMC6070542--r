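# connrep

Test-retest reproducibility analysis for weighted structural brain
networks built from probabilistic-tractography connectivity matrices.

## The problem

Probabilistic tractography yields, for each subject, a symmetric node ×
node matrix of connection probabilities `P_ij ∈ [0, 1]` between cortical
regions (e.g. 78 AAL regions, hence 78·77/2 = 3003 edges). Graph metrics
computed on these weighted networks are used as biomarkers, so their
short-term scan-rescan reproducibility matters — and it depends strongly
on how spurious low-probability edges are removed and on how networks
are normalized. `connrep` is for imaging researchers who want to
quantify that reproducibility, and to compare thresholding and
normalization strategies, on their own cohorts or on synthetic cohorts
with known ground truth.

## What it computes

**Group thresholding.** An edge is removed for the whole group when
`mean(P_ij) + 2·sd(P_ij) < τ` for a connectivity threshold τ. The
statistic is pooled over all scans of both sessions (*common* strategy —
every subject keeps identical edge positions and sparsity) or evaluated
per session (*separate* strategy — sparsity may differ between
sessions). Sweeping τ from 0.01 to 0.10 in 0.0025 steps gives 37
networks per scan.

**Weighted network metrics**, with edge length `ℓ_ij = 1/w_ij`:

- global efficiency `E_glob = (1/(n(n−1))) Σ_{i≠j} 1/d_ij`
- characteristic path length `L_w` = mean `d_ij` over connected pairs
- clustering coefficient `C_w` (Onnela geometric-mean triangle
  intensity, no max-weight rescaling)
- local efficiency `E_loc` (efficiency of each node's neighbor-induced
  subgraph)

computed with raw weights and with *cost normalization* (weights divided
by the subject's total cost `Σ w_ij`). Metrics are summarized across the
sweep by the range-normalized integral over sparsity.

**Reproducibility statistics.** For any subject × session table:
within-subject CV (`CV_ws` = mean within-subject sd / grand mean),
between-subject CV (`CV_bs` = mean per-session between-subject sd /
grand mean), and the two-way absolute-agreement single-measures
intraclass correlation ICC(A,1)
`(MS_R − MS_E) / (MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E))`, applied
edge-wise (with connectivity-binned summaries) and to integrated
metrics, plus within/between-subject Pearson similarity of whole
matrices.

**Synthetic cohorts.** `generate_cohort()` draws test-retest cohorts
from a two-level lognormal variance-components model with
distance-dependent connectivity and connectivity-dependent noise, so
every statistic above can be validated against closed-form expectations
(`theoretical_reliability()`).

## Worked example

```r
library(connrep)

coh <- generate_cohort(synthetic_config(seed = 1))
coh
#> connrep cohort: 30 subjects x 2 sessions, 78 nodes (3003 edges)

edge_reliability(coh)
#> edge reliability: 78 nodes; median CV_ws 7.9%, CV_bs 31.2%, ICC 0.89
#> (0 undefined edges)

unlist(similarity(coh))
#>  within_subject between_subject
#>       0.9989467       0.9897650

res <- run_full_analysis(run_config(synthetic = synthetic_config(seed = 1)))
subset(res$integrated, normalized & metric %in% c("C_w", "E_loc"),
       c(strategy, metric, cv_ws, icc))
#>  strategy metric  cv_ws   icc
#>    common  E_loc 0.0885 0.849
#>    common    C_w 0.1037 0.855
#>  separate  E_loc 0.1950 0.568
#>  separate    C_w 0.3149 0.450
```

Reading the output: repeated sessions of the same subject correlate at
0.999 versus 0.990 between subjects; the median edge has a
within-subject CV of ~8% (between-subject ~31%) and ICC ~0.89. The last
table shows the central methodological effect: integrated
cost-normalized clustering and local efficiency are highly reproducible
when both sessions are thresholded to a common sparsity (ICC ≈ 0.85),
but letting sparsity differ between sessions (separate strategy)
inflates `CV_ws` and drops the ICC to ≈ 0.45–0.57.

A thin CLI wrapper is installed at `inst/cli/connrep.R`
(`simulate`, `run`, `reliability` subcommands).

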