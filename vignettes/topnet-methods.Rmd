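---
title: "Methods: trend-of-progression selection on state-specific gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend-of-progression selection on state-specific gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

topnet implements a network-based gene prioritization procedure for cohort
expression data collected in several ordered physiological states (for
example healthy tissue, a precursor lesion, and an overt disease state).
The premise is that in a systems disease the *interactions* of a gene
matter as much as its expression level: a gene that is peripheral in the
healthy interaction network but becomes a well-connected, locally dense hub
as the disease develops is a stronger disease-gene candidate than one that
merely changes mean expression.

For each state a **gene-gene interaction network (GGIN)** is built over the
measured genes. A gene pair becomes an edge iff

1. the two-sided Pearson p-value of the pair's expression correlation over
   the state's arrays is at most a threshold $p_0$ (default 0.01), and
2. the protein pair encoded by the genes interacts in a supplied
   protein-protein interaction (PPI) scaffold.

Because network properties depend on sample size, every network is built
from the same number of arrays (`subsample_size`, default 8). A state with
exactly that many samples yields one network; a larger state yields an
ensemble of `n_subsamples` (default 100) networks from random 8-array
draws, and per-gene statistics are ensemble-aggregated.

For each gene and state we track the degree $D$ and the local clustering
coefficient

$$C = \frac{2e}{k(k-1)},$$

where $e$ is the number of edges among the gene's $k$ neighbors ($C = 0$
for $k \le 1$ by convention). The **trend-of-progression (ToP)** rule then
selects a gene iff, along the ordered state sequence, (a) it appears in at
least one network; (b) in at least one state it is a hub with local
density ($D > 4$ and $C > 0$, jointly); and (c) its $D$ and $C$ grow into
the final (disease) state — by default the final state must strictly
dominate every earlier state in $D$ and weakly dominate in $C$, while
transitions *among* the earlier states are unconstrained (a healthy-to-
intermediate dip is explicitly tolerated). The **TPS** variant additionally
requires the gene to be differentially expressed (adjusted $p < 0.05$ and
fold change $> 1.5$ or $< 1/1.5$) in the intermediate-vs-first or
final-vs-first contrast.

Selections are calibrated by two bespoke randomizations: **type-1**
permutes each gene's intensities across all arrays (conserves each gene's
value distribution, destroys all pairwise correlation); **type-2** replaces
every network link by a distinct gene pair drawn uniformly from the
universe (conserves the link count, destroys the topology). Permutation
p-values use the add-one estimator $p = (1 + \#\{null \ge obs\})/(1 + N)$,
so they are never zero. A topology-conserving "type-3" relabelling is
deliberately refused: it does not randomize the construction process.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `p0` | 0.01 | Pearson p-value threshold for GGIN edges |
| `subsample_size` | 8 | arrays per network (sample-size normalization) |
| `n_subsamples` | 100 | networks per over-sized state |
| `min_hub_degree` | 4 (exclusive) | hub criterion $D > 4$ |
| `c_tolerance` | 0 | slack $\varepsilon$ in the $C$ trend comparison |
| `trend_mode` | `into_final_strict` | see below |
| `p_adj_threshold`, `fc_threshold` | 0.05, 1.5 | TPS DEG filter |
| `degree_fold` | 5 | early-marker degree increase first → intermediate |
| `deg_p_threshold` | 1e-4 | early-marker raw DEG p-value bound |

Early-detection markers are TPS genes whose degree rises at least
`degree_fold`-fold from the first to the intermediate state (absence from
the healthy networks, $D = 0$, passes when the intermediate degree reaches
the fold), that are strongly differentially expressed there (raw
$p <$ `deg_p_threshold`), and that are not tps-DEGs in the other
intermediate state (exclusivity).

## Design choices where the procedure was open

* **C compared weakly, with configurable tolerance.** Published example
  records of selected genes include cases whose printed $C$ dips slightly
  from the intermediate to the final state while $D$ keeps growing; a
  strict $C$ inequality would reject them. The default therefore uses
  $C_{final} \ge C_s - \varepsilon$ with $\varepsilon = 0$, and
  `c_tolerance` / `trend_mode` expose stricter or fully monotone variants.
* **Hub criterion is joint** ($D > 4$ and $C > 0$ in the *same* state),
  matching the reading "in at least one GGIN satisfies ..."; `hub_joint =
  FALSE` relaxes this.
* **Ensemble aggregation** of per-gene $D$ and $C$ is the arithmetic mean,
  with absence counted as $D = 0$ and $C$ averaged over networks where the
  gene is present. Integer degrees in published per-gene tables suggest
  single-network values may also have been used; `aggregate =
  "single_network"` and `"median"` are provided.
* **Pearson p is t-based by default** ($t = r\sqrt{(n-2)/(1-r^2)}$,
  $n - 2$ df): fast and deterministic; a seeded permutation mode is
  available and the two agree within ±0.01 at $n = 8$ (tested against a
  10,000-permutation oracle).
* **Degree-exponent fit** is a least-squares line on the log10-log10
  degree histogram over nonzero-count degrees. It is descriptive only (no
  xmin selection, no MLE); it exists to reproduce summary tables, not to
  test scale-freeness.
* **Welch t** (unequal variances) is the default two-class statistic, for
  heterogeneous cohorts; pooled t is available. The SAM d-statistic with
  its fudge constant is *not* reproduced; where a SAM-like significance
  filter is needed, a pooled-null permutation p and a plug-in permutation
  FDR around the plain t stand in.
* **Plain hypergeometric enrichment** (upper tail, BH across sets)
  replaces ontology-graph-conditional testing; the universe defaults to
  the caller's choice (platform genes vs network genes both make sense and
  change p-values; both are supported by passing the universe explicitly).
* **Type-2 rewiring samples pairs without replacement** so the rewired
  graph stays simple, matching the observed networks; pairs are drawn by
  unranking uniform linear indices, which is exact and O(links).
* **Null campaigns for trend selections randomize jointly**: type-1 on
  intensities before network construction plus type-2 on every built
  network (`type = "both"`), with `"type1"`/`"type2"` available singly.

## Numerical and degenerate-input conventions

* $|r| \to 1$ pairs get $p = 0$ (the $t$ transform is clamped); zero-
  variance genes cannot enter correlations and are skipped with a warning
  during network construction rather than failing the build.
* Duplicate probe symbols collapse to the max-mean-intensity row by
  default (`collapse_rule = "mean"` averages instead); symbols are matched
  case-insensitively via uppercasing throughout.
* BH adjustment is the standard step-up with enforced monotonicity,
  order-preserving, and is cross-checked against an independent
  implementation in the tests.
* Empty selections error in `hit_rate` (a hit rate of an empty list is
  undefined); null replicates with zero selected genes record `NA` hit
  rates and are treated as hit rate 0 when summarized against an observed
  value.

## What the synthetic generator emulates — and what it does not

`simulate_study()` plants co-expression modules on a scale-free PPI
scaffold. Members of a module in state $s$ are drawn as

$$x = \mu_g + \delta_s + \sigma\left(\sqrt{\rho_s}\, f + \sqrt{1-\rho_s}\,\epsilon\right)$$

with a shared per-sample factor $f$, giving expected pairwise correlation
exactly $\rho_s$; all within-module pairs are added to the scaffold so
that planted correlation edges can pass the PPI filter. The
`paper_shaped` fixture states the world the tests run in: 600 genes, four
states with 8/15/15/15 samples (the cohort layout of the motivating
study), a 1500-edge scaffold with degree exponent 2.5, three disjoint
12-gene modules with $\rho = (0.2, 0.6, 0.6, 0.9)$ and
$\delta = (0, 1, 1, 2)$ log2 units along the sequence, unit noise, and
baselines $\mathcal{N}(8, 1.5^2)$ — typical log2 microarray intensities.
These values were chosen once as a realistic planted-progression world
(module correlation growing from weak to strong, a twofold-per-stage mean
shift) and are not tuned to test outcomes.

The generator does **not** model probe effects, batch structure, missing
values, heavy-tailed noise, or correlated background modules. A green
recovery test therefore establishes that the pipeline finds genes whose
network prominence genuinely grows along the sequence and rejects
reversed sequences and randomized data — it does not establish
performance on real microarray cohorts, where noise structure and the
PPI scaffold's incompleteness matter.

## Known limitations

* Published cohort-derived numbers (list sizes, hit rates, network
  node/edge counts) depend on the original expression data and curated
  catalogs; the package reproduces the procedure and the published
  arithmetic identities, not those data-dependent lists.
* The power-law exponent is a descriptive fit, unsuitable for inference.
* The permutation-FDR stand-in is not the SAM d-statistic; exact DEG
  counts from SAM-based analyses will not be matched.
* Hypergeometric enrichment ignores gene-set overlap structure
  (no conditional testing).
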