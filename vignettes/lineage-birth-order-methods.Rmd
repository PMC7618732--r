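---
title: "Models and methods behind lineagekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lineagekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagekit)
library(dplyr)
```

`lineagekit` implements the annotation heuristics and statistics used to
organise single-cell atlases of the *Drosophila* central brain along two
developmental axes — neuroblast lineage and birth order — plus the
evaluation metrics that accompany them. This vignette explains the
models, the parameters that matter, the synthetic data the package is
validated on, and the numerical choices made where the design was open.

## The synthetic atlas generator

Every stage of the package is exercised against atlases from
`generate_atlas()`, whose ground truth is known by construction. The
generator encodes the structure the heuristics assume:

- **Lineages and clusters.** `n_lineages` lineages of
  `cells_per_lineage` cells; each lineage is one cluster (the heuristics
  treat transcriptional clusters as hemilineage proxies) and carries a
  two-TF identity code expressed only in that lineage.
- **Birth order.** Each cell has a latent `birth_time` uniform on
  [0, 1]; cells below `early_fraction` (default 0.3, the approximate
  share of early-born neurons in adult central-brain atlases) are
  early-born. Two-gene early and late marker programs are mutually
  exclusive by construction: each program's genes have zero
  negative-binomial mean in the opposite class.
- **Early-born transcriptional excess.** Early cells both activate an
  extra block of 50 genes (low baseline everywhere, stochastic per-cell
  bursts in early cells, so the block is not a single on/off module) and
  receive a uniform scaling calibrated so the expected total-UMI ratio
  early/late equals `early_umi_multiplier` exactly. The default 1.5 is a
  free parameter: published boxplots show a clear but unquantified
  excess, so the generator takes a moderate value rather than a
  calibrated one.
- **Temporal cascade.** `n_cascade` (5) TF genes switch on in ordered,
  adjacent-overlapping windows of `birth_time`, shared across lineages —
  the recurrent temporal-TF code the pseudotime stage must recover.
- **Regulons.** `n_regulons` (5) TFs each drive `regulon_size` (10)
  target genes through a shared bimodal per-cell activity (active in a
  random 40% of cells), giving strong TF–target rank correlations.
- **Counts.** Negative binomial per gene and cell,
  `var = mu + phi * mu^2` with `phi = noise_dispersion` (default 0.5),
  background means uniform on [0.8, 2] over ~600 genes so that a typical
  cell has ~800–1,200 UMI and ~400 detected genes — comfortably above
  the droplet QC thresholds, as real post-QC data would be. Batch
  effects are i.i.d. normal shifts (sd `batch_shift_sd`) on each
  (gene, batch) log-mean.
- **Embedding geometry.** `generate_embedding()` lays each lineage out
  in its own territory: early-born cells as `k = 3` well-separated
  Gaussian blobs (inter-centre distance at least 10 blob standard
  deviations; blobs are discrete birth-time slices), late-born cells
  along a single sine arc ordered by birth time with Gaussian tube
  noise. The default arc (span 12, amplitude 2, one cycle) keeps local
  point spacing well inside the DBSCAN core criterion at the default
  cell numbers; a steeper first draft fragmented spuriously, which is
  why the curve is gentle. `serpentine_lineage_spec()` instead lays a
  whole lineage (early head plus late tail) along one curve — the
  geometry of a continuous birth-order trajectory used by the
  pseudotime analyses.
- **Doublets.** `spike_doublets()` appends columns that are element-wise
  sums of two distinct real cells (UMI counts are additive), flagged and
  with parent ids recorded.

What the generator does *not* emulate: ambient RNA, read-level noise,
isoforms, unbalanced cluster sizes, partially overlapping marker
programs, or embeddings produced by an actual t-SNE/UMAP. Passing tests
therefore demonstrate that the implementations compute their statistics
correctly and recover structure when it is present as designed — not
that the heuristics are robust to every pathology of real data.

## Module scores and classification rules

`module_score()` follows the binned-control recipe: genes are placed
into `n_bins = 24` equal-frequency bins by mean log-normalised
expression (`ln(1 + count/total * 1e4)`); for each program gene,
`n_ctrl = 100` control genes are drawn from its bin (with replacement
when the bin is small); the score is the mean over program genes minus
the mean over the pooled control draws. The bin/control defaults follow
the convention of the tool family that popularised the score; they are
assumptions, not published values. Control sampling is seeded, so scores
are reproducible.

Two classification rules sit on top:

- **Broad types**: a cell is labelled with the program whose raw score
  is positive *and* whose l2-normalised score strictly exceeds all
  others; ties and all-negative cells are unassigned, and cluster-modal
  labels are extrapolated to whole clusters (modal ties broken
  lexicographically, for determinism).
- **Birth order**: early iff the l2-normalised early score is positive
  and above the late score; symmetric for late; both-negative or equal
  cells are unassigned and excluded from downstream morphology and
  pseudotime.

The l2 normalisation direction is ambiguous in prose descriptions of
this procedure; `lineagekit` normalises **per program across cells**
(so program magnitudes are comparable at the argmax) and exposes the
per-cell alternative via `score_programs(direction = "cell")`.
In-silico sexing is the one-program special case: male-program score
below zero calls female; a score of exactly zero is assigned to female
as the conservative majority choice (the rule's source leaves zero
unspecified).

## Marker statistics

`find_markers()` runs one-vs-rest two-sided Wilcoxon rank-sum tests per
gene and cluster. Although descriptions of this step sometimes name the
*signed-rank* test, the groups are independent, so the rank-sum
(Mann–Whitney) form is the applicable one; the signed-rank test is used
where it belongs, in the *paired* early/late morphology comparison. For
ordinary sample sizes the normal approximation with tie-corrected
variance and continuity correction is used; for tiny inputs (combined
n ≤ 12) the p-value is computed by exact enumeration over all group
assignments, so that small-sample p-values coincide with a brute-force
permutation test. Fold changes are
`ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))` and Bonferroni
correction is per cluster over the genes tested.

`select_variable_tfs()` keeps significant TFs whose between-cluster
coefficient of variation (sample sd of per-cluster mean normalised
expression over its mean) strictly exceeds 2. Note the geometry of this
threshold: a perfectly cluster-specific marker across *k* clusters has
between-CV √(k−1), so the rule only has headroom with ≥ 6 or so
clusters — with 4 clusters a one-hot marker sits exactly at 2. Whether
the CV should be computed on raw or normalised per-cluster means is
unstated in the descriptions this follows; normalised is used.

`expressed_gene_universe()` applies four inclusive criteria (total UMI
≥ 400; max UMI in a cell ≥ 4; every dataset's UMI share ≤ 60%; a
designated high-ambient dataset's share ≤ 30%) and reports which
criteria each excluded gene failed.

## Cluster morphology

Three statistics quantify punctate vs serpentine geometry per
(cluster × birth class) group of 2-D embedding coordinates:

1. **Mean pairwise distance** over all point pairs (needs ≥ 2 cells).
2. **Fragmentation**: the number of non-noise DBSCAN subclusters at
   eps = 0.5, minPts = 5 (the published parameters; embedding units).
   DBSCAN is implemented in-package: core points have ≥ minPts
   neighbours within eps (self included), clusters are connected
   components of cores under eps-reachability, border points join the
   lowest-index core that reaches them (a deterministic resolution of a
   genuinely arbitrary choice), noise is labelled 0 and contributes
   nothing to the count — a group that is entirely noise scores 0, not
   1.
3. **Modularity**: a complete weighted similarity graph with Gaussian
   kernel `w_ij = exp(-d_ij^2 / (2 sigma^2))`, `sigma` = median pairwise
   distance (an inverse-distance kernel is exposed as an option, since
   the distance-to-graph transform is an open choice), fast-greedy
   community detection, and the weighted modularity Q of the resulting
   partition. All-identical point sets fall back to a unit-weight
   complete graph with a warning.

`compare_early_late()` pairs early and late rows within clusters and
applies the two-sided Wilcoxon signed-rank test per metric: zero
differences dropped, exact distribution (by convolution over sign
patterns, valid with tied ranks) up to 25 pairs, normal approximation
with tie correction and continuity correction beyond, Bonferroni factor
equal to the number of metrics (3).

## Consensus regulons and AUCell

The consensus layer is exact rule-following: a TF survives iff present
in strictly more than `min_run_frac` (0.5) of runs; its high-confidence
targets are genes recurring in strictly more than that fraction of all
runs; the regulon survives iff it keeps at least `min_targets` (5)
targets. "50 of 100 runs" therefore fails and "51 of 100" passes.

The per-run inference backend is pluggable; runs supplied as plain
`list(TF = targets)` objects (e.g. parsed from external tools' output)
are accepted directly. The built-in backend is correlational: on a
bootstrap resample of cells, a gene is a TF's target when its absolute
Spearman correlation exceeds the larger of (a) a permutation-null
quantile and (b) a floor of 0.35. The floor deserves explanation: a
pure null threshold admits every structurally co-expressed gene (birth
order and lineage drive large correlated blocks), which full inference
pipelines remove using motif evidence; the floor is this backend's crude
analogue of that pruning, chosen from the designed separation between
planted-regulon correlations (≈0.5–0.7) and indirect structure. Genes
with zero count variance are never targets — their log-normalised
values track sequencing depth only.

`aucell()` ranks each cell's genes by decreasing expression (ties broken
by a seeded shuffle) and scores a gene set by the area under its
recovery curve within the top `top_fraction = 5%` of ranks, divided by
the maximal area for a set of that size — so a set occupying the top
ranks scores exactly 1, a set entirely below the threshold scores 0, and
scores are comparable across set sizes and invariant to monotone
transforms of expression. The 5% rank window is the scoring tool's
convention. `binarize_auc()` thresholds strictly; its `"auto"` cutoff
fits a two-component 1-D Gaussian mixture by EM (quartile
initialisation, 200 iterations, tolerance 1e-8) and takes the
minimum-density point between the component means, falling back to
mean + 2 sd with a warning when the fit degenerates. The cutoff
procedure is an artifact decision — descriptions of the original
pipeline say only that "a cutoff" was used.

## Pseudotime and temporal TFs

`select_lineage_clusters()` applies three eligibility criteria per
cluster: an allowed neuroblast lineage type (modal over cells); late
dominance, evaluated as the cluster mean l2-normalised late score being
positive and above the early score (the reduction from per-cell rule to
cluster decision is unstated in the source procedure; the mean is used);
and a single DBSCAN sub-region (eps 0.5, minPts 5 — parameters are this
package's choice, none are published for this step) among cells positive
for a mid-temporal marker.

`compute_pseudotime()` is a deliberately transparent stand-in for
principal-graph trajectory tools: a symmetrised kNN graph (k = 15,
doubled with a warning until connected) with Euclidean edge weights, and
pseudotime = Dijkstra geodesic distance from the nearest root cell
(roots = early-marker-positive cells, at 0). Validation is therefore
rank correlation with the generator's true birth time, not equality with
any external tool. Pseudotime is translation-invariant and
scale-equivariant; the percent normalisation
(`(v - min)/(max - min) * 100`, constant input to all-zero with a
warning) cancels the scale, making trajectories comparable across
clusters.

`morans_i_test()` computes the graph autocorrelation
`I = (n/W) Σ w_ij (x_i-x̄)(x_j-x̄) / Σ (x_i-x̄)²` with binary symmetric
kNN weights on log-normalised expression, and one-sided permutation
p-values with the add-one correction
`p = (1 + #{I_perm ≥ I_obs}) / (n_perm + 1)`; q-values are
Benjamini–Hochberg per lineage, and a gene passes at q < 0.05 and
I > 0.1. The default is 999 permutations; the test-suite and acceptance
runs use 199 (and 99 for null-calibration checks), which bounds the
smallest attainable p at 1/200 — ample for a 0.05 threshold at the
problem sizes used. `recurrent_temporal_tfs()` keeps TFs passing in at
least 50% of analysed lineages — inclusive, in deliberate contrast to
the strict ">50%" of the regulon rule; both are implemented exactly as
their sources state them.

## Integration metrics

`lisi()` tunes a per-cell Gaussian kernel bandwidth by bisection (64
iterations, entropy tolerance 1e-5) to a target perplexity of 30 over
the 3×perplexity nearest neighbours, and reports the inverse Simpson
index of the kernel-weighted label distribution — the effective number
of labels near each cell, between 1 and the number of distinct labels.
`adjusted_rand_index()` is the standard pair-counting ARI.
`coverage_correlation()` compares atlas cell counts with anatomical
reference counts per type: depth of coverage is the ratio of totals, and
the correlation is Pearson on log10 counts with a Fisher-z confidence
interval (whether the published comparison used log axes is unstated;
the linear scale is exposed via `log10_scale = FALSE`). Types with zero
anatomical count are excluded with a warning.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic
atlases sized for interactive use: the shared fixture is 4 lineages ×
150 cells × 800 genes; the sexing evaluation uses 5,120 cells; the
morphology comparison uses 40 lineages × 250 cells (the generator's
default cells-per-lineage — the paired fragmentation test needs the
serpentine groups dense enough that annotation noise cannot push them
below the DBSCAN core criterion); consensus-regulon recovery uses 10
bootstrap runs. Every stochastic step — count generation, control-gene
sampling, bootstrap resampling, tie-breaking, permutation tests — is
seeded, and a fixed configuration and seed reproduce an atlas
bit-identically.

## Known limitations

- The generator's marker programs are perfectly exclusive and its
  clusters balanced; real atlases are messier, and the recovery rates
  reported by the tests are upper bounds in that sense.
- The correlation backend is a stand-in: it has no motif evidence, and
  its correlation floor is tuned to this generator's contrast, not to
  real data. Real inference-tool outputs can and should be fed to
  `consensus_regulons()` directly.
- Geodesic pseudotime assumes the trajectory is a single connected
  ribbon in the supplied coordinates; branching lineages would need the
  principal-graph machinery this package intentionally does not
  reimplement.
- LISI values depend on perplexity; comparisons are meaningful only at
  matched settings.
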