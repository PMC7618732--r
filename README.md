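# lineagekit

Single-cell atlases of the *Drosophila* central brain organise along two
developmental axes: **lineage** (the neuroblast hemilineage a neuron comes
from, marked by combinatorial transcription-factor codes) and **birth
order** (early-born *Imp*⁺ versus late-born *dati*⁺ neurons, laid down by
a temporal transcription-factor cascade). `lineagekit` packages the
computational heuristics used to build and interrogate such atlases as
tested, reusable R functions, together with a ground-truth synthetic-atlas
generator so every stage can be validated without any external data.

## What is in the box

| Stage | Functions |
|---|---|
| Synthetic atlas with known truth | `simulation_config()`, `generate_atlas()`, `generate_embedding()`, `spike_doublets()` |
| Droplet QC, doublets, sexing | `filter_droplets()`, `score_doublets_knn()`, `consensus_doublets()`, `annotate_sex()`, `evaluate_sexing()` |
| Module scores and classification | `module_score()`, `score_programs()`, `l2_normalize_scores()`, `classify_by_scores()`, `extrapolate_by_cluster()`, `annotate_birth_order()` |
| Markers and gene universes | `find_markers()`, `select_variable_tfs()`, `expressed_gene_universe()` |
| Cluster morphology | `mean_pairwise_distance()`, `dbscan_points()`, `fragmentation_score()`, `modularity_score()`, `morphology_report()`, `compare_early_late()` |
| Consensus regulons and AUCell | `infer_grn_once()`, `consensus_regulons()`, `aucell()`, `binarize_auc()`, `regulon_markers()` |
| Pseudotime and temporal TFs | `select_lineage_clusters()`, `compute_pseudotime()`, `normalize_pseudotime()`, `morans_i_test()`, `recurrent_temporal_tfs()` |
| Integration evaluation | `lisi()`, `adjusted_rand_index()`, `coverage_correlation()` |

The core statistics, briefly:

- **Module score** of a gene set *S* in cell *c*: mean log-normalised
  expression of *S* minus the mean of expression-matched control genes
  sampled from equal-frequency expression bins. Program scores are
  l2-normalised across cells and a cell is labelled by the positive,
  strictly-maximal program; a score below zero on the two-gene male
  program calls a cell female.
- **Fragmentation score**: the number of non-noise DBSCAN subclusters
  (eps = 0.5, minPts = 5) a cell group forms in a 2-D embedding —
  punctate early-born groups fragment, serpentine late-born continua do
  not. Compared early-vs-late per cluster with a Bonferroni-corrected
  Wilcoxon signed-rank test, alongside mean pairwise distance and
  fast-greedy graph modularity.
- **Consensus regulons**: a TF kept iff present in >50% of repeated
  stochastic network-inference runs with ≥5 targets that each recur in
  >50% of runs; per-cell activity scored with AUCell (normalised area
  under the top-5%-rank recovery curve).
- **Moran's I** over a cell kNN graph with permutation p-values flags
  genes varying along root-anchored, percent-normalised pseudotime;
  temporal TFs recurring in ≥50% of analysed lineages form the shared
  birth-order code.
- **LISI** (local inverse Simpson index) and the **adjusted Rand index**
  quantify batch mixing and clustering agreement.

## Worked example

```r
library(lineagekit)

sim <- generate_atlas(simulation_config(n_lineages = 4,
                                        cells_per_lineage = 150,
                                        seed = 101))
atl <- sim$atlas
atl
#> <atlas> 800 genes x 600 cells (60 TFs, 0 flagged doublets)

# in-silico sexing from the two-gene male program
sx <- annotate_sex(atl, sim$truth$male_genes)
evaluate_sexing(sx$sex_pred, atl$cell_meta$sex, "female")
#> <label_eval> positive = female: precision 0.9810, recall 1.0000

# birth-order annotation and embedding morphology
bo <- annotate_birth_order(atl, sim$truth$early_genes, sim$truth$late_genes)
cells <- dplyr::mutate(atl$cell_meta, birth_class = bo$birth_class)
rep <- morphology_report(cells, eps = 0.5, min_pts = 5)
compare_early_late(rep)
#> # A tibble: 3 x 7
#>   metric            n_pairs statistic p_value p_bonferroni median_early median_late
#>   <chr>               <int>     <dbl>   <dbl>        <dbl>        <dbl>       <dbl>
#> 1 mean_pairwise_di…       4        10  0.125         0.375        5.95         4.49
#> 2 fragmentation           4        10  0.125         0.375        3            2
#> 3 modularity_q            4         0  0.125         0.375        0.103        0.224
```

The precision/recall line says the module-score sexer recovers the
generator's ground-truth sexes almost perfectly. The morphology table
shows the designed geometry: early-born cells scatter over three blobs
(fragmentation 3, larger pairwise spread), late-born cells form an
almost unbroken ribbon. Four clusters are too few for the
signed-rank test to reach significance — the atlas-scale comparison is
run over 40 lineages by the acceptance script below.

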