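# metabotyper

Metabolic typing of cell line panels from multi-batch untargeted
metabolomics.

Large metabolomics screens of cell line panels face two coupled
problems. First, data collected over months in separate growth and
measurement batches carry strong multiplicative artifacts — batch
offsets, injection-order drift, per-sample amount variation — that
must be removed before any biology is read, and competing
normalization methods need an objective benchmark. Second, single
metabolite levels are ambiguous (an increase may mean more flux through
a pathway or a block right after it), so pathway-level summaries are
needed: when flux through a pathway changes, most of its intermediates
shift coherently, and the first principal component of the pathway's
member ions captures exactly that coherent shift.

`metabotyper` implements the full workflow:

* **Injection QC and normalization** — TIC-based outlier filtering;
  sample-variance methods (quantile, log10-mean, median, SD, MAD, TIC,
  PQN, confluency), injection-order drift correction (moving median in
  a 120-min window, loess, robust loess), and an empirical-Bayes
  location/scale batch correction (ComBat, with a QC-only estimation
  mode), composable into ordered stacks.
* **Benchmarking** — five reproducibility criteria computed from
  repeated QC-line injections (resampled fold-change threshold,
  cross-batch fold-change reproducibility on all ions and on amino-acid
  ions, PCA/Bhattacharyya inter-batch distance, Kolmogorov–Smirnov
  batch-effect rate), each scaled so the raw data score 1 and smaller
  is better.
* **Pathway activity scores** — reaction-level curation of overlapping
  pathway definitions, formula-based ion mapping (isomers kept), and
  per-pathway PC1 scores in [−1, 1] with a fixed orientation rule,
  validated against planted fluxes: score s_c = PC1 of the z-scored
  log intensities of the pathway's ions, averaged over replicates and
  scaled by the maximum absolute value.
* **Metabolic typing and association scan** — Ward clustering of score
  profiles; every dendrogram branch holding ≥ 10% of the cohort tested
  against every trait (hypergeometric for categorical, pooled t for
  continuous), all p-values pooled into one global Storey–Tibshirani
  q-value computation with signed q ≤ 0.10 reported.
* **¹³C tracing** — natural-abundance correction by non-negative
  least-squares deconvolution, fractional contributions
  FC = Σ i·mᵢ / n, type-wise fractional differences, lipid class
  totals and unsaturation indices.
* **Enrichment** — hypergeometric tail enrichment of ranked metabolite
  lists, per-gene dependency/drug contrasts, and pre-ranked GSEA with
  1,000 permutations.
* **Synthetic data** — generators that emulate the screen's statistical
  structure (batch design with QC lines everywhere, multiplicative
  artifacts, flux-driven ion levels, two planted metabolic types,
  planted trait associations, binomial-mixture isotopologue vectors),
  so the whole pipeline is testable end to end without any download.

## Worked example

The numbered scripts under `analysis/` run the whole study on
synthetic data and write their tables under `results/`. For instance:

```sh
Rscript analysis/02_normalization_benchmark.R
Rscript analysis/04_typing_association.R
Rscript analysis/05_isotope_tracing.R
```

prints (abridged):

```
stacks ranked by mean scaled criterion:
  quantile+moving_median+combat  mean scaled = 0.269
  quantile+combat                mean scaled = 0.336
  combat                         mean scaled = 0.491
  moving_median                  mean scaled = 0.939
  baseline                       mean scaled = 1.000
  quantile                       mean scaled = 1.330
  ...
top split recovers planted types for 100% of lines
association scan: 5656 tests, 26 significant at 10% FDR (pi0 = 1.00)
planted traits recovered: planted_cat0001, planted_cont0001, ...
glucose tracer: 11/11 TCA metabolites in the bottom half of the ranking
  TCA       bottom k=10/11 q=1.26e-07  (bottom tail = higher labeling in type 2)
  storage   top    k=8/8   q=4.66e-06  (top tail = higher labeling in type 1)
```

Reading this: on a screen with planted 2–3× batch effects and a 2×
injection drift, stacks that include the empirical-Bayes batch
correction improve all five reproducibility criteria (mean scaled
< 1), quantile normalization alone makes replicate fold-changes worse,
and the full sample-variance + drift + batch stack wins. Ward
clustering of the pathway scores recovers the two planted metabolic
types exactly; the association scan flags the planted traits and
nothing else at 10% FDR; and the ¹³C fractional-difference ranking
places the TCA-cycle metabolites in the tail of higher labeling in
type 2, with significant tail enrichment.

A minimal interactive session:

```r
library(metabotyper)
scr  <- simulate_screen(seed = 1)                    # 7-batch screen
norm <- apply_stack(filter_abnormal_tic(scr$table)$table,
                    normalization_stack(
                      list(class = "sample_variance", method = "quantile"),
                      list(class = "batch_effect",    method = "combat")))
sc   <- pathway_score(norm, truth_ion_pathway_map(scr))
tree <- cluster_cell_lines(sc)
cut_types(tree, 2)                                   # the metabolic types
```

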