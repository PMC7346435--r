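# orthoquant

Cross-species comparison of RNA-seq expression profiles through
orthology-aware quantile mapping.

## The problem

Model organisms are justified by conservation, but conservation at the
sequence level does not guarantee conservation at the expression
level. Given gene-level TPM matrices for the same cell type in two
species (the motivating case: human and zebrafish metaphase-II
oocytes, three single-cell replicates per dataset) and a many-to-many
ortholog table with binary confidence flags, orthoquant asks whether
orthologous genes occupy similar *relative* expression positions in
the two transcriptomes — a rank-based question that sidesteps
cross-species normalization entirely.

## The method

- **Expression calls.** A gene is *expressed* when TPM > 1 in every
  replicate; *highly expressed* when its per-replicate z-score of log2
  TPM (computed over expressed genes) exceeds 1.5 in at least 2 of 3
  replicates.
- **Quantile mapping.** Each dataset's expressed genes are split into
  expression deciles Q1 (top 10%) … Q10. High-confidence ortholog
  pairs expressed in both datasets are cross-tabulated into a 10 × 10
  grid by (row-species decile, column-species decile); two margin
  rows/columns hold genes whose orthologs are unexpressed on the other
  side and genes with no high-confidence ortholog.
- **Region enrichment.** For a region R of the grid, a 2 × 2 Fisher
  exact test of row-membership × column-membership over the N mapped
  pairs, with the uniform expectation N·|rows|·|cols|/100 reported
  alongside.
- **Highly concordant orthologous genes.** Row-side genes of the top
  3 × 3 corner (top 30% in both species), intersected across the human
  datasets and ranked by grand-mean TPM over all nine samples
  (ortholog TPMs stand in for the zebrafish samples).
- **Sample similarity.** Row-normalized UPGMA clustering with
  Pearson-correlation distance 1 − r, PCA, and ANOSIM / adonis
  (PERMANOVA) permutation tests on PC-space Euclidean distances, with
  exact label enumeration for small designs.
- **EASE over-representation.** Fisher's one-sided test with one hit
  removed (the EASE score), Bonferroni correction reported alongside,
  significance at EASE ≤ 0.05.
- **Synthetic studies.** A generator with a Gaussian-copula coupling
  between species (`concordance_rho`), calibrated zero / below-1-TPM
  fractions, compositional renormalization to 10⁶, and recorded ground
  truth, so the whole pipeline is testable offline.

## Worked example

```r
library(orthoquant)

study <- simulate_study(sim_config(seed = 42, n_genes_a = 8000,
                                   n_genes_b = 8600))
calls <- lapply(study$datasets, expression_calls)
calls$H1
#> <expression_calls> H1: 944 expressed, 83 highly expressed
calls$ZF
#> <expression_calls> ZF: 3074 expressed, 260 highly expressed

qa <- lapply(calls, assign_quantiles, n_quantiles = 10)
qm <- build_quantile_mapping(qa$H1, qa$ZF, study$orthology)
qm
#> <quantile_mapping> H1 (rows) vs ZF (cols), cross-species mode: 297 ortholog pairs in the 10x10 grid

region_enrichment(qm, rows = 1:3, cols = 1:3)
#> <region_enrichment> rows {1,2,3} x cols {1,2,3}: observed 69, expected 26.73, OR 1.92, p = 0.0104
```

Of the 297 ortholog pairs expressed in both datasets, 69 sit in the
top-30%-by-top-30% corner where a uniform spread would put ~27 — the
concordance signal the generator planted (`concordance_rho = 0.7`,
boosted among top-expressed genes) recovered as corner enrichment.

```r
sets <- list(
  H1 = top_region_genes(build_quantile_mapping(qa$H1, qa$ZF, study$orthology), 3),
  H2 = top_region_genes(build_quantile_mapping(qa$H2, qa$ZF, study$orthology), 3))
conc <- intersect_and_rank(sets, study$datasets, om = study$orthology,
                           species = "speciesA")
conc
#> <concordance_result> 43 concordant gene(s) across 2 set(s) (63% of the smallest set)
#>   rank    gene    avg_tpm multi_ortholog
#> 1    1 GA00285 132433.842          FALSE
#> 2    2 GA04624  59290.597          FALSE
#> 3    3 GA07520  35864.046          FALSE
#> 4    4 GA07649  23312.941          FALSE
#> 5    5 GA05997   9597.332          FALSE
```

The 43 genes in the top corner against zebrafish in *both* human-like
datasets are the "highly concordant orthologous genes", ranked by
average TPM across all nine samples.

The whole workflow (calls → maps → enrichment → concordance →
similarity → over-representation), with per-stage TSV outputs and a
checksummed `MANIFEST.yaml`, runs from one config:

```r
run_pipeline(list(output_dir = "run",
                  simulate = list(seed = 42),
                  parameters = list(seed = 42)))
```

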