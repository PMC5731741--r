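# fgmd: overlapping functional gene modules from co-expression

Genes that are co-expressed across samples tend to be co-regulated — by the
same transcription factors, microRNAs or copy-number events — and to act in
the same pathways. Most module-detection methods (hierarchical clustering,
k-means, WGCNA) partition the gene universe, forcing each gene into exactly
one module, although a single gene is often involved in several biological
functions. `fgmd` implements the FGMD algorithm, a seed-and-extend strategy
that detects *overlapping* co-expression modules from a genes × samples
expression matrix, plus the validation battery used to judge them. It is
aimed at computational biologists analysing tumor expression profiles
(microarray or RNA-Seq, gene- or isoform-level), and at anyone who needs
overlapping correlation modules with statistical quality control.

## The algorithm

With `a_ij = |corr(x_i, x_j)|` the absolute Pearson correlation between
gene rows:

1. **Seed pairs** — gene pairs in the top `S`% of `a_ij` values (default
   0.005%) form a seed network; genes whose seed degree is below `D_min = 5`
   or above `D_max` (the degree at the top-0.1% rank) are filtered out.
2. **Greedy expansion** — each seed pair grows into an SPE module: a
   candidate gene's fit is its *minimum* correlation to current members
   (`P_min`); candidates with `P_min > M` (the top-1% pair quantile) are
   eligible and the `k = 10` best join per iteration, until none is
   eligible. Seed pairs expand independently, so modules can share genes.
3. **Merging** — SPE modules are clustered on Jaccard-overlap dissimilarity
   (`1 − |m1∩m2|/|m1∪m2|`) with average linkage and an adaptive dynamic
   tree cut; each cluster's gene union is a *large module*.
4. **Splitting** — each large module is re-clustered on `1 − a_ij` and cut
   again; the resulting clusters are the final modules (disjoint within one
   large module, overlapping across large modules). An optional extension
   step re-introduces overlap within a large module by adding parent genes
   while the module's mean in-module correlation improves.

Validation: a permutation test of module coherence (mean in-module `|PCC|`
vs `N = 1000` random same-size gene sets, Bonferroni-corrected),
hypergeometric gene-set enrichment with Benjamini–Hochberg correction
(GMT collections, set sizes 3–300), gene-list ratio statistics, and
weighted-network statistics (connectivity, density, centralization,
heterogeneity). A planted-block synthetic generator makes the whole
pipeline testable without any external data.

See `vignettes/fgmd-methods.Rmd` for the model, parameter meanings and
design decisions.

## Worked example

Plant five correlated blocks (40 genes each, within-block r = 0.8, two
blocks sharing 10 genes) in a 600-gene × 80-sample noise matrix, then run
the pipeline with parameters scaled to that size:

```r
library(fgmd)

blocks <- default_planted_blocks()                 # 5 blocks, 10 shared genes
expr   <- generate_block_expression(600, 80, blocks, seed = 1)

cfg <- pipeline_config(S = 0.5, D_min = 3, k = 10, M_percent = 2,
                       minModuleSize = 15, permutation_N = 1000, seed = 1)
res <- run_pipeline(expr, cfg)
#> [fgmd] correlating 600 features over 80 samples
#> [fgmd] step 1: 857 seed pairs over 125 genes (threshold 0.8154)
#> [fgmd] step 2: 857 SPE modules (mean size 38.1, M 0.6171)
#> [fgmd] step 3: 8 large modules
#> [fgmd] step 4: 8 final modules
#> [fgmd] size filter [10, 300]: 8 modules retained
#> [fgmd] permutation test: 8 of 8 modules significant (Bonferroni q < 0.05)

planted_recovery_score(res$final, blocks)
#> block_1 block_2 block_3 block_4 block_5
#>    1.00    1.00    0.95    0.75    0.98

res$summary
#>   n_modules mean_size unique_genes duplication_ratio mean_occurrence mean_in_module_pcc
#> 1         8      37.1          189             0.125            1.57              0.767
```

Reading the output: 857 of the ~179,700 gene pairs pass the top-0.5%
correlation threshold (realized value 0.815) and the degree filter; each
becomes an SPE module of ~38 genes; overlap merging collapses the 857 SPE
modules to 8 large modules, and splitting yields 8 final modules. Every
planted block is recovered with best-match Jaccard ≥ 0.75, the mean
occurrence of 1.57 modules per gene reflects the overlap between final
modules, and all modules beat 1,000 random same-size gene sets in
coherence (mean in-module |PCC| 0.767).

`run_pipeline` also accepts a TSV path (header of sample ids, one feature
per line), writes per-stage TSV exports and a JSON manifest when `out_dir`
is set, and is fully deterministic given the seed. A command-line wrapper
with `simulate`, `preprocess`, `seeds`, `expand`, `merge`, `split`,
`extend`, `validate` and `run-all` subcommands lives at
`inst/cli/fgmd.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","fgmd.R",package="fgmd"))')" \
    run-all in=expr.tsv out_dir=run1 S=0.5 D_min=3 M_percent=2 seed=1
```

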