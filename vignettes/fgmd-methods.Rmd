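---
title: "Detecting overlapping co-expression modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting overlapping co-expression modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmd)
```

## The problem

Genes that are co-expressed across tumor samples tend to be co-regulated and
to act in the same pathways, so a natural unit of analysis is the
*functional gene module*: a set of genes whose pairwise expression
correlation is high. Classical approaches — hierarchical clustering of a
correlation dissimilarity, k-means, WGCNA — partition the gene universe, so
each gene belongs to exactly one module. That contradicts a basic biological
observation: one gene frequently participates in several functions or
pathways. This package implements FGMD (functional gene module detection), a
seed-and-extend strategy that produces *overlapping* modules, together with
the validation battery used to judge module quality.

## The model and the four stages

Throughout, the similarity between genes $i$ and $j$ is the absolute Pearson
correlation of their expression rows, $a_{ij} = |corr(x_i, x_j)|$, and all
quantile parameters are expressed in "top percent of pairs" units (0.005
means the top 0.005% of all unordered gene pairs).

**Step 1 — seed gene pairs.** Pairs in the top $S$% of $a_{ij}$ values
(default $S = 0.005$) form a seed network. A gene's degree there is its
number of seed partners. Genes with degree below $D_{min} = 5$ would grow
undersized modules; genes above $D_{max}$ — the degree found at the
top-0.1% rank of the degree distribution — are promiscuous hubs that would
generate many near-identical modules. Both are removed, in a single pass on
the degrees of the unfiltered network, so a gene survives on its own
original degree even if its partner is removed. (An iterative variant that
re-evaluates degrees to a fixed point is available behind the `iterate`
flag.) The ranking universe for $D_{max}$ is the set of genes with non-zero
seed degree; ranking over the full universe is available via
`rank_over_all`.

**Step 2 — greedy expansion.** Each seed pair grows into an SPE
(seed-pair expansion) module. A candidate gene's similarity to the module is
its weakest link $P_{min}$, the minimum $a$ to any current member. Genes
with $P_{min}$ strictly greater than the module threshold $M$ (the top-1%
pair quantile by default) are eligible, and the $k = 10$ candidates with the
largest $P_{min}$ join simultaneously; iteration continues until no gene is
eligible. Because each seed pair expands independently, one gene can be
claimed by many modules — this is where overlap enters. Two authored
decisions: candidates tied with the $k$-th $P_{min}$ value are all admitted
(the result cannot depend on internal ordering), and the degree constraint
on candidates is an upper bound only — genes whose degree in the
$M$-thresholded correlation graph exceeds the top-0.1% degree value are
excluded from candidacy, since only the upper bound serves the stated goal
of limiting redundancy. A ceiling of 1,000 iterations guards termination;
the greedy loop provably adds at least one gene per iteration, so reaching
the ceiling is reported as an error.

**Step 3 — merging.** SPE modules grown from seeds inside the same
structure are nearly identical. Their pairwise overlap is measured by the
Jaccard index $|m_1 \cap m_2| / |m_1 \cup m_2|$; average-linkage
hierarchical clustering on $1 - $ overlap, cut with the dynamic tree cut
(below, `minModuleSize = 50`, `maxTreeHeight = 1`, `deepSplit = TRUE` by
default), groups them, and each cluster's gene union becomes a *large
module*. The linkage method is a package choice (the convention of the
dynamic-cut methodology); complete and single linkage are configurable.
SPE modules left unassigned by the cut become singleton large modules,
flagged in the provenance, rather than being discarded silently. With
Jaccard dissimilarities bounded by 1, the default height cap of 1 is
vacuous at this step; the parameter is retained for generality.

**Step 4 — splitting.** Each large module is re-clustered at the gene level
with dissimilarity $1 - a_{ij}$ (the absolute-correlation form; a signed
variant is available) and cut again. The resulting clusters are the final
modules. Genes the cut leaves unassigned are dropped — the size filter
removes fragments anyway — so final modules from one large module are
disjoint, while modules from *different* large modules can share genes.
Module-size bounds of 10–300 genes (10–500 for isoform-level features) are
applied last.

**Overlap extension (optional).** Splitting removes overlap within one
large module. The extension restores it: for each final module, the parent
gene with the highest mean correlation to the members is added repeatedly,
as long as the module's mean in-module correlation strictly improves. The
procedure can add at most $|parent|$ genes and never decreases coherence.

## The dynamic tree cut

The reference dynamic-cut methodology adaptively chooses cluster boundaries
in a dendrogram instead of one global cut height. This package implements
that contract with an explicit, documented procedure:

1. The tree is cut statically at `maxTreeHeight`; merges above the cap never
   join clusters.
2. Inside each branch of at least `minModuleSize` leaves, every internal
   merge height is a candidate cut. A candidate is *admissible* only when
   the next merge above it is separated by at least 5% (`deepSplit = TRUE`)
   or 25% (`deepSplit = FALSE`) of the dissimilarity scale — the height cap,
   or the tree top if lower. This bars jitter-level height differences
   inside a homogeneous branch from being read as structure.
3. Among admissible cuts, the one producing the most clusters of size
   $\ge$ `minModuleSize` wins; ties go to the cut assigning more leaves,
   then to the lower cut. Leaves in undersized fragments at the chosen cut
   are unassigned (label 0), which is what makes the procedure robust to
   outlying leaves.

Clusters are numbered by decreasing size, so the labelling — not just the
partition — is invariant to the input item order. On dissimilarity matrices
with clearly separated groups the procedure provably recovers the group
partition, which is how it is validated in the test suite (against an
independent connected-components oracle).

## Validation battery

* **Permutation coherence test.** A module's coherence is its mean
  in-module $a_{ij}$ over unordered pairs. $N = 1000$ random gene sets of
  the same size are drawn uniformly from the universe (without replacement
  within a draw); the p-value is the fraction of random sets whose coherence
  beats the module's. P-values are Bonferroni-corrected across the tested
  modules. Random sets do not exclude the module's own genes; for module
  sizes far below the universe this bias is negligible.
* **Hypergeometric enrichment.** For each module and gene-set term,
  $p = P(X \ge \mathrm{overlap})$ under the hypergeometric law with the
  dataset's gene count as the population. Terms are restricted to the
  analysis universe and filtered to 3–300 surviving members. Adjustment is
  Benjamini–Hochberg per module within one collection (a global mode is
  available); a module is called enriched when any term has $q < 0.05$.
* **Gene-list ratios.** Pooled (per-membership) and unique (per-distinct-
  gene) fractions of an external list, e.g. known cancer genes.
* **Network statistics.** Connectivity $k_i = \sum_{j \ne i} a_{ij}$,
  per-gene coefficient of variation of connection strengths, density
  $\sum_{i \ne j} a_{ij} / (n(n-1))$ (diagonal excluded), centralization
  $\max(k)/n - $ density (implemented exactly in this form, which can be
  negative; a normalized variant is behind a flag), and heterogeneity
  $\sqrt{\mathrm{var}(k)}/\mathrm{mean}(k)$ with the population
  (divide-by-$n$) variance, for determinism and consistency with the
  standard definition.

The "ratio of module duplication" summary statistic is defined here as
(module count − distinct member-set count) / module count; this definition
is a package choice, exposed under an explicit name.

## The synthetic generator

`generate_block_expression()` plants correlated blocks in Gaussian noise:
each block has a latent sample factor and a member gene is
$\sqrt{r} f_b + \sqrt{1-r}\,\epsilon$, giving within-block correlation $r$;
genes in several blocks sum their blocks' loadings and are renormalized to
unit variance. Gaussian factors and noise were chosen because the intended
real inputs are log-ratio expression values, which are approximately
continuous and symmetric; heavy-tailed noise is a possible extension. Block
overlap via shared genes mirrors the premise that one gene serves several
functions.

The reference study configuration (`default_planted_blocks()`) is 5 blocks
of 40 genes at $r = 0.8$ in a 600-gene universe observed over 80 samples,
with the last two blocks sharing 10 genes, analysed with parameters scaled
to that size: seed quantile top 0.5%, $D_{min} = 3$, $k = 10$, module
threshold top 2%, `minModuleSize = 15`. These sizes keep the full pipeline,
the 1,000-draw permutation battery and the 500-replicate calibration of the
test suite within a few minutes on one CPU.

What the generator does *not* emulate: count noise (negative-binomial
RNA-Seq behavior), platform batch effects, heavy-tailed expression,
isoform-from-gene structure, and realistic pathway-sized gene sets. Passing
tests on this generator therefore demonstrate the algorithmic contract —
recovery of genuinely correlated, possibly overlapping structure — not
robustness to every artefact of real data.

## Numerical choices and degenerate inputs

* Quantile thresholds use `ceiling(P * top_percent / 100)` over unordered
  pairs; pairs tied exactly at the threshold are all admitted.
* $P_{min}$ comparisons use strict `>` against $M$.
* Zero replacement uses the global matrix minimum positive value (the
  per-row variant is a flag); an all-zero matrix is an error.
* Constant-expression genes have no defined correlation: strict mode
  errors, permissive mode drops them with a warning.
* An empty seed network is a warning (there is simply nothing to expand);
  the pipeline aborts with a stage-named error.
* A large module smaller than `minModuleSize` is returned unsplit and
  flagged; a cut finding no valid sub-cluster likewise keeps the module
  whole.
* Mean-expression ties at the low-expression filter boundary keep the
  lexicographically smaller gene id, for determinism.

## Known limitations

With few samples, a planted block's *realized* coherence wanders
substantially around its target $r$ (the block factor's sample variance is
itself random). Because seeds are taken from a single global correlation
quantile, a block whose realized coherence falls below the global threshold
contributes no seeds and is invisible to the pipeline — at 80 samples and
five blocks this happens in a minority of random draws. More samples, or a
larger $S$, make seeding robust. This is a property of global-quantile
seeding itself, not of the implementation.

The expansion stage is the complexity bottleneck: every seed pair is
expanded independently ($O(\mathrm{pairs} \times n)$ per iteration).
Results are identical to sequential execution by construction, so callers
may parallelize over seed pairs if needed.
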