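# hichipr

Desk-scale, fully tested analysis of HiChIP-style chromatin-interaction
data in R.

Protein-directed proximity-ligation assays (HiChIP and its
phosphorylated-linker and spike-in variants) produce *loops*: pairs of
genomic anchors supported by paired-end tags (PETs) and a significance
q-value. Making biology out of those loops takes a stack of small,
error-prone computations — spike-in scaling, restriction-fragment
bookkeeping, priority-ordered functional annotation, anchor-level overlap
between factors, motif scanning, network reconstruction and signal
statistics — that usually live in one-off scripts. `hichipr` packages that
stack as composable, documented functions over plain data frames, together
with a synthetic-data generator that plants known truth into every input so
the whole pipeline can be verified end to end without any sequencing data.

## What it computes

* **Spike-in (reference-exogenous) normalization.** For samples with counts
  `c_i` mapping exclusively to the primary genome and `s_i` to the spike
  genome, each sample is scaled by `f_i = min_j(s_j) / s_i`, so normalized
  signal is `c_i · f_i`. Applies to ChIP-Rx reads and to valid HiChIP PETs
  (spike PETs removed from the primary set first).
* **In-silico digestion and PET classification.** Fragments from exact
  GATC (DpnII) occurrences; linker-junction trimming that keeps the
  fragment-terminal GATC; classification of read pairs into
  valid / dangling-end / self-circle / re-ligation / single-end from the
  fragment-and-strand geometry.
* **Loop filtering and annotation.** Loops kept at `q ≤ 0.01`; each anchor
  gets the first matching class in the fixed priority order *enhancer >
  promoter > TES > gene body > tRNA > rRNA > miRNA > snRNA > snoRNA > SINE >
  LINE > LTR > satellite* (≥ 1 bp overlap), with derived tracks: promoter =
  TSS ± 0.5 kb, TES window = TES ± 0.3 kb, enhancer = H3K4me1 ∩ H3K27ac
  sites without H3K4me3.
* **Loop-set overlap** with bedtools-pairtopair semantics (`either` /
  `both`, self-hits excluded, strand ignored) and A-centred Venn summaries
  (`one = either − both`).
* **PWM motif scanning with exact p-values** (dynamic programming over a
  discretized score grid, verified against full `4^w` enumeration),
  per-anchor dedup and E-box > B-box > A-box priority labelling.
* **Promoter-hub networks.** Anchors as nodes (exact-coordinate identity),
  loops as PET-weighted edges, clusters as connected components with
  promoter/enhancer node counts, Wilcoxon comparison of cluster sizes, and
  hypergeometric gene-set over-representation with BH correction.
* **Signal metrics.** Strand-aware windowed counting, metagene densities
  (mean ± SEM), equal-size binning, reference-median normalization,
  binding-per-interaction ratios, Welch-t / exact rank-sum comparisons.

## Worked example

```r
library(hichipr)

# spike-in scaling of a two-sample batch
counts <- data.frame(sample_id = c("ctrl", "treat"),
                     primary = c(1000, 800), spike = c(200, 100))
chiprx_factors(counts)
#>   sample_id primary spike factor normalized
#> 1      ctrl    1000   200    0.5        500
#> 2     treat     800   100    1.0        800
```

The `treat` sample has the smallest spike library and keeps its raw count;
`ctrl` is scaled down by 100/200 = 0.5.

```r
# a full synthetic study: genome-free annotation + loops with planted truth
spec    <- synthetic_spec(seed = 5)
ann     <- generate_annotations(spec)
gl      <- generate_loops(spec, ann)
catalog <- derive_catalog(ann$genes, ann$repeats, ann$histone)
loops   <- annotate_loops(filter_loops(gl$loops, q_max = 0.01), catalog)
#> [filter] q <= 0.01: 506 in, 46 dropped
classify_loops(loops)
#>              loop_class count percent
#> 4     promoter-promoter   130      28
#> 2 intergenic-intergenic   125      27
#> 3    promoter-gene_body    78      17
#> 5         promoter-SINE    75      16
#> 1     enhancer-promoter    52      11
```

The 46 dropped loops are exactly the planted decoys (q-values drawn above
0.01), and the recovered class composition matches the generator's planted
fractions (0.28 / 0.19 / 0.14 / 0.10, remainder intergenic) up to
multinomial sampling noise at n = 460. From here,
`build_graph(loops)` and `clusters()` reconstruct the interaction network
and report per-cluster node, promoter and enhancer counts, and
`hub_gene_enrichment()` tests hub genes against gene sets.

A thin command-line dispatcher mirrors the stages
(`generate`, `extract-pets`, `normalize`, `annotate`, `overlap`, `motifs`,
`hubs`, `signal`):

```sh
Rscript inst/cli/hichipr.R generate --out work/gen --seed 2
Rscript inst/cli/hichipr.R annotate --dir work/gen --loops work/gen/loops.tsv --out work/ann
```

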