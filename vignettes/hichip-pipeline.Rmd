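---
title: "Analysing HiChIP loop data with hichipr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing HiChIP loop data with hichipr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hichipr)
```

# Scope and model

`hichipr` implements the downstream analysis of protein-directed
chromatin-interaction experiments (HiChIP-style assays and their spike-in
variants). The inputs are the standard products of an upstream
alignment/loop-calling stack: called loops in mango-style tables (two
anchors, a PET count, p- and q-values), BED annotation tracks, coverage
tracks, and per-sample read-count tables. Alignment and peak calling are out
of scope by design: peaks and loops are inputs, and the read-level module
works on synthetic reads whose mapping positions are known by construction.

A *loop* is an unordered pair of genomic anchors supported by `pet`
paired-end tags and a significance q-value. Anchors are canonicalized so
that `(chromA, startA) <= (chromB, startB)` under natural chromosome order;
every operation downstream is invariant to the input anchor order. All
coordinates are 0-based half-open (BED convention) in every container and
file the package touches; conversions to the 1-based IRanges machinery
happen only inside overlap computations. This single-convention rule
eliminates the usual off-by-one class of bugs and is exercised by round-trip
tests on every reader/writer pair.

# Restriction fragments and PET classification

`digest_genome()` cuts at each exact occurrence of the recognition site
(GATC, the DpnII site, by default). Fragments tile each chromosome exactly;
a chromosome without sites is one fragment. `trim_linker()` implements
ligation-junction trimming: if either chimeric linker-junction string
(`GATCAGATTTGGGGATC` / `GATCCCCAAATCTGATC`) occurs in a read, the read is
truncated at the earliest occurrence *plus four bases*, retaining the
fragment-terminal GATC. Keeping the terminal GATC preserves the mappable
fragment end; this choice is a documented design decision, as upstream
pipelines differ in whether the motif half is retained.

A read pair becomes a PET classified by the fragment geometry of its two
ends:

* different, non-adjacent fragments — `valid`;
* same fragment, inward-facing strands — `dangling_end`;
* same fragment, outward-facing — `self_circle`;
* adjacent fragments (`|iA - iB| = 1`, same chromosome) — `re_ligation`;
* missing mate — `single_end`; same fragment with equal strands —
  `unassigned`.

Re-ligation counts as invalid, mirroring standard Hi-C quality control.
Classification is a total, symmetric function of the two ends, which is
tested as a property. Duplicates (identical coordinates and strands) are
*retained* in both processing modes; multi-mapped records are removed only
in IP (`plhichip`) mode — the duplicate tolerance reflects the low-input
character of the assay. No aligner is invoked: ends are placed by positional
lookup of the synthetic truth, because exclusive mapping, not alignment
accuracy, is the property every downstream formula consumes.

# Spike-in normalization

For a batch of samples with counts of reads (or valid PETs) mapping
exclusively to the primary and to the spike genome, the scale factor of
sample *i* is

$$f_i = \frac{\min_j s_j}{s_i}, \qquad \tilde{c}_i = c_i \, f_i$$

where $c_i$ and $s_i$ are the primary and spike counts. The sample with the
smallest spike library keeps its raw counts; everyone else is scaled down.
Two properties pin the formula: between-sample ratios of normalized counts
equal ratios of $c_i/s_i$ exactly, and multiplying every count by a common
constant scales all normalized values by that constant. The minimum is taken
over the sample group passed in one call (an experiment batch), matching
per-figure normalization practice. For HiChIP PET counts, spike PETs are
removed from the primary set before counting. Scaled coverage tracks are
consumed by the density module with no further per-sample normalization.

# Loop filtering and priority annotation

Loops are kept at `q <= 0.01` (inclusive). Each anchor receives exactly one
functional class: the first class in the fixed priority order

> enhancer, promoter, TES, gene body, tRNA, rRNA, miRNA, snRNA, snoRNA,
> SINE, LINE, LTR, satellite

whose interval set overlaps the anchor by at least 1 bp (the bedtools
default minimum, since no other threshold is stated); anchors matching
nothing are `intergenic`, a label the figures imply but do not name.
Derived tracks: promoters are TSS ± 0.5 kb and TES windows TES ± 0.3 kb
(strand-aware: a minus-strand gene's TSS is its right end); gene bodies are
the union of exons and introns, i.e. the gene span; enhancers are the
H3K4me1/H3K27ac co-marked sites that do not overlap any H3K4me3 peak. The
exclusion is site-level — a co-marked site touching H3K4me3 is removed as a
whole rather than trimmed — because the defining rule speaks of
*overlapping sites without* the promoter mark. Class percentages are
reported as integers, rounded half away from zero, matching the printed
style of loop-composition bar charts (1277 of 4591 prints as 28%).

# Loop-set overlap

`pair_to_pair()` reproduces bedtools-pairtopair semantics: under `either` a
loop pair matches when at least one anchor of *a* overlaps an anchor of
*b*; under `both`, when the two anchors match the two anchors in one of the
two pairing orientations. Strand is ignored and self-hits are excluded by
record identity (distinct records with identical coordinates still match,
mirroring bedtools' `-is`). The Venn summary counts at loop level — an
A-loop is counted once however many B-loops it matches — with
`one = either - both`; the report is A-centred and deliberately asymmetric.
A quadratic brute-force oracle over all pairs and all four anchor pairings
backs the implementation in the test suite. One published description of
the overlap options is internally inconsistent (it pairs "both anchors"
with the `either` type); the implementation follows the bedtools semantics
of the option names.

# Motif scanning with exact p-values

Anchor sequences are scanned on both strands with position weight matrices
against an order-0 background fitted from the input sequences
(strand-symmetrized, with a pseudocount; the symmetrized fit is the default
of the standard background tools, and `symmetrize = FALSE` is available for
single-strand compositions). Scores are $\sum_j \log_2
(p_{\mathrm{motif}}/p_{\mathrm{bg}})$ with a FIMO-style
background-proportional pseudocount of 0.1. The p-value of a score is the
exact probability that a random background word scores at least as high,
computed by dynamic programming over positions on a discretized score grid
(0.001-bit bins). The binned score of any word deviates from its true score
by at most $w \cdot \mathrm{bin}/2$, so the DP tail probability is bracketed
by the exact tails at $\pm w \cdot \mathrm{bin}$; the tests verify this
bound against full $4^w$ enumeration for $w \le 8$. Hits are kept at
`p <= 1e-4`; per anchor and motif only the lowest-p hit survives, and the
anchor label is the highest-priority motif present (E-box over B-box over
A-box — priority beats p-value). The shipped PWMs are consensus-anchored
synthetic stand-ins (CACGTG-centred E-box with weak flanks; GTTCGAANNC
B-box; TRGCNNARYNNG A-box), labelled synthetic in the fixture file: curated
database matrices are inputs, not package content. Note that a short strong
word cannot beat the threshold whatever its match: for $w = 6$ the best
achievable p-value is about $2.4 \times 10^{-4}$ under a uniform
background, which is why the stand-ins carry realistic widths of 10-12.

# Hub networks

Anchors become nodes merged by exact coordinate identity (loop callers emit
shared anchor coordinates by construction; a fuzzy merge is deliberately
not applied since no merge radius is defined anywhere). Loops become edges
weighted by PET count, parallel edges merging with summed weight. Clusters
are the connected components of this graph — the package treats the
published "cluster membership" as componenthood, the simplest reading
consistent with quantifying nodes per cluster; a community-detection
alternative would be a strict refinement and is intentionally not
implemented. Per cluster the module reports node, promoter-node and
enhancer-node counts and total PET weight. Promoter nodes map to genes by
the promoter window containing the anchor midpoint, ties broken by nearest
TSS (the gene-assignment rule is not specified upstream; this one is
deterministic and local). Gene-set over-representation is an upper-tail
hypergeometric test with Benjamini-Hochberg correction at `q <= 0.05`;
duplicate gene symbols are merged beforehand, carrying the median of their
PET counts. Cluster-size comparisons use the two-sided Wilcoxon rank-sum
test, exact for small tie-free samples; in the approximate branch no
continuity correction is applied so that identical size multisets give
exactly p = 1.

# Signal metrics

`count_in_window()` counts reads overlapping strand-aware gene windows
(TSS ± w, TES ± w, or TSS→TSS+w into the gene) by at least 1 bp, once each.
`metagene_density()` averages a pre-scaled coverage track over a gene set
on a fixed grid (default TSS ± 2 kb), flipping minus-strand genes, and
reports per-bin mean ± standard error (SD with the $n-1$ denominator over
genes). `bin_average()` sorts records and forms consecutive equal-size bins
with the remainder in the last bin (14,085 records at 150 per bin give 94
bins, the last holding 135). `normalize_to_reference()` divides by the
reference group's median, mapping that median to 1.
`binding_per_interaction()` is the global sum-ratio of spike-normalized
reads to interaction counts over a shared window set by default, with a
per-window mode exposed because either reading of the published ratio is
defensible. Group comparisons are Welch's t-test or the exact rank-sum
test; a degenerate-variance t-test falls back to the rank test rather than
erroring.

# The synthetic-data generator

Every pipeline input can be generated with known planted truth, and the
defaults define the study conditions at one tenth of the real study's
scale, keeping a full run interactive: a 13.5 Mb three-chromosome toy
genome plus a 200 kb spike chromosome, 1,470 genes, 460 loops with class
fractions promoter–promoter 0.28, promoter–gene body 0.19, promoter–SINE
0.14, promoter–enhancer 0.10 and the remainder intergenic–intergenic
(mirroring the published composition of 4,591 loops; the mixed
"promoter/gene-body to enhancer" tenth is realized as promoter–enhancer),
expression strata of 1,470/61/92 genes (one tenth of 14,704/613/921), and a
5% spike fraction representing the 1:20 spike cell ratio. PET counts are
geometric on {1, 2, ...} with mean 4 — the upstream PET-count distribution
is not characterized anywhere, so the geometric is an explicit stand-in.
True loops draw q-values uniformly from (0, 0.01], decoys from (0.01, 1],
making the q-filter's behaviour exactly predictable. Hubs are planted as
random trees (or paths) over dedicated promoter and enhancer anchors on one
chromosome; hub anchors are never reused for background loops, and
background anchors are drawn without replacement while the pools last, so
background components stay small by construction.

Anchors of each planted class are sub-intervals guaranteed to annotate as
that class and nothing higher-priority, which is what makes the end-to-end
identity suite exact: on noise-free settings every planted truth — loop
class, decoy status, hub membership, read validity class, junction offset —
is recovered perfectly by the corresponding module, and that identity is
asserted in the tests. What the generator does *not* emulate: polymer
physics of chromatin contact frequency, sequencing errors beyond none, GC
bias, ambiguous mapping (spike-ness is a label, not a competitive
alignment), and realistic repeat sequence content (repeat tracks are
coordinates, not sequence families). Passing tests therefore demonstrate
algorithmic correctness on data with the stated statistical structure, not
robustness to the noise of real libraries.

Generation is deterministic: identical spec and seed give byte-identical
outputs, each generator consuming an independent sub-seed derived from the
master seed.

# Numerical choices and degenerate inputs

* Rounding of printed percentages: half away from zero, to integers.
* Motif DP discretization: 0.001-bit bins; the error bound above is tested
  against enumeration.
* Rank-sum tests: exact when tie-free and small; otherwise normal
  approximation with tie correction and no continuity correction; complete
  ties yield p = 1.
* Empty inputs: empty loop sets write empty files and produce empty (not
  failing) tabulations; a sequence shorter than a motif yields no hits; a
  chromosome without restriction sites is a single fragment.
* Windows clipped at chromosome bounds are logged, not errors.
* bedGraph output requires disjoint spans and errors otherwise.

# Problem sizes

The test suite runs the generators at reduced scale (two 0.6 Mb
chromosomes, 80 genes, ~100 loops; reads at a few hundred PETs over a 100 kb
chromosome), chosen so the whole suite completes in well under a minute
while every planted-truth recovery remains exact. The end-to-end
composition check uses 2,000 loops at the default genome scale; the
planted-hub reconstruction uses a 3.8 Mb two-chromosome genome with 300
genes, one 44-node hub and 60 background loops. These sizes are the
package's own desk-scale choices for fast, deterministic verification.

# Known limitations

* Connected components stand in for cluster membership (see above); no
  community detection is offered yet.
* The background model for motif p-values is order-0; higher-order Markov
  backgrounds are not implemented.
* No statistical significance is attached to loop-set overlaps (no
  permutation null is defined for them upstream).
* The CLI is a thin dispatcher over the package functions; orchestration
  beyond one stage per invocation (pipelines, resumption) is left to the
  caller.
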