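---
title: "Methods: k-mer sub-region similarity, lineage tracing and copy-number analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer sub-region similarity, lineage tracing and copy-number analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpaint)
```

## The problem

Phylogenetic trees assume that a genome has a single, linear line of
descent. Hybrids, introgressed genomes and domesticated lineages violate
that assumption: different chromosomal segments can descend from different
populations. The motivating case is the alloaneuploid lager-brewing yeast,
an interspecies hybrid whose *S. cerevisiae* sub-genome is an admixed
mosaic of ale-brewing, wine and laboratory lineages, carrying 0–5 copies
of each chromosome. kpaint implements a deliberately simple, reference-free
alternative to phylogenetic network inference for such genomes: score every
small window of the genome independently against a panel of strains, then
summarise where in a fixed population tree the most similar strains sit.

## Sub-region similarity model

The reference assembly is partitioned into non-overlapping **sub-regions**
of `region_size` bases (default 2000, `partition_reference()`). Coordinates
are 0-based half-open; a trailing window shorter than `region_size` is kept
when it is at least `k` bases (it can still contribute k-mers; dropping it
would systematically discard subtelomeric sequence, which is exactly where
strain differences concentrate).

Each sub-region is reduced to its set of **canonical k-mers** (default
`k = 21`): every length-k window, replaced by the lexicographic minimum of
itself and its reverse complement, duplicates removed. Canonicalisation
makes sets strand-invariant; windows containing non-ACGT symbols are
skipped rather than guessed. 21 is the conventional k for genome sketching
in yeast-sized genomes — long enough that almost all 21-mers are unique in
a 12 Mb genome, short enough that a 2 kb window still yields ~2000 of them.

Panel strains are represented the same way, but their k-mers are taken from
**read alignments** (`region_sets_from_alignments()`): for every primary
mapped read, the aligned (M/=/X) CIGAR blocks are projected onto reference
coordinates and the read bases falling inside a sub-region contribute
k-mers to that region's set. A read spanning a boundary feeds both regions,
but no k-mer straddles a boundary, so sample sets are built exactly like
the reference sets and compare one-to-one. Using reads rather than
assemblies means heterozygous positions contribute both alleles' k-mers —
heterozygosity raises rather than splits similarity. Unmapped, secondary
and supplementary records are ignored; duplicates are not detected.

The similarity of sub-region $r$ to sample $s$ is the **containment**

$$C(r, s) = \frac{|K_r \cap K_{r,s}|}{|K_r|}$$

of the reference region set $K_r$ in the sample's region set $K_{r,s}$.
Containment rather than Jaccard is the default because the sample set size
grows with read depth and error content; dividing by the reference set size
makes scores comparable across samples of different depth. Jaccard is
available via `score_matrix(..., metric = "jaccard")`.

### The k-mer multiplicity floor

A sequencing error creates up to k novel k-mers. At 30x coverage with a
per-base error rate of only 0.002, singleton error k-mers roughly *double*
a region's read-derived set, and containment of such a set in any clean
target collapses to ~0.5. `region_sets_from_alignments(min_freq = 2)`
drops k-mers seen only once in a region: true k-mers recur with the
coverage, error k-mers almost never recur. The floor mirrors the standard
minimum k-mer frequency used when sketching read sets (see below). The
default is `min_freq = 1` (the plain set-union contract); use 2 whenever
depth is ~20x or more. The end-to-end benchmark uses 2.

### Top-scoring calls

`assign_top()` marks, per sub-region, every sample within `tie_delta`
(default 0: exact ties) of the maximal score as top-scoring. A region whose
maximum falls below `min_similarity` (default 0.75) is `low_similarity` and
gets no winners; winners spanning more than one lineage give
`ambiguous_lineage`. Both thresholds are reported in output headers. The
0.75 default is a pragmatic floor — about the containment expected between
genomes ~1.5% diverged at k = 21 — and is deliberately conservative: a
region is only painted when some panel strain explains most of its k-mers.

## Population tree and tracing

The panel's population structure is either supplied (a newick tree plus a
sample-to-lineage table) or computed: genomes or read sets are MinHash
**bottom sketches** (`minhash_sketch()`: k-mers below a multiplicity floor
discarded, remaining k-mers hashed with a fixed 64-bit FNV-1a hash
truncated to 53 bits so values survive R's doubles exactly, smallest
`sketch_size` hashes kept, default $10^6$). The Jaccard index is estimated
with the standard merged bottom-sketch estimator and converted to the
**Mash distance** $d = -\tfrac{1}{k}\ln\frac{2j}{1+j}$, capped at 1 when
$j = 0$. The default multiplicity floor of 2 is meant for read sets;
assemblies, whose k-mers are single-copy, are sketched with `min_freq = 1`
(the `tree` subcommand's default).

Trees come from a hand-rolled **UPGMA** (`upgma()`) — size-weighted average
linkage, merge at distance $d$ placing the new node at height $d/2$. Ties
are broken by the lexicographic order of the clusters' smallest leaf
labels and children are written smallest-leaf first, so output is fully
deterministic. Neighbor-joining (`nj_tree()`, via ape) is offered for
users preferring an additive tree.

`trace_tree()` aggregates the per-region winners onto the tree: every
traced region increments each of its top-scoring leaves (tied samples all
count, so the total N equals the sum over regions of the number of
winners), internal nodes receive the sum of their descendant leaves, and
lineages the sum of their members. Fractions of N are what a tree-tracing
display scales its edge widths by.

### What "recovering the topology" means here

The synthetic panel generator radiates strains from a lineage founder, so
the generating truth tree is multifurcating within lineages, and a binary
UPGMA tree can never reach symmetric Robinson–Foulds distance 0 against
it. Topology recovery is therefore measured on the splits the truth
actually resolves: the number of lineage clades that fail to be
monophyletic in the inferred tree (`lineage_monophyly()`); zero means
every resolved truth split is present, i.e. RF restricted to the truth's
resolution is 0.

## Copy-number analyses

**Chromosome level** (`window_medians()`, `chromosome_copy_number()`):
per-base depth is summarised as medians over non-overlapping 100-base
windows (medians resist alignment pileups and dropouts; the trailing
partial window is kept; an even count takes the mean of the two middle
values). Each contig's median of window medians is scaled against the
smallest *positive* contig median, attributed `baseline_ploidy` copies,
and rounded to an integer. Zero-coverage contigs are reported as copy 0
and excluded from the baseline — a contig at copy 0 must not define the
per-copy depth.

**Gene level** (`gene_copy_deviation()`): within a contiguous region of
fixed copy number (user-supplied, or segmented from the track by
`region_stats_from_track()`, which estimates the per-copy depth from the
lowest positive coverage level among windows), a gene's mean coverage is
compared with the region's mean and standard deviation by an uncorrected
Z-test. The test is two-sided (both gains and losses are of interest) at
α = 0.05 by default; zero-variance regions are flagged untestable rather
than divided by zero. The test is intentionally uncorrected — it is a
screen, and its output says so in the header.

**Heterozygous SNP filter** (`filter_het_snps()`): discards calls within
10 kb of chromosome ends, with minor-allele frequency below 0.15, or with
depth below 3. "Below" thresholds are implemented as strict-less-than
exclusions, so a SNP exactly at a floor is retained; the boundary choice
is stamped into output headers since the convention is ambiguous in common
usage.

## Tandem repeat copy numbers

Flocculin-type genes carry intragenic tandem repeats whose copy number
correlates with flocculation strength; copy number is estimated from the
gene sequence and a known repeat unit. `align_units()` finds all
non-overlapping local alignments of the unit (both strands) against the
gene by iterated best-hit search: Smith–Waterman (match +1, mismatch −1,
gap −2 linear, via Biostrings) finds the best hit, then the search recurses
into the flanks on either side. The score floor is tied to the identity
floor (default 0.7); hits below the identity floor are dropped.
`cluster_repeats()` removes hits covering less than half the unit, then
chains hits whose gap — measured from the running end of the current
cluster, so nested hits cannot shrink it — is at most 3 unit lengths.
Copies = cluster span / unit length, which is what produces fractional
copy numbers for truncated or spaced copies; reports round to one decimal
and show the largest cluster per gene x unit, with all clusters retained
in an attribute.

## The synthetic data generator

`simulate_panel()` builds a random ancestor, one founder per lineage at
`between_div` substitutions per site from the ancestor, and strains at
`within_div` from their founder; substitutions hit i.i.d. uniform sites
and pick uniformly among the three alternative bases. The model is
substitution-only — no indels — so every simulated genome stays
coordinate-colinear with the reference, and segment truth projects exactly
onto sub-regions. That is a deliberate trade: it makes
`region_sets_from_genome()` valid for panel genomes and truth exact, at
the cost of not exercising indel/rearrangement robustness, which real
panels (aligned with a real aligner) would encounter. Likewise
`simulate_reads()` draws uniform read starts with a uniform substitution
error rate and emits alignments at the true positions — no aligner runs,
so mapping bias and soft-clipping are out of scope of what passing tests
demonstrate. `simulate_aneuploid_depth()` draws per-base Poisson depth at
ploidy x per-copy-depth, and `simulate_repeat_gene()` concatenates exact
unit copies with random spacers. All generators are seed-deterministic and
record their seed in the returned truth object.

## The benchmark conditions

`admixture_benchmark()` fixes the study conditions used throughout the
package's end-to-end checks: 5 lineages x 3 strains on a 200 kb two-contig
genome, within-lineage divergence 0.003 and between-lineage 0.02 (the
within value mirrors sub-percent strain divergence, the between value the
few-percent divergence of yeast populations), a query copying 60% of its
genome from one donor strain and 40% from a donor in a different lineage
with the breakpoint deliberately off the 2 kb grid (so exactly one
breakpoint region has mixed truth and is excluded from accuracy), 30x
150 bp reads at error rate 0.002, k = 21, 2 kb sub-regions,
`min_similarity` 0.75, `min_freq` 2. The 200 kb genome keeps the whole
pipeline — simulation, SAM round-trip, scoring, sketching, clustering,
tracing — under ~2 minutes on one CPU while leaving 100 sub-regions, a
large enough count for ±5-percentage-point fraction comparisons. What the
benchmark demonstrates is the method's logic, not robustness to real
sequencing artefacts (see the generator's limitations above).

## Numerical choices and degenerate inputs

- Empty reference region sets (possible when a region is all ambiguous
  bases) give status `missing`, never a score; empty sample sets likewise.
- `containment` of an empty reference is `NA`; `mash_distance(0, k)` is
  capped at 1; an empty MinHash sketch warns and compares as `NA`.
- UPGMA branch lengths are formatted at 15 significant digits when the
  newick string is assembled, so cophenetic distances survive the
  string round-trip to ~1e-15.
- The k-mer hash is fixed (FNV-1a 64-bit, top 53 bits); sketches record
  it, and sketches from different runs/machines are comparable.
- All thresholds phrased as "below X excludes" are strict-less-than;
  ties at a floor are kept.

## Known limitations

- Substitution-only simulation; indel-bearing panels must come from real
  alignments.
- `region_sets_from_genome()` on a non-reference genome assumes
  colinearity and is only exact for such synthetic genomes.
- No duplicate-read detection and no base-quality weighting.
- The repeat aligner is exact but iterative; for genes beyond tens of kb
  with hundreds of hits a dedicated aligner would be faster.
- MinHash sketching is exact at these genome sizes (sketches rarely fill);
  the estimator's sampling error only matters for multi-megabase inputs.
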