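---
title: "Phasing assembly graphs with Strand-seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing assembly graphs with Strand-seq: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unitigphaser)
```

## The phasing problem

A diploid assembly graph represents each chromosome pair as chains of
unitigs: homozygous regions collapse into single nodes, heterozygous
regions form bubbles whose two arms carry the two haplotypes. Phasing
the graph means deciding, for every unitig, whether it belongs to
haplotype 1, haplotype 2, or to both (homozygous). Strand-seq provides a
global signal for this: each single-cell library retains only one
template strand per chromosome copy, so the *direction* (Watson or
Crick) of read alignments encodes which chromosome copies contributed a
read.

`unitigphaser` consumes the aggregated output of upstream alignment:
two long-format tables of per-unitig, per-library Watson/Crick
first-mate alignment counts — one from all reads, one restricted to
haplotype-informative reads (reads aligning to unique sequence, i.e.
with a single super-maximal exact match) — plus the assembly graph in
GFA1. Everything upstream of counting (alignment, merging,
deduplication, SMEM filtering, homopolymer compression) is out of
scope; the bundled simulator emulates the *output* of those steps.

## Strand state frequency

For Watson count $w$ and Crick count $c$ of a unitig in a library, the
strand state frequency is

$$\mathrm{SSF} = \frac{w - c}{w + c} \in [-1, 1].$$

A chromosome pair inherits, per library, a matched (WW/CC) or unmatched
(WC/CW) template-strand state, each with probability 1/2. Matched
states drive the SSF toward $\pm 1$, unmatched states toward 0. Cells
with $w + c = 0$ carry no evidence; we set their SSF to 0 and mark them
undefined rather than propagating NaN, which keeps all downstream
vector algebra total (an undefined cell then simply contributes nothing
to any inner product).

The vector of SSF values across libraries is the unitig's signature.
Under ideal conditions all unitigs of one chromosome share a signature
direction $v_\mathrm{clust}$, so clustering by *direction* groups
unitigs by chromosome.

## Chromosome clustering

Similarity is the absolute cosine, $|\cos\theta|$, between SSF vectors:
absolute because a misoriented unitig has its signature negated, and
cosine because degenerate (repetitive) sequence attracts balanced
alignments from everywhere, shrinking every dimension of the signature
by a comparable factor without rotating it. Both invariances are tested
as properties (a uniformly shrunk vector changes no pairwise similarity
and no assignment).

The batched agglomerative procedure admits unitigs in descending
coverage order (batches of 1000; if fewer than 5 batches would result,
5 near-equal quantile batches instead), so high-signal unitigs seed the
clusters. Within the active set three operations alternate:

* **grow** — attach the unclustered unitig with the highest mean
  pairwise similarity to any cluster, while that exceeds `grow_thresh`;
* **create** — seed a new cluster from the best unclustered pair above
  `create_thresh`, then return to growing;
* **merge** — merge cluster pairs above `merge_thresh`, first among
  clusters sharing a connected component of the graph, then globally.

Refinement then dissolves clusters smaller than `min_cluster_size` and
clusters holding under 2% of their component's clustered base pairs,
and lets single-cluster components absorb their unclustered unitigs; a
second clustering round over the remaining unclustered unitigs and a
second refinement complete the procedure.

The three similarity thresholds are genuinely open design parameters;
we default to grow 0.6, create 0.7, merge 0.5. Cross-chromosome
similarities concentrate near $|\cos\theta| \approx \sqrt{2/\pi n}$
for $n$ libraries (inner products of random $\pm 1$ patterns), about
0.09 at 96 libraries, while within-chromosome similarities sit near 1,
so any thresholds well inside (0.1, 1) separate the regimes; the
defaults leave margin on both sides and are exposed in
`clustering_params()`. Ties break to the lexicographically smallest
(unitig id, cluster id) pair, making runs reproducible.

Before clustering, the component heuristic is repaired for acrocentric
chromosomes: the largest component by summed base pairs is taken as the
putative acrocentric component, and the largest connected blob of nodes
shorter than 50 kbp inside it (the rDNA tangle) is excised. "Largest
tangle" is not further specified by the method's description; we rank
maximal short-node-induced connected subgraphs by summed bp, breaking
ties by node count and then smallest id. Unitigs shorter than 50 kbp
are excluded from all downstream stages ("shorter than" read strictly:
a unitig of exactly 50 kbp is retained).

Library quality control mirrors standard Strand-seq preprocessing:
states are discretized (matched when $|\mathrm{SSF}| \ge 0.6$ with at
least 10 reads), and libraries with over 80% unmatched callable cells
(failed BrdU chemistry produces no matched states) or fewer than 20
callable unitigs are discarded. These cutoffs are declared defaults in
the style of existing preprocessing tools, not recovered constants, and
all are configurable.

## Orientation correction

Within a cluster, unitigs of opposite orientation have antipodal
signatures. A two-group cut of a hierarchical clustering on signed
cosine distance ($1 - \cos\theta$, average linkage by default) bisects
the cluster by orientation. Because highly contiguous clusters may
already be consistently oriented — leaving no bisected structure to
find — clustering runs on the unitig vectors *plus a negated copy of
each*, which guarantees both orientations are present; only the
original copies are then kept. Which side is "flipped" is arbitrary; we
deterministically keep the group containing the smallest unitig id as
`FORWARD`. A unitig landing in the same group as its own negation has
near-orthogonal geometry (no orientation signal); it is flagged
ambiguous and left unflipped. Orientation uses the all-reads SSF, where
matched-state libraries carry the $\pm 1$ orientation signal.

## The chromosome plane and the phase vector

In hap-informative SSF space, a diploid cluster's unitigs fall on three
ideal directions — maternal $m$, paternal $p$, homozygous
$(m + p)/2$ — all inside the plane spanned by
$v_\mathrm{clust} \propto m + p$ and $v_\mathrm{phase} \propto m - p$.
$v_\mathrm{phase}$ is zero on matched-state libraries and $\pm 1$ on
unmatched-state libraries, with the sign saying which read orientation
maps to which haplotype.

The plane is estimated per cluster by **uncentered** SVD: the ideal
plane passes through the origin, and projecting/rotating
$v_\mathrm{clust}$ requires a linear subspace, not an affine one.
Explained-variance proportions are the normalized squared singular
values of that uncentered decomposition. $v_\mathrm{clust}$ is the
length-weighted mean of the cluster's (orientation-corrected) unitig
vectors — length weighting so unequal fragmentation of the haplotypes
does not skew it — and $v_\mathrm{phase}$ is its in-plane 90° rotation.
Haplotype labels are parentage-unknown, so either rotation sign is
valid; we rescale $v_\mathrm{phase}$ by its largest-magnitude
component, which fixes the sign deterministically and puts components
on the ideal $-1/0/+1$ scale.

Pooling swaps Watson and Crick counts in libraries with negative
$v_\mathrm{phase}$ components and dots each count column with
$|v_\mathrm{phase}|$, yielding a marker-count pair $(h_1, h_2)$ per
unitig with the exact identity
$h_1 + h_2 = \sum_\ell |v_{\mathrm{phase},\ell}|\,(w_\ell + c_\ell)$.
Components act as continuous weights by default; a `discretize_phase`
option rounds them to $-1/0/+1$ at $|x| \ge 0.5$ for comparison. The
bundled caller assigns `HAP1`/`HAP2` at a marker ratio of 0.8 with at
least 10 markers, `HOM` otherwise; these are plumbing defaults standing
in for graph-threading tools that consume the marker counts directly.

## Haploid chromosomes

A haploid chromosome's unitigs stay on a single line in hap-informative
space, so its cluster shows a near-total first explained-variance
proportion. Clusters with $\mathrm{EV}_1 > 70\%$ and
$\mathrm{EV}_2 < 20\%$ are flagged haploid and merged into one cluster,
so pseudoautosomal unitigs phase together with both sex chromosomes.
Detection happens before orientation correction (the flags are
invariant to per-unitig sign flips, so the order is immaterial to the
outcome).

For the merged cluster, the length-weighted $v_\mathrm{clust}$ is
biased toward the larger chromosome (e.g. X over Y). The correction
projects each unitig direction into the plane, expresses it in
$(v_\mathrm{clust}, v_\mathrm{phase})$ coordinates, and takes the
unitigs with the extreme coordinate products as representatives of the
two chromosomes; $v_\mathrm{clust}$ is rotated onto the bisector of the
two representative directions and $v_\mathrm{phase}$ re-derived. We
compute the coordinate product on plane-normalized directions: this
makes the "all products equal" degenerate case (a single haploid
chromosome, nothing to bisect) detectable regardless of per-unitig
signal strength, and makes the representative choice a function of
direction rather than magnitude.

## What the simulator emulates

`simulate_strandseq()` generates: chromosomes with human-scale lengths
(22 diploid autosomes plus X/Y by default), segments that are
heterozygous bubbles (two haplotype unitigs) with probability
`het_fraction` or collapsed homozygous unitigs otherwise, i.i.d.
equiprobable WW/CC/WC/CW states per chromosome and library, and
binomial read counts around length × depth (about 0.1 reads per kbp per
haplotype per library, the sparse-coverage regime typical of
Strand-seq). Reads from both haplotypes align across a bubble: an
informative share (default 25% for heterozygous segments, the reads
overlapping distinguishing variation) lands deterministically on its
own arm and constitutes the hap-informative counts; the remainder picks
an arm at random. Homozygous unitigs contribute a 20% informative
share. Misoriented unitigs have counts swapped; degenerate unitigs
receive additional orientation-balanced reads in every library (absent
from the hap-informative table, since multi-copy sequence fails the
single-SMEM filter); background noise adds a configurable
orientation-random fraction to both tables. The graph writes bubble
chains per chromosome plus a short-node tangle joining the acrocentric
chromosomes.

Ground truth (chromosome, haplotype, orientation, degeneracy, strand
states) is returned for evaluation;
`evaluate_against_truth()` scores base-pair-weighted call disagreement
under the per-cluster haplotype-label mapping that parentage-unknown
phasing permits, overall and for acrocentric chromosomes.

The simulator does **not** model sister-chromatid exchanges, GC or
mappability bias, nucleotide-level errors, or structured (non-uniform)
background noise, and every simulated segment is at least 60 kbp so
the length filter's effect is exercised only by the tangle nodes.
Passing recovery tests therefore demonstrates correctness of the
algorithms under the model's assumptions, not robustness to every
artifact of real Strand-seq data.

## Numerical choices and degenerate inputs

* Zero SSF vectors have similarity 0 to everything and can never
  cluster; single-cluster components may still absorb them.
* All ties (grow/create/merge targets, representative selection) break
  deterministically; identical seed and configuration give
  byte-identical outputs.
* Basis vectors from the SVD are sign-fixed (largest component
  positive). Rank-1 clusters get a deterministic orthogonal completion
  as the second plane axis and are flagged.
* A cluster vector orthogonal to its plane
  ($\|P v_\mathrm{clust}\| < 10^{-8} \|v_\mathrm{clust}\|$) is a hard
  error — it indicates the cluster has no coherent direction.
* Clusters with a single member get no phase model (a plane needs two
  vectors); their calls are `NONE`.

## Problem sizes used by the test suite

Unit tests run on genomes of 3–8 chromosomes with 24–48 libraries; the
end-to-end recovery checks use the full study conditions (22 diploid
chromosomes plus X/Y, 96 libraries, 8–13 segments per chromosome,
roughly 300–500 unitigs) — sizes at which every algorithmic path
(batching, both refinement rounds, tangle excision, haploid merging) is
exercised while the whole suite stays fast.

## Known limitations

* A fully homozygous genome is indistinguishable from a haploid one by
  the explained-variance heuristic: every cluster is rank-1, all
  clusters get flagged and merged, and pooling then manufactures phase
  where none exists. Real diploid genomes have heterozygous bubbles, but
  near-zero-heterozygosity inputs (or very small clusters with few
  libraries, where the explained-variance estimates are noisy) can
  trigger the same failure mode.
* Misassemblies *within* a unitig (internal inversion breakpoints,
  switch errors in the input graph) are out of scope and propagate to
  the output.
* Clusters are anonymous labels; no chromosome naming is attempted.
* Graph threading of the marker counts into haplotype paths and
  scaffolds belongs to downstream tools; `markers.tsv` is written in
  the `node  hap1  hap2` format they consume.
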