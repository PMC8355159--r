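---
title: "Clonal landscape analysis of IgH repertoires: methods and design"
author: "IghClonal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal landscape analysis of IgH repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

B-cell responses in murine lupus models involve several splenic subsets —
follicular B cells (FoB), age-associated B cells (ABC), germinal-center B
cells (GCB) and plasmablasts/plasma cells (PB/PC), the latter two stratified
by CD11c expression. Bulk IgH sequencing of sorted subsets (each amplified as
two replicate libraries) yields annotated rearrangements: V and J gene calls,
the CDR3 junction, copy counts and sample metadata. `IghClonal` turns those
tables into a clonal landscape: which clones exist, how oligoclonal each
subset is, how mutated the clones are, and how much clonal material the
subsets share within an animal.

The package consumes AIRR Rearrangement TSVs (the community standard for
annotated receptor sequences). Upstream read QC and V/J annotation
(pRESTO/IgBLAST territory) are out of scope.

## Clone definition and inference

A clone is the set of rearrangements inferred to descend from one VDJ
recombination event. `callClones()` implements a two-stage rule:

1. **Partition and cluster.** Records are partitioned by (mouse, V gene,
   J gene, CDR3 nucleotide length). Within a partition, records whose CDR3
   amino-acid identity is at least the threshold (default 0.85, inclusive)
   are joined; clusters are the connected components of that graph
   (single-linkage). Identity is position-wise over the common length; `X`
   (untranslatable codon) matches only `X`.
2. **Consensus collapse.** Each cluster's copy-weighted per-position majority
   CDR3 nucleotide consensus is computed (ties break A < C < G < T; `N`
   never beats a concrete base on a tie). Clones of the same mouse and CDR3
   length whose consensuses are within 2 nt (Hamming) are merged
   *transitively, ignoring V/J calls* — this absorbs erroneous gene calls,
   which otherwise split one biological clone into several gene-labelled
   fragments.

Design choices worth spelling out:

* **Single linkage as the default.** A threshold-cut hierarchical
  single-linkage dendrogram equals the connected components of the
  at-threshold graph, which is order-invariant and has no tie ambiguity.
  Complete linkage is available (`linkage = "complete"`) for users who want
  to forbid chained clusters.
* **Gene-level calls.** Allele suffixes (`*01`) are stripped and ambiguous
  multi-gene calls collapse to their first gene at ingest, because the clone
  definition operates on genes, not alleles.
* **Clustering is scoped within a mouse.** VDJ events are per animal;
  identical CDR3s in two mice are independent recombinations, so the mouse
  id is part of the partition key and all overlap statistics stay
  within-animal.
* **Collapse requires equal CDR3 length.** Hamming distance is undefined
  across lengths and the first stage never merges lengths either; the 2-nt
  collapse is a same-length repair step, not an indel-aware comparison.
* **Merged clone identity.** The merged clone takes the V/J calls of its
  largest pre-merge member (ties broken by a canonical clone order:
  descending copies, then consensus string, then gene labels); its consensus
  is recomputed over the merged membership, and the merge is iterated to a
  fixed point so `collapseClones()` is idempotent.
* **Deterministic ids.** Final clones are numbered by descending total
  copies, then consensus string, so outputs are reproducible and invariant
  to input row order.

Records whose CDR3 length is not a multiple of 3 (possible when the
functional filter is disabled) are clustered on the translation of their
in-frame prefix; this is consistent within a partition because partitions
share the nucleotide length.

## Functional filtering

A rearrangement is functional when its CDR3 length is divisible by 3 and the
translation contains no stop codon; an explicit `productive` flag in the
input takes precedence. Whether non-functional sequences should be excluded
from every analysis or only from replicate-overlap statistics is not
something the data dictate, so it is a single pipeline-wide switch
(`functional_only`, default `TRUE` = exclude everywhere). `filterFunctional()`
is idempotent.

## Per-subset repertoire statistics

* **D20** (`d20Index`, `d20BySample`): the fraction of a sample's sequence
  copies contributed by its 20 largest clones — an oligoclonality index in
  (0, 1]. Sorting is stable with ties at the rank-20 boundary resolved by
  the caller's clone order (clone id ascending in `d20BySample`), so the
  value is deterministic.
* **Replicate Jaccard** (`replicateJaccard`, `replicateOverlap`): each sorted
  sample is amplified as two libraries; the Jaccard index between the two
  libraries' clone sets (each clone counted once, no size weighting)
  measures clone-level resampling. Two empty sets define Jaccard 0 with a
  warning.
* **SHM** (`shmByCloneSubset`, `shmFraction`): per-record mutation load is
  the mismatch count between the germline-aligned V segment and the
  same-length germline slice (positions with `N` excluded from both
  numerator and denominator), or an explicit `v_mutation_count` with the
  full germline V length as denominator. A clone's mutation percent in a
  subset is the copy-weighted mean over *that subset's* members only, so a
  clone overlapping several subsets is re-evaluated per subset. A clone
  "has SHM" when its percent is at or above `mutated_threshold_percent`
  (default 1% of compared V positions, a conventional buffer against
  sequencing error; 0 is the strict alternative). Fractions come unweighted
  (clones count once) or weighted by subset copy count.
* **CDR3 lengths** (`cdr3LengthDistribution`): one nucleotide-length entry
  per clone per (strain, subset) combination.
* **VH usage** (`vhUsageMatrix`): clone counts per V gene and stratum (a
  clone counts once per stratum), top 20 genes by total count
  (lexicographic tie-break), each gene row min–max scaled to [0, 1] — the
  relative row scheme of standard heatmap tools. A constant row has no
  min–max image; it maps to 0 and is flagged rather than silently inventing
  contrast.

## Cross-subset overlap

Within one mouse, `subsetOverlap()` builds the clone-by-subset copy matrix
(replicate libraries merged — presence, not depth, is the question) and
derives:

* **Jaccard matrix**: shared clones over either-subset clones, presence
  only. A subset with zero clones yields 0 entries and a warning.
* **Cosine matrix**: cosine similarity of the copy-count vectors over the
  union clone axis, so clone size is taken into account. Cosine is 1 exactly
  when abundances are proportional; Jaccard is 1 exactly when supports are
  identical — neither dominates the other in general.
* **Venn region counts**: exact clone counts per membership combination
  (2–6 subsets); regions partition the clones present in at least one
  subset.
* **Presence tracks**: clones present in at least `min_subsets` subsets,
  ordered by (number of subsets, total copies) descending, with per-subset
  clone counts attached.

Clones are never pooled across animals; `aggregateOverlap()` averages
per-mouse matrices entrywise.

## The repertoire simulator

`simulateRepertoire()` generates AIRR-format repertoires with ground truth so
every stage is testable without sequencing data. Per mouse:

1. **Memberships.** Subsets are filled in panel order. A clone already
   present in earlier subsets enters subset *k* with probability
   `1 - prod(1 - sharing[j, k])` over the earlier subsets *j* containing it;
   the rest of subset *k*'s `n_clones` slots are fresh founders. With
   exactly two subsets and sharing *p* the shared count is Binomial(n, p),
   so the expected between-subset Jaccard has the closed form `p / (2 - p)`
   — the calibration the tests check. The default panel uses baseline
   sharing 0.05 with the ABC–PB/PC pairs elevated to 0.25, reflecting the
   elevated ABC–PB/PC association the pipeline is meant to resolve.
2. **Founders.** Random V gene (from a synthetic germline panel of 15
   families × 4 similar genes; sister genes differ by ~2% of positions),
   random J, and a random in-frame CDR3 (conserved Cys first codon, Trp
   last, no stops) with amino-acid length drawn from a peaked 9–22
   distribution.
3. **Sizes.** Per subset, copies follow a Zipf rank law with exponent
   `alpha` (every clone keeps at least one copy; the remaining
   `copies_total - n` copies are multinomial with weights `rank^-alpha`).
   Defaults: FoB 0.4 < ABC 0.9 < GCB 1.3 < PB/PC 1.9, the skew gradient
   behind the D20 ordering.
4. **Sequences.** Each clone contributes `1 + Poisson(0.7)` variants per
   subset; non-founder variants substitute CDR3 bases at 1% per base (well
   inside the 0.85 identity radius). V segments acquire
   `Poisson(shm_rate × v_len)` mutations; default rates per nucleotide are
   FoB 5e-4 < ABC 6e-3 < GCB = PB 2e-2, giving expected mutated-clone
   fractions near 0.02 / 0.25 / 0.95 at the 1% call threshold.
5. **Artifacts and replicates.** With probability 2% a record's V call is
   relabelled to a sister gene of the same family — the realistic miscall
   mode the 2-nt collapse exists to repair (and, because sister germlines
   are similar, one that only mildly perturbs SHM counting). Copies split
   binomially (0.5) into the two replicate libraries; zero-copy rows vanish,
   so small clones can drop out of a library, as in resampling reality.

Everything is deterministic under `seed`. `evaluateRecovery()` scores a
called `CloneSet` against the truth partition (adjusted Rand index via the
standard contingency formula, plus merge/split error counts).

### What the simulator does and does not emulate

It reproduces: the strain × subset × duplicate-library design, heavy-tailed
subset-specific clone sizes, the SHM gradient, tunable (and asymmetric)
clone sharing, within-clone CDR3 variation and V miscalls. Passing tests on
it therefore demonstrate the pipeline's correctness on data with those
structures.

It does not emulate: biophysical VDJ recombination (TdT insertions, RSS
usage), selection, indels, or realistic diversity-to-depth ratios. The last
point matters for one statistic: with equal per-subset clone counts and
ample sequencing depth, almost every FoB clone appears in both replicate
libraries, so simulated replicate Jaccard is *high* for FoB and *low* for
the copy-skewed PB/PC pool — the opposite of real repertoires, where FoB
diversity vastly exceeds sequencing depth and resampling overlap instead
tracks clone size. The replicate-Jaccard estimator itself is validated on
enumerable fixtures; its subset ordering on simulated data should not be
read as a biological prediction.

## Problem sizes and numerical conventions in the test suite

The test suite validates clone calling against a brute-force all-pairs
oracle on 500 random instances of up to 12 records, property-tests
conservation/idempotence/permutation-invariance on 200 further instances,
and runs the simulator at one mouse per seed with the default six subsets ×
200 clones (20 seeds for recovery, where the adjusted Rand index stays
above 0.95 and collapse strictly reduces split errors; 50 seeds for the D20
and SHM subset orderings). Jaccard calibration uses two subsets of 500
clones over 200 simulated mice per sharing value, agreeing with
`p / (2 - p)` within three standard errors at p = 0.1, 0.3, 0.5. One mouse
per simulated repertoire is the natural unit because clone inference and
overlap are per-animal; the full four-strain, two-mice-per-strain design
remains the simulator default.

Numerical conventions: the identity threshold is inclusive (0.85 joins);
consensus ties break by fixed alphabet order with `N` demoted; empty
replicate pairs define Jaccard 0 with a warning; zero-norm abundance vectors
define cosine 0 with a warning; constant VH rows normalize to 0 and are
flagged; D20 of fewer than 20 clones is 1 by construction; degenerate inputs
(empty clone lists, empty strata, mismatched lengths) raise errors rather
than returning silent defaults.

## Known limitations

* Indel-containing CDR3 variants of one clone are not merged (Hamming-only
  comparison, as specified by the clone definition).
* Light chains, lineage trees within clones, and diversity indices beyond
  D20 (Shannon, Chao1, rarefaction) are out of scope.
* SHM uses the V segment only; mutations in D/J are not counted.
* Statistical testing of overlap differences between groups is not provided;
  the package reports the similarity structures themselves.
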