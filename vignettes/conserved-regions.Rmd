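---
title: "Discovering conserved regions in protein sequence collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering conserved regions in protein sequence collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conregid)
```

`conregid` identifies highly conserved sequence regions shared among a
diverse collection of protein sequences and associates each region with
the sequences that carry it. This vignette explains the model behind
each stage, the parameters that matter, the numerical choices the
implementation makes, and what the synthetic benchmark does and does
not demonstrate.

## Pipeline model

The pipeline treats a conserved region — an uninterrupted stretch of
alignment columns with high residue conservation — as the observable
trace of a domain or family region, and proceeds in five stages.

**Similarity graph.** All sequence pairs are aligned locally
(Smith–Waterman, affine gaps) and scores are converted to e-values
under the extreme-value model `E = K · m · N · exp(-λS)`. An edge is
kept when `E ≤ 0.01` — deliberately loose, so that only clearly
non-significant similarities are discarded. The threshold comparison is
inclusive. Because two directional alignments of the same pair carry
one score, the map stores the minimum per unordered pair, and the query
length `m` is taken as the shorter sequence of the pair so that the map
does not depend on input order.

**Grouping.** Connected components capture everything that could be
related, but chain unrelated families through multi-domain sequences. A
maximal clique, in contrast, requires full pairwise interconnection, so
sequences sharing no feature never co-occur in one; a multi-domain
sequence simply appears in several cliques. Since clique enumeration is
exponential in the worst case, components larger than `max_group = 100`
are first split uniformly at random into groups of 100 (the random
split is repaired later by the merge stage). Missing edges (remote
pairs, alignment noise) make enumeration produce many near-duplicate
cliques; these are clustered by single linkage at fractional Hamming
distance 0.3 — the membership-vector Hamming distance divided by the
sum of the two clique sizes, which removes the effect of clique size —
and each cluster is represented by its largest clique. The distance
threshold of 0.3 and group size of 100 are exposed as configuration
but are not meant to be tuned per dataset.

**Conservation scoring.** Each clique is aligned with a progressive
multiple aligner (see *Numerical choices*). Rows are weighted by mean
pairwise distance, so over-represented near-identical sequences do not
dominate; each column is scored with the weighted sum-of-pairs
`Σ w_i w_j Mut(x_i, x_j) / Σ w_i w_j`. The raw track is noisy, so a
one-dimensional median filter with frame 50 (a 51-value window: 25
positions each side plus the centre, zero padded at the edges)
smooths it while preserving region boundaries better than linear
smoothers. Conserved positions are those strictly above 0.2 after
smoothing; maximal runs of at least 20 columns become regions. An
analytic consequence of the 51-value window worth knowing: an isolated
perfectly conserved run survives the filter only from length 26
upwards (a window holds at most `len` ones, and the upper median rises
only when at least 26 of the 51 values are high), so the filter itself
enforces a minimum detectable region size close to the 20-column rule.
Boundaries of ideal planted runs are recovered within ±3 columns.

**Profile search.** Every region profile (per-column residue and gap
counts) becomes a position-specific scoring matrix over its
consensus-retained columns, `score(col, a) = log2((count + pc·bg_a) /
((N + pc)·bg_a))` with total pseudocount `pc = 1` and the dataset's own
residue composition as background. The PSSM is aligned locally against
*all* input sequences; per-PSSM Gumbel statistics are calibrated on
residue-shuffled decoys drawn from the dataset, and only hits at
`E ≤ 10⁻⁵` are kept, one best hit per sequence, in a single pass with
no profile re-estimation. This stage is what attaches remote homologs
and singleton sequences — whose pairwise e-values were too weak for
the graph — back to the families whose domain they carry.

**Merge and association.** Non-gapped consensus sequences (majority
residue per column; columns at least half gaps are dropped) are aligned
all-against-all; significantly aligned pairs (`E ≤ 0.01`) are merged
when the alignment covers the shorter consensus entirely or more than
90% of it. Slightly overlapping regions are deliberately left separate.
Merging proceeds in ascending e-value order and repeats to a fixpoint,
so the result does not depend on enumeration order; the merged profile
sums counts over aligned columns, keeps the longer profile's unaligned
flanks (trimming would discard observed counts), and takes the union of
the two association sets. The binary association table (sequences ×
regions) is the pipeline's main output; an optional final clustering
links sequences sharing at least one region.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `evalue_connectivity` | 0.01 | e-value | edge threshold of the similarity graph (inclusive) |
| `max_group` | 100 | sequences | component size above which random splitting applies |
| `hamming_threshold` | 0.3 | distance | redundant-clique single-linkage threshold |
| `frame` | 50 | positions | median filter neighbourhood (window = frame + 1) |
| `conservation_threshold` | 0.2 | score | conserved-position cut-off (strict) |
| `min_region_length` | 20 | columns | minimum region length |
| `search_evalue` | 1e-5 | e-value | PSSM hit threshold |
| `merge_evalue` | 0.01 | e-value | consensus-alignment significance for merging |
| `overlap_fraction` | 0.9 | fraction | minimum overlap of the shorter consensus |
| `align_matrix`, `gap_open`, `gap_extend` | BLOSUM50, 10, 2 | — | local alignment scoring |
| `score_matrix`, `msa_gap_open`, `msa_gap_extend` | BLOSUM62, 10, 1 | — | MSA and conservation scoring |

The window definition follows the 51-value description (25 left, 25
right, centre); `frame` remains exposed for the alternative reading of
a 50-value neighbourhood.

## Numerical choices

**Conservation similarity.** The substitution matrix must be mapped to
`[0, 1]`. A plain min–max rescaling of the BLOSUM62 residue block maps
a *chance* pair to ≈ 0.23 — above the 0.2 threshold — so densely
aligned but unrelated linker columns would form fake conserved runs;
it also scores a column of identical alanines 0.53 rather than "fully
conserved". We therefore anchor the map at the chance expectation:

`Mut(a, b) = (M(a, b) − E) / sqrt((M(a,a) − E)(M(b,b) − E))`,

clipped to `[0, 1]`, where `E` is the expected pair score under a
standard background composition. Identical pairs score exactly 1,
chance pairs ≈ 0, and the ordering of substitution scores is
preserved. Pairs involving a gap or an unknown residue (X) contribute
0 while still counting in the denominator; an all-gap column scores 0.

**Median filter.** Upper median (the 26th of 51 sorted values) with
zero padding at the track edges; on a binary track this makes the
filter's behaviour exactly countable, which both the tests and the
acceptance computation exploit.

**Progressive MSA.** Guide tree by UPGMA (average-linkage `hclust`) on
pairwise-identity distances; profiles are merged bottom-up with an
affine-gap profile–profile aligner on expected sum-of-pairs column
scores, implemented in C++. Terminal gaps are free: members of a clique
share a core region embedded in flanks of unequal length, and free end
gaps let flanks stagger instead of forcing spurious flank-to-flank
alignment. Ties in the dynamic program resolve diagonal-first, making
the alignment deterministic for a fixed input order. There is no
iterative refinement — the conservation scoring tolerates imperfect
flank alignment, and external alignments can be supplied through
`read_alignment()`. Pairs with no aligned overlap get the maximum
guide-tree distance of 1.

**E-value calibration.** λ and K are fitted by maximum likelihood on
optimal local scores of shuffled decoys (a Gumbel fit; `fit_gumbel()`
uses the standard fixed-point iteration for the scale). The package
ships constants derived this way for the default matrix/penalty
combinations; `calibrate_evalue()` re-derives them for any other
combination, and per-PSSM statistics are always calibrated at run time
from dataset-composition decoys. Exact replication of any particular
search tool's e-values is not attempted — only the ranking and the
loose thresholds matter downstream.

**Tie-breaks.** Equal-size cliques representing one redundancy cluster
resolve to the lexicographically smallest sorted member-id set;
consensus ties resolve to the alphabetically first residue; the ROC
knee resolves to the lower threshold. All output orders are canonical,
which is what makes whole-run artifacts byte-reproducible from the
config seed (randomness — component splitting, decoy shuffling,
simulation — is derived per stage from that seed).

**Degenerate inputs.** Profiles whose columns are all majority-gap are
rejected as degenerate; datasets with fewer than two sequences abort
before the pipeline starts; single-class label vectors are an error
for the ROC knee; an empty similarity map still yields a valid
all-singleton result.

## The synthetic benchmark

`generate_dataset()` emulates the structure the pipeline is designed
for: families defined by a planted consensus domain (default length
80–160 residues) carried by every member (point substitutions at rate
0.1, 1–3-residue indels at rate 0.02) and embedded in i.i.d. random
flanks of 40–150 residues; a fraction of members (default 15%) are
*remote*, mutated at rate 0.3 so their pairwise alignments tend to
fall below graph significance while remaining recoverable by profile
search; a fraction (default 10%) are *multi-domain*, carrying up to
two additional domains of other families separated by random linkers —
the chaining stressor. All lengths keep generated sequences inside the
100–10000 length filter window. The default per-family e-value
behaviour is checked as an invariant: at mutation rate ≤ 0.1, at least
95% of intra-family pairs fall below the 0.01 threshold.

What the generator does *not* emulate: real phylogenetic correlation
structure (members are i.i.d. around the consensus), low-complexity
and compositionally biased segments, signal peptides, coiled coils,
tandem repeats of one domain on one sequence, and realistic domain
length/frequency distributions. Passing the planted-domain benchmark
therefore demonstrates the machinery (grouping without chaining,
remote recovery, reunification of split families, boundary accuracy),
not performance on real proteomes, where those confounders dominate
the error budget.

Benchmark problem sizes used by the test suite: a 15-sequence
three-family topology with one triple-domain sequence (chaining and
determinism checks), a 180-sequence six-family study with 10%
multi-domain and 15% remote members (recovery: combined F ≥ 0.9,
residue-level sensitivity ≥ 0.8), and a single 250-member family that
exercises the `max_group` split and its repair by merging (≥ 95% of
the family reunited under one region).

**Evaluating with overlapping families.** Ground-truth families are
per-domain member sets, and a multi-domain sequence belongs to every
family whose domain it carries; the predicted counterpart of a family
is a column of the association table. Because the final
connected-component clustering chains families through shared
multi-domain sequences *by construction*, clustering quality is scored
on the association columns, and family weights in the combined F-score
are normalised by total family membership (`Σ n_i`) so the score stays
in `[0, 1]`; when families partition the dataset this coincides with
the usual size weighting.

## Known limitations

- Hit spans report one best location per (region, sequence); tandem
  repeats of a domain collapse to a single association.
- The conservation score approximates published conservation measures:
  gap treatment is the simple "gap pairs score 0" rule without a
  separate gap-fraction penalty term.
- The progressive MSA has no refinement pass; very gappy cliques can
  fragment a domain into more than one region, which the merge stage
  only repairs when the consensus overlap rule is met.
- E-values are calibrated empirically; absolute agreement with any
  specific alignment tool is out of scope.
- The pipeline is single-threaded; the all-against-all stage is the
  dominant cost and scales quadratically in the number of sequences.
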