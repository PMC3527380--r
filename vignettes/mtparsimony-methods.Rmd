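---
title: "Methods: parsimony, minimality certificates and rho dating for mtDNA haplogroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parsimony, minimality certificates and rho dating for mtDNA haplogroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions and numerical choices
behind the package, in the spirit of a statistical-methods appendix. It
states no empirical result that the test suite and the acceptance script
do not themselves compute.

## The coordinate frame

Every position is a 1-based coordinate on the revised Cambridge Reference
Sequence (rCRS), the 16,569-bp human mtDNA reference frame; the reference
is an *annotation frame*, never a taxon in any tree. Circularity is
recorded but unused: the default analysis window 550..16050 makes the
problem linear. The packaged gene map is the standard rCRS annotation.
The packaged base sequence is a **synthetic stand-in**, generated
deterministically with rCRS-like base composition and the true rCRS
alleles pinned at the classic haplogroup-defining positions (73, 228,
263, 489, 750, 1438, 2706, 4769, 5460, 7028, 8701, 8860, 9540, 10398,
10400, 10873, 11719, 12705, 13368, 14766, 14783, 15043, 15301, 15326,
16182, 16183, 16189, 16223, 16519, ...). Because the reference only
supplies coordinates, annotation classes and codon context, analyses of
user alignments are unaffected; only variant calls against the packaged
sequence itself at unpinned positions would differ from calls against
the true rCRS.

Positions covered by overlapping annotations resolve to a single class
by the fixed precedence **protein > tRNA > rRNA > control > other**; a
position inside two protein genes (the ATP8/ATP6 and ND4L/ND4 overlaps)
is evaluated in the gene with the smaller start coordinate. Both rules
are arbitrary but deterministic; they exist so that synonymous /
non-synonymous counting is unambiguous.

## Alignment handling

Input is an aligned multi-FASTA in rCRS coordinates (an optional sidecar
track maps columns of pre-trimmed alignments to positions). Masking is
1-based inclusive on both ends. Gap handling is whole-column exclusion:
a column with `-` or `N` in *any* taxon is dropped, which keeps Fitch
scores well-defined over {A,C,G,T}. IUPAC ambiguity codes other than N
are read as N (they are rare in curated complete genomes, and treating
them as partial information would complicate the minimality proof for
negligible gain). A parsimony-informative column has at least two states
each in at least two taxa.

## Parsimony scoring

Binary trees are scored by the Fitch set pass on bitmask-encoded
states, with site-pattern compression (identical columns share one
pattern with a weight). A basal trifurcation is allowed in the Fitch
pass because it is equivalent to rooting an unrooted binary tree along
one of its edges. Any genuinely multifurcating tree is scored by the
unit-cost Sankoff dynamic program, which is exact at any node degree.
Exactness everywhere is non-negotiable here: the minimality certificate
would be worthless if the scorer could over- or under-count on a
polytomy. One direction worth stating explicitly: refining a polytomy
can only preserve or *decrease* the score (extra internal nodes add
freedom), and collapsing an edge that carries no change preserves it.

## Heuristic search

Stepwise addition in input order ("simple") builds the start tree; tree
bisection-reconnection (TBR) then explores rearrangements: every edge is
bisected, the stranded degree-2 endpoints are suppressed, and the two
fragments are rejoined across every pair of attachment edges. The search
keeps a pool of all distinct equal-best topologies (deduplicated by a
canonical split-set key) and explores pool members breadth-first until
no improving or novel equal-score neighbour appears or the deterministic
caps are reached (`max_equal_trees = 100`, `max_explored = 40` expanded
pool members per restart, one extra restart with a rotated addition
order). Ties break on the first candidate in canonical edge order, so
the whole search is reproducible without any RNG; a seed, if supplied,
only randomises the addition order of extra restarts. The caps matter
when the data contain a star radiation: a k-way polytomy has a
super-exponential number of equally parsimonious resolutions, and the
pool is a bounded sample of them — sufficient for the strict consensus
to collapse the unsupported structure, which is the purpose of keeping
the pool.

## The minimality certificate

The certificate machinery is deliberately redundant: `squeeze()` builds
a partition (singletons, then conflict-guided merges, then a budgeted
deterministic hill-climb over block merges, default budget 200
iterations), and `check_certificate()` re-derives every block minimum
from the partition alone. Block minima are exact: taxa are collapsed to
distinct block patterns, and all unrooted binary topologies on the
collapsed taxa are enumerated (refusing blocks that collapse to more
than 9 patterns rather than approximating). Pairwise conflicts are
screened by the bipartite state-graph cycle criterion, and the screen
only *guides* block formation — every bound that enters the certificate
comes from exact enumeration. Constant columns contribute zero and are
excluded. The certificate can fail honestly: `status = "unproven"` with
a valid lower bound is a possible outcome (e.g. higher-order conflicts
the pairwise screen cannot see within the merge budget).

## Branch-mutation mapping

Mapping uses an exact unit-cost traceback on the rooted tree (root from
the configured outgroup; a star genealogy may be declared rooted
explicitly). Tie-breaks are deterministic and ancestral-state
preferring: among minimal root states the reference base wins, and a
child keeps its parent's state whenever that choice is within the
per-site minimum, pushing unavoidable changes toward the leaves. Total
mapped changes therefore always equal the exact tree score. Each change
is annotated in the codon context of its branch's ancestral sequence
(not the reference), which matters for multi-hit codons; reversions are
defined as changes whose derived state equals the reference base while
the parent state does not. Sites needing more than one change tree-wide
are flagged and their hits numbered in preorder.

## Rho dating

Filters: the synonymous clock counts substitutions classified
synonymous (never deletions, never RNA-gene or control-region changes);
the complete-sequence clock counts all substitutions except the
configured excluded positions (default 16182, 16183, 16194, 16519) and
requires an externally supplied rate, since that rate comes from a
published curve fit the package does not re-estimate. Each occurrence
of a recurrent site on a path counts once per occurrence (mutations,
not states). The error model is the heritage branch-weighted estimator
`se_rho^2 = sum_b (n_b/n)^2 m_b`; published ± values for this class of
estimate do not always state their formula, so the choice is documented
prominently and `estimate_age()` accepts an externally computed
`se_rho` for users who prefer another convention. The calibration is
linear by construction: `age_years = rho * years_per_change` exactly,
with 6,760 years per synonymous change as the default.

## The simulator

The generator emulates what matters to this pipeline: ~16.5-kb
rCRS-anchored genomes; star, Yule and coalescent genealogies with branch
durations in years (no effective-population-size parameter — rates are
per lineage-year, which is the natural unit for the clock being tested);
per-class Poisson mutation counts per branch (synonymous default 1/6760
per lineage-year to match the clock; the preset adds non-synonymous at
1/20000, RNA-gene at 1/25000 and control-region at 1/9000 per
lineage-year — chosen once as realistic relative magnitudes for human
mtDNA, the control region fastest, amino-acid-changing and RNA changes
slowest); a 20:1 transition:transversion weight (typical for human
mtDNA); and optional recurrent-site reuse (preset probability 0.02) to
produce occasional parallelisms and reversions. Synonymous and
non-synonymous events are *rejection-sampled in the current lineage
background*, so classification remains correct under multiple hits — the
same convention the annotation module uses.

The `q2a_preset()` fixture encodes the study conditions this package is
exercised under: 11 genomes; a basal lineage at 34,650 years; a
subclade root at 22,430 years with a 7-way polytomy (two immediate
descendants, three further singleton lineages, a 2-leaf group splitting
at 10,000 years, a 3-leaf group at 6,760 years); long private branches.

What the simulator does **not** emulate: selection, site-to-site rate
heterogeneity beyond the four classes, insertions, heteroplasmy,
population structure and migration, and sequencing error. Passing tests
on simulated data therefore demonstrate algorithmic correctness
(scores, certificates, mapping, calibration), not robustness to those
real-data phenomena.

## Test problem sizes

The property suites run at sizes where exact oracles are available:
exhaustive enumeration covers up to 8 taxa (10,395 topologies), so
oracle-equivalence and squeeze-soundness checks use 200 and 60 random
instances weighted toward 5–7 taxa with a tail at 8; dating recovery
uses 500 simulated 7-leaf star clades at the synonymous clock rate;
codon classification is checked against an independently packaged
translation table over all 64 × 9 codon-change contexts on both a plus-
and the minus-strand gene. These sizes were chosen to keep the suite
comfortably interactive while leaving no algorithmic path unexercised.

## Known limitations

* The pairwise conflict screen cannot see strictly higher-order
  incompatibilities; such certificates may stay "unproven" even when a
  cleverer partition would prove minimality.
* The TBR pool is capped; on data with massive equal-best sets the
  strict consensus summarises a bounded, deterministic sample of that
  set.
* Deletions are located but not translated (no frameshift annotation),
  and insertion nomenclature is out of scope.
* The packaged reference sequence is synthetic (see above); packaged-
  reference variant calls at unpinned positions are not rCRS-literal.
* Dating assumes the mapped tree and its mutation placements are
  correct; placement ambiguity under homoplasy is resolved by the
  deterministic tie-break, not integrated over.
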