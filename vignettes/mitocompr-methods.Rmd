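---
title: "Methods: how mitocompr measures a mitogenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how mitocompr measures a mitogenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocompr)
```

This vignette is the package's own account of its methods: the models
and conventions behind each analysis stage, the tunable parameters and
why their defaults are what they are, what the synthetic-data
generators do and do not emulate, and the numerical choices that make
results reproducible.

## The annotation model

A mitogenome annotation is an ordered set of features on a circular
molecule with 1-based inclusive coordinates on the majority strand,
exactly as published feature tables print them. Origin-spanning
features are encoded as `start > end` plus an explicit `wrap` flag;
a `start > end` row without the flag is rejected as a likely typo
rather than silently interpreted. Feature class (PCG, tRNA, rRNA,
control region) is inferred from the canonical gene name; a packaged
alias map resolves GenBank dialects (`COI`, `ND4L`, `12S`,
`trnL-UUR`, ...) case-insensitively.

**Spacer accounting.** For consecutive features the signed spacer is
`next.start − end − 1`; the final record closes the circle with
`genome_length − last.end + first.start − 1`. Each record is
attributed to its *upstream* feature — the convention of published
IGN columns, which makes the packaged fixture reproduce its printed
column value for value. Positive records are intergenic nucleotides,
negative are overlaps, zero-length abutments count as neither a
location nor an overlap. Feature lengths are raw spans (overlap bases
are not subtracted), so the conservation identity

> sum of class totals + total intergenic − total overlap = genome length

holds exactly whenever the features tile the circle; it is asserted in
the tests on both the packaged and synthetic annotations. Control
regions occupy sequence and therefore participate in spacer
computation, but they are treated as unoriented: they are excluded
from strand counts and never enter gene orders.

A known limitation: the circular spacer walk sorts by start
coordinate, so it assumes no feature crosses the origin (true of the
packaged annotation, whose first feature starts at position 1).

## Composition and skews

AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C), computed on
the majority strand, which is how strand asymmetry is conventionally
measured. Ambiguity codes are tallied as "other", excluded from skew
denominators, and a sequence with an empty denominator carries an
explicit undefined-skew flag rather than a NaN surprise. Per-class
composition concatenates the *majority-strand* slices of each class's
features — deliberately strand-agnostic, so class rows are comparable
across genomes regardless of which strand encodes a gene; bases inside
overlapping features count once per class they belong to. Values are
kept at full precision internally; reporting rounds half away from
zero to 2 decimals, matching how published composition tables round
(plain `round()` rounds half to even, which can disagree with a
printed table at the boundary).

## Codon usage and RSCU

Translation table 5 (invertebrate mitochondrial) is packaged directly:
AGA/AGG encode serine, ATA methionine, TGA tryptophan; TAA and TAG are
the only stops. A consequence worth stating: synonymous families are
defined by the code in use, so serine has an 8-codon family and
leucine 6 — each amino acid is one family (no splitting by codon box).
RSCU(c) = count(c) × |family| / family total; families with zero usage
get RSCU 0 plus a flag instead of 0/0. Start codons are counted in
usage — ATN starts are ordinary sense codons under table 5 — and
termination codons are counted but never enter families. For every
nonzero family the RSCU values sum to the family size exactly; this
invariant is tested.

Incomplete stops: a CDS whose length leaves remainder 1 ending in `T`
(or remainder 2 ending in `TA`) is classified as a
polyadenylation-completed stop and rendered `T(AA)` / `TA(A)`; a CDS
in frame 0 whose final codon is not TAA/TAG is flagged anomalous, not
guessed at.

## Control regions

**Tandem repeats.** "Near tandem" is operationalized as: copies at
least `min_identity` = 80% identical to the first unit (per-position
identity, no indels within a copy), separated by gaps of at most a
quarter unit length, unit at least `min_period` = 20 bp, at least
2 copies. The published material gives no thresholds; these reproduce
planted repeat families on synthetic data while rejecting 200 bp of
i.i.d. sequence (both tested). Every phase and period is scanned and
the resulting overlapping candidates are reduced greedily — ranked by
total span, then mean copy identity, then period and start, keeping a
family only if less than half its span is already covered. Ranking by
identity matters: a tandem array also matches at phases shifted into
its flanks and at periods off by one (absorbed by the gap allowance),
and those echoes score lower identity than the true phasing.

**Pairwise identity** is global Needleman–Wunsch with match +1,
mismatch −1, gap −2 (end gaps penalized), identity = matches /
alignment columns × 100. The scheme is fixed and documented because
"percent similarity" is meaningless without one; traceback prefers
diagonal over vertical over horizontal, making the reported alignment
deterministic. The implied alignment score is tested against an
exhaustive-search oracle on short strings.

**Motifs and hairpins.** The motif inventory is the one conserved in
insect control regions: maximal poly-T runs (≥ 5 nt by default,
flagged 5′ when starting in the first 10% of the region), TA(A)n
stretches (≥ 3 consecutive `TA+` units), and exact TATA and GAT hits
(TATA reported at overlapping positions). The stem–loop search is
purely combinatorial — all maximal reverse-complementary arm pairs
with loops of 3–20 nt, where maximal means extendable neither outward
nor inward (inward extension must keep the loop ≥ 3 nt). No
thermodynamics: a free-energy model would demand parameters this
package has no basis to choose, and the search is exactly
reproducible, matching an exhaustive enumerator on every tested
sequence.

## Signed gene orders and rearrangements

A gene order is a signed circular permutation. Canonical form anchors
the order at a chosen gene (default *cox1*) rotated to position 1 and,
if the anchor is on the minority strand, reflects the whole order
(reverse + flip signs) so the anchor reads +1 — circular genomes have
no intrinsic origin, so all comparisons happen in this frame. Oriented
adjacencies are junction pairs (x, y) identified with their reflection
(−y, −x); the breakpoint distance between two orders over the same
genes is the number of adjacencies of one absent from the other,
including the closing circular adjacency, which makes it rotation- and
reflection-invariant. Common intervals are sign-blind: gene sets
contiguous in both linearized orders, enumerated with a running
min/max position scan and verified against a cubic brute-force count.

Rearrangement events act on the linearized order: inversion (reverse a
block, flip its signs), transposition (move a block; the `to`
parameter is the block's start position in the *resulting* order),
inverse transposition (move reversed/flipped), and TDRL (duplicate a
span in tandem, keep each gene in exactly one copy, so the span
becomes `span[keep]` followed by `span[!keep]`).

Scenario inference is an exact search for minimum-length event
sequences, intended for small orders (n ≲ 15) and at most 4 events.
The anchor is held fixed during the search — on a circle every
rearrangement has an anchor-avoiding representation, so no generality
is lost up to circular equivalence. Depth 1 is solved analytically
from the differing window (inversion by reversal check, transpositions
by window-rotation splits, TDRL by a two-subsequence merge test);
greater depths enumerate leading events and recurse. All minimal
scenarios are returned up to a cap (`max_scenarios`, default 100,
with a `truncated` attribute when hit): TDRL alternatives multiply
combinatorially and an uncapped "all scenarios" would be unbounded in
practice. Inference on the full 37-gene order against the ancestor is
outside the exact-search envelope by design; the package reports
orientation changes, breakpoint distance and common intervals there
instead, and treats heuristic whole-genome scenario reconstructions as
qualitative context, not something it claims to reproduce.

## Gene-order phylogeny

The distance stage is the pairwise breakpoint-distance matrix — the
simplest well-defined distance on signed circular orders. Neighbor
joining is implemented directly (Q-criterion minimization, ties broken
by the smallest row/column index pair, standard branch-length
formulas, the last three clusters joined in an unrooted trifurcation);
negative branch estimates are clamped to zero and counted in an
attribute rather than hidden. The implementation recovers the
generating topology on additive matrices from random 5–8-leaf trees
and agrees topologically with an independent NJ implementation; both
properties are in the test suite. Output is an unrooted `phylo` tree;
rooting is a display concern. Newick serialization keeps 6 significant
digits.

## The synthetic-data generators

Every generator is a pure function of its arguments and one integer
seed, threaded through a save/restore of the RNG state so callers'
randomness is untouched.

`synth_spec()` defaults emulate a thrips-like mitogenome: 13 PCGs, 22
tRNAs, 2 rRNAs, 2 control regions; AT-rich background (A .40, C .12,
G .11, T .37 — the whole-genome majority-strand frequencies typical of
these genomes); a minority-strand fraction of 7/37; spacers drawn from
0–41 bp with occasional small overlaps planted only between
consecutive tRNAs; codon bias induced by weighting each sense codon by
the product of its base probabilities (an AT-rich bias), applied
*during* sampling so frames and stops stay valid rather than edited in
afterwards. PCGs always begin with an ATN start and end with TAA/TAG
unless an incomplete stop is explicitly planted. Overlaps involving a
PCG pair are rejected as infeasible because the later-written gene
would corrupt the earlier one's terminal codon.

What the generators do *not* emulate — and hence what passing tests do
not show about real data: no substitution process along lineages (gene
orders are rearranged by explicit logged events, not evolved), tRNA
and rRNA "genes" are compositionally realistic but structureless, no
sequencing or annotation error, and control-region repeats are planted
with point substitutions only (no indel divergence). Recovery results
on synthetic data demonstrate the analysis machinery is correct, not
that real control regions are this clean.

## Problem sizes and runtime choices

The test suite and the acceptance script use: 100 seeded two-event
scenario recoveries on 8-gene orders; 100 random common-interval
instances at n ≤ 10 against the cubic oracle; 50 additive-matrix NJ
recoveries on 5–8 leaf trees; 50 planted control regions of 320 bp
with 57 bp repeat units at 90% identity; composition convergence at
n = 100,000 with a 3-standard-error bound. These sizes were chosen to
exercise every code path at scales where independent oracles are exact
while keeping a full run in minutes on one CPU.
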