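# mitocompr

Comparative analysis of annotated animal mitochondrial genomes, written
for people characterizing newly sequenced mitogenomes — particularly
compact, highly rearranged ones such as those of thrips (Thysanoptera).
Given a feature table (gene, strand, 1-based coordinates) and optionally
the sequence, the package computes the statistics that a mitogenome
description paper reports, and ships seeded synthetic-data generators so
every stage can be verified without downloading anything.

## What it computes

* **Circular annotation accounting** — for every pair of features
  adjacent on the circle, the signed spacer `IGN = next.start − end − 1`
  (positive = intergenic nucleotides, negative = overlap), including the
  wrap-around junction; totals, extrema, strand counts and per-class
  length sums, with the conservation identity
  `Σ class totals + intergenic − overlap = genome length`.
* **Composition and strand asymmetry** — base percentages per gene class
  and the majority-strand skews
  `AT skew = (A − T)/(A + T)`, `GC skew = (G − C)/(G + C)`.
* **Codon usage and RSCU** under the invertebrate mitochondrial code
  (translation table 5: AGA/AGG → Ser, ATA → Met, TGA → Trp), with
  incomplete-stop handling (`T(AA)` / `TA(A)` completed by
  polyadenylation), absent codons and amino-acid usage ranking.
  `RSCU(c) = n_c · |F| / Σ_{c′∈F} n_{c′}` over each synonymous family F.
* **Control regions** — near-tandem-repeat families (approximate copies,
  gap ≤ unit/4), global pairwise identity (Needleman–Wunsch, +1/−1/−2),
  conserved motifs (5′ poly-T, TA(A)n, TATA, GAT) and combinatorial
  stem–loop search.
* **Signed gene-order rearrangement analysis** — orders as signed
  circular permutations anchored at *cox1*(+); oriented adjacencies,
  orientation changes, breakpoint distance, common intervals, and exact
  small-scale inference of minimum event scenarios over inversions,
  transpositions, inverse transpositions and tandem
  duplication–random loss (TDRL), against the packaged ancestral insect
  gene order.
* **Gene-order phylogeny** — pairwise breakpoint-distance matrix and an
  in-package neighbor-joining implementation with Newick output.

## Worked example

The package ships the annotation of the *Neohydatothrips samayunkur*
mitogenome (GenBank MF991901) as a plain-text feature table:

```r
library(mitocompr)
ann <- read_nsamayunkur()
annotation_summary(ann)
#> <annotation_summary> N_samayunkur_MF991901 (15295 bp)
#> intergenic: 204 bp across 23 locations (1-41 bp)
#> overlaps:   3 pairs, 28 bp total (1-24 bp)
#> strands:    30 majority / 7 minority
#> class bp:   PCG 10982, tRNA 1401, rRNA 1808, CR 928
```

204 bp of intergenic sequence over 23 spacers (the longest, 41 bp, sits
at the trnS2 → cox1 wrap junction), three gene overlaps of 1–24 bp, 30
genes on the majority strand, and 10,982 bp of protein-coding sequence —
the numbers that characterize this genome's unusually tight packing.

Comparing its gene order with the ancestral insect order:

```r
ord <- to_signed_gene_order(ann)
anc <- ancestral_insect_order()
orientation_changes(ord, anc)
#> [1] "atp8"  "nad1"  "rrnL"  "rrnS"  "trnC"  "trnF"  "trnL1" "trnQ"  "trnV"
adjacency_present(ord, "trnL2", "cox2")   # FALSE: the conserved block is broken
breakpoint_distance(ord, anc)
#> [1] 33
```

Nine genes have flipped orientation relative to the ancestor, and 33 of
the 37 ancestral gene junctions are gone — an extensively rearranged
mitogenome. RSCU works the way the field expects:

```r
u <- codon_usage(list(paste0("ATG", "AAA", "AAA", "AAA", "AAG", "TAA")))
rscu(u)[c("AAA", "AAG")]
#> AAA AAG
#> 1.5 0.5
```

A multi-genome run (annotation stats, composition, codons, control
regions, gene orders, breakpoint-NJ tree) is driven by one JSON config:

```r
run_pipeline("pipeline.json")   # writes report.json, TSVs, and a Newick tree
```

or from a shell via `Rscript inst/cli/mitocomp.R --config pipeline.json`.

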