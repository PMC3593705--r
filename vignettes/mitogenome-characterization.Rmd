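---
title: "Characterizing circular mitochondrial genomes with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing circular mitochondrial genomes with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

## The problem

A newly sequenced insect mitogenome is described through a fixed battery of
analyses: genome size and gene content, strand distribution, gene order
relative to the ancestral insect arrangement, nucleotide composition by gene
class, start and stop codon usage of the 13 protein-coding genes, relative
synonymous codon usage, the cloverleaf secondary structures of the 22 tRNAs,
and the inventory of intergenic spacers, gene overlaps, microsatellites and
conserved motifs. mitochar implements this battery as a reusable, tested
pipeline over annotated circular genomes, plus a synthetic-genome generator
that provides exhaustive ground truth for every stage.

## Coordinates and containers

Internally every feature lives on a 0-based half-open axis on the stored
forward strand, which is defined as the J (majority) strand — the strand
encoding cox1. A feature crossing the origin of the circle is encoded with
`end > length`; the modular arithmetic is confined to sequence extraction.
GenBank input (1-based, inclusive, `complement(...)`, origin-spanning
`join(...)`) is normalized on read and restored on write, so a
write-then-read round trip is the identity on sequence and coordinates. Gene
aliases (COI, ND2, 16S, tRNA-Met products, D-loop) map onto canonical
symbols; unknown names are kept verbatim with a warning rather than dropped,
so third-party records never silently lose features.

## Composition

`base_composition()` counts A, C, G, T; N bases are excluded from every count
and denominator, so an all-N sequence reports missing percentages rather
than zeros. Partition composition concatenates the reading-direction
sequences of a partition's member features. Because the literature reports
per-gene-class values without defining how shared bases of overlapping genes
are de-duplicated, a base shared by two features deliberately counts once per
feature; the choice is documented here and pinned by a test. The annotated
CDS span is used as-is, including the nucleotides of incomplete stop codons.

## Codon usage

Translation uses the invertebrate mitochondrial code (NCBI table 5:
AGA/AGG → Ser, ATA → Met, TGA → Trp; only TAA and TAG are stops). The variant
arthropod code with AGG → Lys is available as an explicit alternative but is
never the default: a genome that does not use AGG offers no evidence for the
reassignment. Start codons classify as ATN (any of ATT/ATC/ATA/ATG — ATC is
accepted for generality although insect mitogenomes rarely use it), CGA (the
common cox1 start), or other. Stops classify by frame remainder: a complete
TAA/TAG in frame, a single trailing T, or a trailing TA — the truncated forms
are completed to TAA by post-transcriptional polyadenylation, a
transcript-level event, so genomic codon counts exclude both the trailing
bases and terminal complete stops. RSCU treats Leu as one family of six
codons and Ser as one of eight, the standard convention when the source of a
table does not state otherwise; within every family with a nonzero total the
RSCU values sum to the family size, an identity the tests assert exactly.
Amino-acid percentages are taken over all translated non-stop codons.

## tRNA folding

The folder performs an exhaustive search over all boundary assignments
satisfying canonical cloverleaf geometry: acceptor stem fixed at 7 bp, DHU
stem 3–4 bp with a 4–12 nt loop, anticodon stem fixed at 5 bp with a 7-nt
loop, TψC stem 4–5 bp with a 3–9 nt loop, variable region 3–9 nt, inter-arm
spacers and discriminator 0–3 nt each. The objective is the number of paired
stem positions, counting Watson–Crick pairs and G-U wobbles; there are no
thermodynamic energies, because the goal is the desk-scale, fully verifiable
inference of a secondary structure, not a folding free energy. Ties resolve
by more Watson–Crick pairs, then by the smaller DHU-loop start index, then by
lexicographic order of the free geometry parameters, making the fold a total
function of the sequence. An optional anticodon anchor restricts the search
to folds placing the expected triplet at the loop center.

Some mitochondrial tRNAs — trnS1(AGN) in most insects — lack the DHU arm. A
DHU-less topology (DHU arm replaced by an unpaired 4–15 nt connector) is
searched when the cloverleaf solution is unconvincing: either one of the
acceptor/anticodon/TψC stems falls under 60% paired, or the DHU stem itself
does. In the latter case the DHU-less fold is preferred whenever it explains
the remaining arms at least as well — a cloverleaf whose DHU stem pairs at
under 60% carries no evidence for that arm, and keeping it would simply
reward pairing by chance. A corollary, and a known limitation: a genuine DHU
stem with two or more true (non-wobble) mismatches out of three or four
pairs is indistinguishable from no DHU arm under a pair-counting objective,
and will be reported as DHU-less.

The mismatch census aggregates every non-Watson-Crick stem pair by arm
(DHU, acceptor, TψC, anticodon) and by class, with G-U wobbles counted
separately from true mismatches, which are named as unordered base pairs
(A-A, C-A, C-T, …). T stands in for U throughout, as the analysis is at the
gene (DNA) level.

## Non-coding analysis

Features sorted by start on the circle define junctions; a positive gap is a
spacer, a negative one an overlap, and the origin-spanning junction is
handled identically. A feature wholly contained in another is catalogued
separately and excluded, with a warning, since containment breaks the
accounting identity Σ feature lengths − overlap bp + spacer bp = genome
length, which is otherwise asserted on every synthetic genome. When a record
does not annotate the A+T-rich region, the largest unannotated gap stands in
for the control region (and the decision is logged); when it is annotated it
is a feature, and therefore not a spacer.

Tandem repeats are maximal exact arrays with unit sizes 1–6 and per-class
minimum copies (mononucleotide 8, dinucleotide 5, longer units 3 — chosen so
that a (TA)5 array registers while ordinary AT-rich background does not).
Units are normalized to their lexicographically least rotation, which
resolves the (AT)n-versus-(TA)n naming ambiguity; arrays whose unit is itself
periodic are reported once under the primitive unit. Fractional trailing
copies are retained in the copy number and coordinates.

Sequence identity uses a hand-written Needleman–Wunsch global alignment with
match +1, mismatch −1 and linear gap −2, with a deterministic traceback
(diagonal, then gap-in-second, then gap-in-first). The parameters are
configurable because sources rarely state their identity method; the
defaults are ordinary unit-cost choices. `spacer_origin_scan()` slides a
spacer across all gene windows of its length to ask whether it arose by
partial duplication of a neighbour — the lepidopteran trnQ–nad2 spacer being
the motivating case.

## The synthetic generator

`generate_mitogenome()` emits a deterministic, seeded, annotated genome in
the derived lepidopteran gene order (control–trnM–trnI–trnQ–nad2–…, 14 J- and
8 N-strand tRNAs) with exhaustive ground truth. The defaults realize the
conditions of a typical pyralid mitogenome: 15,273 bp in total; a 351 bp
control region at 96–97% A+T carrying ATAGA + 20 bp poly-T, (TA)9, (TA)8 and
a 10 bp poly-A; a 61 bp trnQ–nad2 spacer at 96.7% A+T; a 49 bp trnE–trnF
spacer containing (TA)18 and (TTAT)3; a 16 bp trnS2–nad1 spacer with the
ATACTAT motif; ten minor spacers of 1–5 bp (15 non-coding regions in all
counting the control region); and 35 bp of overlap over eight junctions, led
by the 7-nt atp8/atp6 ATGATAA overlap and an 8-nt trnW/trnC overlap. PCGs are
generated in frame with the classic start assignments (CGA for cox1, ATN
elsewhere) and stop classes (single T for nad2, cox1, cox2, nad4; TAA for
the other nine). Gene lengths sit in realistic per-class ranges (tRNAs
64–73 nt, rRNAs 779 and 1,312 nt, PCGs 162–1,734 nt).

Background sequence is drawn per site with P(A) = P(T) = at/2 (default
at = 0.80). The realized whole-genome A+T lands slightly below the nominal
target — in-frame codon sampling rejects TAA/TAG, which are A+T-rich, and
the fixed start/stop codons and anticodons contribute — so composition
recovery is asserted within ±2 percentage points, not at binomial precision.

tRNA genes are built from cloverleaf templates with fully Watson–Crick stems
into which a configured set of non-WC pairs is planted; the default plan
places 43 pairs (24 of them G-U) across 20 of the 22 genes — 20 in DHU stems,
8 in acceptor stems, 9 in TψC stems, 6 in anticodon stems — with trnM and
trnV perfect and trnS1(AGN) built DHU-less. Three design rules make the
planted structure the unique optimum of the fold search, so that recovery is
a well-posed test rather than a coin flip: unpaired template regions are
drawn from the alphabet {A, C}, within which no Watson–Crick or wobble pair
exists, so loops cannot host an alternative helix; the bases immediately
flanking each stem are adjusted so no helix extends or shifts by one
position without losing pairs; and planted mismatches in the
length-flexible stems (DHU, TψC) go to interior pair positions, since an
edge mismatch could be shed by an equally scoring shorter stem. A draw is
kept only if the folder, run with the same constraints as the pipeline,
recovers exactly the planted boundaries — a rejection that is rare after the
first two rules and keeps generation deterministic under the seed.

What the generator does not emulate, and what passing tests therefore do not
show: realistic codon-usage bias (codons are sampled independently, so rare
codons like AGG do occur), rRNA secondary structure, sequencing error, and
heteroplasmy. Tests against synthetic genomes validate the bookkeeping and
the inference machinery, not the biology of any particular record.

## Numerical and degenerate-input choices

Percentages print to two decimals but are carried at full precision. Skews
with zero denominators, compositions of all-N sequences and folds of
sequences outside 55–90 nt are reported as missing/unfoldable rather than
contrived numbers. The fold search space (at most ~10^5 assignments before
the length filter) is enumerated vectorized; a plain-loop enumeration serves
as the independent oracle in the tests. Problem sizes in the test suite —
2 kb brute-force repeat scans, 100 seeded genomes for the accounting
identity, 300-codon translation oracles — were chosen as the smallest sizes
at which the properties are non-trivial while the whole suite stays
desk-scale.

## Reproducing a published characterization

The test suite contains a reproduction block for the deposited record the
package's default conditions emulate (GenBank HQ897685: 15,273 bp, whole
genome 80.43% A+T, PCGs 78.96%, rrnL 82.95%, rrnS 85.86%, control region
96.58%, a 61 bp trnQ–nad2 spacer at 96.72%, 35 bp of overlaps, Leu 14.42%
with the top four amino acids at 45.53%, and AGG unused). The record itself
is not redistributed; `deposited_record_path()` documents how to supply it.
`scripts/acceptance.R` computes the same battery on the default synthetic
genome, where the structural quantities (length, gene counts, spacer and
overlap inventory, planted tRNA census) are fixed by the generator's
conditions and the compositional ones vary with the seed.
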