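---
title: "Characterizing annotated mitochondrial genomes with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing annotated mitochondrial genomes with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

## Scope and data model

`mitochar` implements the descriptive battery applied in comparative
mitogenomics of insects: given annotated circular mitochondrial genomes of
the canonical 37-gene layout (13 protein-coding genes, 22 tRNAs, 2 rRNAs,
and a control region), it computes nucleotide composition and strand
asymmetry, codon usage, start/stop-codon classes, gene overlap and
intergenic spacer structure, control-region tandem repeats, and the
codon-position partitioned supermatrix handed to phylogenetic software.

The central container is the `mitogenome`: a DNA sequence, an ordered
feature table with 1-based inclusive coordinates, and a genetic-code
identifier (translation table 5, the invertebrate mitochondrial code,
under which TGA encodes tryptophan, AGA/AGG encode serine, and only TAA
and TAG terminate). Features annotated on the complement carry strand `L`
and are analyzed on their coding (sense) strand. Two kinds of genomes are
first-class:

* **real-sequence genomes**, read from GenBank flat files or generated
  synthetically, on which every analysis runs; and
* **placeholder genomes**, built from a coordinate table alone (an all-`N`
  sequence of the right length). These support all layout and size
  arithmetic — which is pure integer work on the annotation — while
  composition-level analyses refuse them explicitly.

The package ships a coordinate fixture for five leafhopper mitogenomes
(four *Mileewa* species and *Processina sexmaculata*, 14,787–15,436 bp),
transcribed from the published annotation table; `mileewinae_fixture()`
loads one species. All layout quantities discussed below are reproduced
from that fixture by integer arithmetic.

## Composition and strand asymmetry

For any region the package reports base counts, AT/GC/GT content and the
skew statistics

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C},$$

computed on the region's analysis strand. Ambiguous bases are excluded
from numerators and denominators; a skew with zero denominator is
reported as missing rather than zero. Reverse-complementing a sequence
negates both skews, which the test suite checks as a property.

Reported regions follow the conventional table: the 13-PCG concatenation
and its three codon-position slices, each PCG, `l-rRNA`/`s-rRNA` and the
rRNA and tRNA concatenations, the control region, and the full genome.
Two conventions matter and are deliberate:

* **Incomplete stop codons.** PCGs ending in `TA` or `T` (completed to
  TAA by post-transcriptional polyadenylation) have those trailing bases
  excluded from the PCG *concatenation*, making its length divisible by 3
  (10,953 bp for the *M. mira* fixture; codon-position slices of 3,651).
  Per-gene composition rows, by contrast, use the full annotated span,
  which is how the published per-gene sizes are tabulated.
* **Strand convention.** Per-gene, tRNA and rRNA rows are computed on the
  coding strand; the full genome and control region on the deposited (H)
  strand. Because the source reports do not state their convention,
  `region_report(..., strand_convention = "deposited")` recomputes
  everything on the deposited strand as a sensitivity check.

## Codon usage

Codons are extracted per PCG on the coding strand with incomplete-stop
bases dropped; an internal in-frame stop is reported as a warning (an
annotation smell worth inspecting), not an error. Relative synonymous
codon usage for codon $i$ in a synonymous family of size $k$ is

$$\mathrm{RSCU}_i = \frac{X_i}{\frac{1}{k}\sum_{j=1}^{k} X_j},$$

so the family mean is exactly 1 whenever the family is observed at all;
unobserved families report missing values. Families follow the split
two-tRNA convention used in mitogenome reports: Leu1 = CUN, Leu2 =
UUA/UUG, Ser1 = AGN, Ser2 = UCN, partitioning the 62 sense codons of
translation table 5. (Table 5 has only two stop codons, hence 62 = 64 − 2
sense codons.) Start codons are counted by default — they are in-frame and
code an amino acid — with a flag to exclude them; complete terminal stop
codons are never counted, since RSCU is defined over amino-acid-coding
families.

## Layout: overlaps, spacers, gene order

The signed spacing between consecutive genes is
`start(next) − end(prev) − 1`: negative values are overlaps, positive
values intergenic spacers, zero abutting genes. Boundary pairs flanking
the control region are excluded from overlap/spacer tallies by default;
this convention reproduces the published counts (10 overlaps and 14
spacers for the *P. sexmaculata* fixture). Ties for the longest overlap
or spacer break by genome order so output is deterministic.

One fixture-level discrepancy is preserved rather than reconciled: the
source text reports 16 overlaps for *M. sharpa*, while its printed
intergenic column contains 17 negative entries. The package computes from
the coordinates, so the test suite asserts 17 and documents that the
published prose count differs.

`gene_order_signature()` canonicalizes the circular gene order to a
rotation-invariant string (anchored at `trnI` when present, else at the
lexicographically smallest rotation), so rearrangement-free genomes
compare equal regardless of where the deposited sequence was opened.

## Control-region tandem repeats

`find_tandem_repeats()` is a deliberately simple, fully specified
detector rather than a reimplementation of alignment-based repeat
finders: identity is mismatch-only (no indels), the consensus is the
first copy, and a candidate array is extended copy by copy while each
full copy stays at or above `min_identity` (default 0.85) against the
consensus, with a fractional final copy counted TRF-style as the matching
prefix of the next segment. Defaults bracket the repeat structure typical
of leafhopper control regions: periods 10–220 bp, at least 2 copies.

Numerical and policy choices:

* **Low-complexity masking.** Mononucleotide runs ≥ 6 bp and
  dinucleotide tandems ≥ 8 bp are masked to `N` before scanning (and `N`
  never matches anything, including `N`), because such runs satisfy every
  small period and would saturate the scan. A candidate whose consensus
  is a homopolymer is skipped regardless.
* **Pruning.** A hit nested inside a same-period hit is dropped; a hit
  whose span is contained in another period's span with strictly higher
  identity is dropped; and phase-shifted re-detections of one array
  (same-period hits overlapping by at least one period) keep only the
  best-identity phase, ties going to the leftmost. Harmonic ambiguity is
  preserved on purpose: an exact 4 × 47 bp array is also, literally, an
  exact 2 × 94 bp array, and both are reported.
* **Oracle.** The detector is checked against an independent brute-force
  scan (direct per-copy identity computation over every start × period)
  on sequences up to 300 bp in the test suite.

Because the model has no indel tolerance and no alignment scoring, exact
unit boundaries of real control regions found by alignment-based tools
are out of scope; the detector is built for, and validated on, planted
repeats with known ground truth.

## Supermatrix construction

`build_supermatrix()` concatenates per-gene alignments in fixed genome
order (`nad2, cox1, cox2, atp8, atp6, cox3, nad3, nad5, nad4, nad4L,
nad6, cytb, nad1` — the source does not state its concatenation order, so
genome order was fixed for reproducibility), gap-filling taxa missing
from a gene. The partition scheme enumerates one partition per gene and
codon position — 39 for 13 genes — pairwise disjoint and covering every
column. Alignment itself is consumed, not performed: equal-length inputs
are accepted so tests need no aligner. Export formats are relaxed PHYLIP,
NEXUS with a `sets` charset block, and RAxML-style partition lines
(`DNA, nad2_pos1 = 1-969\3`), all byte-stable for fixed inputs and read
back losslessly by the package's own parsers.

## The synthetic-genome generator

`generate_mitogenome()` produces the study conditions the analyses
assume, with ground truth for recovery tests. Defaults mirror the
*M. mira* fixture column: its gene order, strands, lengths, signed
spacings, start codons (ATN and TTG where annotated), incomplete stops
(`TA` for cox2, `T` for nad6 and nad1), a 14,917 bp genome, target AT
content 0.79 (the published genomes range 78.3–80.2%), drawn-strand AT
skew 0.057 and GC skew −0.101, an AT fraction of 0.85 for control-region
flanks, and one planted 168 bp unit repeated twice in the control region.

Generation details that required genuine design choices:

* **Overlaps share literal sequence.** Coordinates come from the spacing
  ledger, so overlapping genes physically share bases. Genes are written
  in genome order with the later-starting gene's draw winning, then a
  repair pass re-draws the earlier PCG's affected codons jointly with the
  winner's mutable codons until both reading frames satisfy their
  constraints (correct start codon, no internal TAA/TAG, the specified
  terminal stop). Start codons and stop literals are immutable during
  repair; bounded retries guard against pathological ledgers.
* **Composition calibration.** PCG body codons are drawn i.i.d. per base
  but rejected if they form a stop; since TAA/TAG are AT-rich, rejection
  depresses AT below target. The codon base distribution is therefore
  calibrated (one-dimensional root-finding on the conditional
  expectation) so the post-rejection AT content hits the target in
  expectation. Composition targets are expectations, not constraints;
  tests use a ±1 percentage-point band at genome scale.
* **Plantable repeats.** Repeat units are drawn from a mildly AT-rich
  distribution and rejected unless a doubled copy is free of the masking
  patterns, so planted copies survive low-complexity masking. Flank
  positions aligned with the unit just outside each planted block are
  forced to mismatch it (so the realized copy number is exactly the
  requested one), and the one or two bases adjacent to each block edge
  are additionally forced not to extend a mononucleotide run or
  dinucleotide alternation across the boundary, which would otherwise be
  masked into the copies.

What the generator does *not* emulate: substitution processes on a
phylogeny, codon usage shaped by selection, tRNA/rRNA secondary structure
constraints, and indel variation in repeats. Tests passing on synthetic
genomes therefore demonstrate the correctness of the arithmetic and the
detector contracts, not fidelity to every property of real sequences;
quantities that require the deposited sequences (published composition
and skew *values*, real repeat unit boundaries) are deliberately not
asserted in the test suite.

## Problem sizes and runtime

The test suite and acceptance script run on: the five-species coordinate
fixture (pure integer arithmetic, instantaneous); full synthetic genomes
of ~14.9 kb (a few hundredths of a second each to generate); 100 planted
control regions of 600–920 bp for repeat recovery (well under two
minutes end to end); repeat-oracle instances up to 300 bp; and 13-gene
toy supermatrices of 3–4 taxa. These sizes were chosen to exercise every
code path at the scale of a real mitogenome while keeping the whole suite
fast enough to run habitually.

## Known limitations

* The GenBank reader targets the minimal single-record flat files this
  package writes and the deposited-style records it consumes; it is not a
  general-purpose GenBank parser (no multi-record files, no rich
  qualifier handling).
* Terminal-codon classification trusts the span arithmetic: a span whose
  tail is not TAA/TAG/TA/T is an error rather than a guess.
* The repeat detector's mismatch-only model understates copy numbers for
  arrays with indels between copies.
* Placeholder genomes deliberately refuse sequence-level analyses; there
  is no imputation.
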