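---
title: "Guide design methods: models, parameters and numerical choices"
author: "guideForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide design methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guideForge)
library(GenomicRanges)
```

# Scope and model

guideForge enumerates and ranks CRISPR target sites. The unit of
analysis is the *candidate*: a protospacer of the requested spacer
length adjacent to a PAM that satisfies a degenerate IUPAC pattern,
on either strand of the supplied sequence. Everything downstream —
scoring, off-target counting, nickase pairing, annotation — operates on
these candidates.

Two conventions run through the package and are worth stating once:

* **Coordinates are 1-based and inclusive throughout**, carried in
  `GRanges`/`IRanges` objects. This is the native convention of the
  Bioconductor stack the package is built on; BED input and output are
  converted at the boundary by `rtracklayer`, so BED's 0-based
  half-open semantics never leak into user-visible values. Offsets and
  gaps (for example the nickase pair offset) are length quantities and
  identical under either convention.
* **Guide orientation**: protospacer, PAM and scoring context are
  always reported 5′→3′ as the sgRNA spacer reads. For 3′-anchored
  (Cas9-type) PAMs the PAM follows the spacer; for 5′-anchored
  (Cpf1-type) PAMs it precedes it.

## IUPAC matching and the N policy

Matching is implemented on bitmask-encoded sequences (A=1, C=2, G=4,
T=8; a degenerate code is the union of its bases). A genomic `N`
encodes to 0 and therefore matches *no* pattern code, including pattern
`N`. The consequence is deliberate and conservative: assembly gaps and
ambiguous bases can never anchor a candidate or an off-target site.
Characters outside A/C/G/T/N in input FASTA are mapped to `N` with a
warning rather than guessed at; soft-masking (lower case) is folded to
upper case and ignored. This policy is why matching is written
in-package rather than delegated to `Biostrings::matchPattern(fixed =
FALSE)`, whose `N`-in-subject semantics differ.

## Enumeration and region modes

A candidate is emitted only when protospacer *and* PAM lie fully inside
the selected region (the stricter of the plausible readings; partially
overlapping designs are not silently reported). The scoring context
*may* extend past the region and even past the contig; where it runs
off the contig it is N-padded and the candidate is flagged
`partial_context` instead of being dropped — edge targets are real
targets.

Gene-model targeting accepts BED12 and resolves a mode into concrete
regions: whole transcript, exonic CDS, exonic 5′/3′ UTR, individual
exon (counted in transcript 5′→3′ order), splice junctions, or
promoter. Defaults where a window size is needed: splice flank
**20 bp** each side of every internal exon boundary, promoter window
**2000 bp upstream / 500 bp downstream** of the TSS. These are
conventional display-scale choices, not biological claims, and every
one is an argument.

## Scoring

* **GC fraction** is computed over the spacer only (PAM excluded), and
  the *ideal* window is 40–80 % with **inclusive** bounds: a 20-mer
  with exactly 8 G/C is ideal.
* **PAM-proximal G**: for 3′-anchored effectors, whether the final
  (PAM-adjacent) spacer base is G — position 20 of the customary 20-mer,
  generalized to the final base for truncated or extended spacers. For
  5′-anchored effectors the classical evidence does not apply and the
  flag is reported `NA` rather than silently 0.
* **Self-complementarity** counts *maximal* antiparallel duplexes of at
  least 4 consecutive base pairs, within the spacer (requiring ≥ 3
  unpaired loop bases between the halves) and between spacer and the
  invariant scaffold. "Maximal" means a run of pairable positions along
  one pairing register: a 5-bp stem is one stem, not two 4-bp windows,
  but a homopolymeric block that can pair in several shifted registers
  contributes one stem per register, which is the physically defensible
  reading. Pairing is Watson–Crick; G·T(U) wobble is off by default and
  switchable (`wobble = TRUE`), and the wobble count is never smaller —
  a property the tests enforce. The scaffold ships as an editable
  resource (`extdata/backbone.txt`, the invariant S. pyogenes
  tracr-fused scaffold in DNA alphabet).
* **Efficiency** is a linear position-feature model over the context
  window (default geometry 4 | spacer | PAM | 3, i.e. the familiar
  30-mer for 20-nt spacers with NGG): intercept plus the weights of all
  1–2-nt features whose k-mer matches at its offset, optionally passed
  through a logistic link. Models carry their own window geometry, so
  layouts that read different flank lengths load unchanged; a model
  whose geometry disagrees with the candidates is refused rather than
  misaligned. A candidate whose N-padded context would be read by any
  feature scores `NA` ("unavailable") rather than a silently wrong
  number. The package ships the file format and a clearly labelled
  illustrative model; published coefficient tables are drop-in
  resources rather than vendored data.

## Off-target search

Off-targets are *counted, not scored*: a site qualifies if its PAM
satisfies the run's degenerate pattern exactly and its protospacer is
within Hamming distance ≤ 3 of the spacer. Mismatches are counted over
the protospacer only; a site with a non-matching PAM is not an
off-target at any distance, because PAM recognition precedes binding.
The 3-mismatch cap is a hard interface decision — sites at four or more
mismatches are almost never cleaved and searching for them buries the
signal — so no flag raises it. Self-exclusion is by locus (contig,
start, strand), not by sequence: a second exact copy of the target
elsewhere is a genuine MM0 off-target and colors the design red.

The search itself is a seed-pigeonhole index: every PAM-adjacent window
in the genome is hashed under `nSeeds = 4` contiguous spacer fragments;
any site within 3 mismatches of a query must match at least one
fragment exactly, so the hash retrieves a small candidate set that is
then verified by full comparison. Spacers shorter than `2 * nSeeds`
cannot be split into informative fragments and fall back to verifying
every site, with a notice. A naive full scan
(`findOfftargetsNaive`) is part of the package surface and the
equivalence of the two paths — positions, strands and mismatch counts —
is asserted in the test suite on genomes with planted near-duplicates.

## Nickase pairing

A paired-nickase design is two opposite-strand candidates in PAM-out
orientation: the minus-strand guide's PAM at the genomic left, the
plus-strand guide's PAM at the genomic right. The *offset* is defined
as the gap in bp between the two protospacers' facing (PAM-distal)
edges; since the literature's "bind within 10–31 bp" does not fix the
measuring points, this definition is stated once, used everywhere, and
printed in output headers. The accepted window is **10–31 bp
inclusive** by default.

The *break region* reported for a pair is the inter-protospacer gap —
the "intermediate" segment between the two binding sites. The nick
positions themselves are available per guide as `cut_pos` (3 bp from
the PAM-proximal protospacer end for Cas9-type effectors, 18 bp for
Cpf1-type; these cut-geometry constants are documented, overridable
conventions, since cut-site reporting and primer centering need *some*
anchor).

Paired off-targets ask where both nicks could land elsewhere and
jointly make a double-strand break: the two guides' single-nick hits
(≤ 3 mismatches each) are combined — either guide may take either side,
since nothing biological forbids a guide pairing with its own distal
hit — filtered to opposite strands, PAM-out, same contig, offset within
a window that defaults to the on-target 10–31 but is independently
settable, with the on-target pair itself excluded. Pairs are ranked by
paired-off-target count, then combined single-guide off-target burden,
then mean efficiency.

## Accessory annotation

Restriction sites are IUPAC-motif matches on both strands; a motif
equal to its own reverse complement is reported once per position.
`unique_in_amplicon` marks single-cutters, and sites spanning the cut
position are flagged for RFLP validation. The enzyme table is a ~20-row
editable TSV, not a licensed database.

Primer design is a transparent exhaustive scan: all left/right primers
within the length range whose nearest-neighbor melting temperature
falls in the band, paired subject to product-size limits and a minimum
margin of 50 bp between cut and product edge, ranked by Tm balance then
product-size centrality. Tm uses the unified DNA/DNA nearest-neighbor
parameter set (shipped as a table: stacking ΔH/ΔS per dinucleotide
step, terminal initiation terms, entropic salt correction
0.368·(N−1)·ln[Na⁺], total strand concentration 250 nM, Na⁺ 50 mM).
This internal designer keeps the package dependency-free and testable;
an `engine` argument accepts an external Primer3-compatible designer
returning the same columns.

## Ranking and colors

The sort key is (MM0, MM1, MM2, MM3 ascending, efficiency descending
with `NA` last, self-complementarity ascending, genomic position), in a
stable sort — specificity dominates efficiency by design, since an
efficient guide with an exact second locus is a liability. Colors
compress this: *green* requires MM0 = MM1 = 0, ideal GC and zero stems;
*red* means MM0 > 0; everything else *amber*. No published rank formula
exists to reproduce, so the policy is explicit, configurable through
arguments, and deliberately simple.

# The synthetic-data generator

`makeFixture` builds the genomes the tests and the acceptance script
run on: a seeded i.i.d. background at a chosen GC content with planted,
exactly recoverable features — on-target sites, copies at specified
Hamming distances, and PAM-out half-site pairs at specified offsets.
With `clean = TRUE` every PAM occurrence not belonging to a planted
feature is destroyed by mutating a pattern-constrained position outside
protected spans, so enumeration recovers the truth table *exactly*;
with `clean = FALSE` the background keeps its natural PAM density
(~one NGG site per ~8 bp of random 50 % GC sequence on both strands),
which is what the search-equivalence stress tests want. The same seed
yields byte-identical FASTA/TSV/BED output.

What the generator emulates — and what it does not: it reproduces site
density, planted homology structure and strand geometry, but its
background is i.i.d.; real genomes have repeat families, segmental
duplications and biased composition that make off-target counts far
heavier-tailed. Passing the planted-truth suites therefore demonstrates
correctness of the machinery (no candidate missed, no mismatch
miscounted, no pair outside the window), not that any particular real
locus is safe.

Problem sizes used by the shipped suites — 50–60 kb genomes, up to 200
query guides, offset ladders 8–35, mismatch ladders 0–5 — were chosen
so every planted regime (accepted/rejected offsets, reported/unreported
mismatch depths) is exercised multiple times while a full run stays
comfortably interactive.

# Degenerate inputs and tie-breaks

* Empty results are legal everywhere: an all-AT genome yields a valid
  empty `GuideSet`, header-only TSV and empty BED/FASTA.
* Candidate order, hit order and pair order are fully determined
  (contig, start, strand / left start, right start), so identical
  inputs produce byte-identical outputs.
* `expandIupac` refuses patterns longer than 12 positions (4¹²
  expansions) rather than attempting them.
* Guide lengths below 10 are refused at enumeration; stem counting
  refuses `minStem < 2`; off-target depth above 3 is refused.
* Model weights round-trip through their TSV representation at full
  `digits = 17` precision.

# Known limitations

* Off-target counting is unweighted Hamming: no position-dependent
  (seed-region) penalties, no CFD/MIT-style aggregate score, no
  bulge/indel off-targets. A cleavage-probability scorer is a named
  extension point, not an implemented feature.
* Only the run's own PAM pattern qualifies off-target sites;
  alternate-PAM leakage (e.g. NAG for SpCas9) is not modeled.
* One transcript at a time: no isoform collapsing across a gene.
* The efficiency interface is linear position-features only; SVM or
  tree-ensemble models are out of scope by design.
* Primer design screens thermodynamics and geometry, not secondary
  structure or primer-dimer formation.
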