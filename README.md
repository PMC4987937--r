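# guideForge

CRISPR guide RNA design for arbitrary effectors: candidate enumeration
under degenerate PAMs, efficiency and self-complementarity scoring,
bounded-mismatch off-target counting, paired-nickase design, and
restriction-site / primer annotation — as an R package built on
Bioconductor infrastructure (Biostrings, GenomicRanges, rtracklayer).

## Who it is for

Anyone designing CRISPR knock-out, knock-in, nickase or
dCas9-activation/repression experiments who needs ranked spacer
candidates for a target region, with honest accounting of genomic
off-targets, on sequences they supply as FASTA (plus optional BED12 gene
models). The engine is effector-agnostic: PAMs are IUPAC patterns
anchored 3′ of the protospacer (Cas9-type) or 5′ (Cpf1-type), and spacer
length is free (≥ 10 nt), so truncated sgRNAs and new effectors work
unchanged.

## What it computes

For a target region scanned on both strands, every position where the
PAM pattern matches adjacent to a full-length protospacer becomes a
candidate. Each candidate gets:

- **GC content** of the spacer, flagged *ideal* in the inclusive window
  40–80 %.
- **PAM-proximal G** — whether position 20 (generalized: the final,
  PAM-adjacent base) is G; a classical proxy for activity of 3′-anchored
  effectors.
- **Self-complementarity** — the number of maximal duplexes of ≥ 4 bp
  the spacer can form with itself (loop ≥ 3 nt) or with the invariant
  sgRNA scaffold; stems impair loading into the effector complex.
- **Efficiency score** — a pluggable linear position-feature model
  s = β₀ + Σᵢ βᵢ·1[context(offsetᵢ) = kmerᵢ] over a context window
  (upstream flank | spacer | PAM | downstream flank, default 4+20+3+3),
  with identity or logistic link. Model files are plain TSV; published
  coefficient tables drop in unchanged.
- **Off-target counts MM0–MM3** — genomic sites with a valid PAM within
  Hamming distance 0–3 of the spacer (the biologically relevant range;
  deeper searches are refused). The search uses a seed-pigeonhole index
  — the spacer is split into 4 fragments, so any site within 3
  mismatches matches one fragment exactly — and is verified in tests
  against a naive full scan.
- For **nickase mode**: opposite-strand candidates in PAM-out
  orientation are paired when the gap between their PAM-distal
  protospacer edges is 10–31 bp (inclusive), and each pair's *paired*
  off-targets — elsewhere-in-genome half-site combinations that could
  jointly produce a double-strand break — are counted.
- **Restriction sites** (IUPAC motifs, both strands, uniqueness and
  cut-overlap flags for RFLP validation) and **flanking primers**
  (nearest-neighbor Tm, length/Tm/product-size constraints) for
  validation assays.

Candidates are ranked by specificity (MM0, MM1, MM2, MM3 ascending),
then efficiency, then self-complementarity, and colored green (best) to
red (worst: an additional exact-match locus exists).

## Worked example

```r
library(guideForge)

## a deterministic 10-kb synthetic genome with 3 planted target sites,
## one of which also has planted copies at 1 and 2 mismatches
fx  <- makeFixture(seed = 42, length = 10000, nGuides = 3,
                   offtargetMm = list(c(1, 2)))
res <- designGuides(fx$genome,
                    scoreModel = system.file("extdata", "example_model.tsv",
                                             package = "guideForge"))
as.data.frame(res$table[, c("id", "protospacer", "pam_seq", "gc_fraction",
                            "selfcomp", "efficiency", "mm1", "mm2", "color")])
```

```
             id          protospacer pam_seq gc_fraction selfcomp efficiency mm1 mm2 color
1 chr1_3316_fwd GCTCGTCTCGTATTACGTAC     TGG        0.50        5       0.65   0   0 amber
2 chr1_4988_fwd TTCGTACGTTTGAACTATTA     CGG        0.30        5       0.55   0   0 amber
3 chr1_8332_fwd TGCATCGCAGAATATACGAG     TGG        0.45        0       0.85   0   1 green
4 chr1_6660_fwd ATCATCGCAGAATGTACGAG     TGG        0.45        0       0.70   1   0 amber
5 chr1_1644_fwd ATCATCGCAGAATATACGAG     CGG        0.40        0       0.70   1   1 amber
```

Reading the table: the two spacers with empty mismatch buckets rank
first regardless of their lower efficiency scores — specificity
dominates the sort. Row 4 is the planted 1-mismatch copy of row 5's
spacer: each sees the other in its MM1 bucket. Row 3 ranks above row 4
because an MM2 hit is sorted after an MM1 hit. Colors follow the
documented policy: green needs MM0 = MM1 = 0, ideal GC and no stems;
rows 1–2 are amber because of scaffold stems (selfcomp > 0), rows 4–5
because they carry low-mismatch off-targets (its 40 % GC sits exactly
on the inclusive lower bound of the ideal window, which alone would not
demote it).

`writeOutputs(res$table, "out/")` writes `results.tsv` (documented
column order), `targets.bed` (BED6, score = rank) and `guides.fasta`.
A thin command-line wrapper is installed at
`system.file("scripts", "guideforge.R", package = "guideForge")`:

```sh
Rscript guideforge.R --fasta genome.fa --bed genes.bed --gene tx1 \
    --mode cds --effector SpCas9 --nickase --out results/
```

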