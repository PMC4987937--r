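test_that("a homopolymer G run yields forward candidates at every fit", {
  g <- toy_genome(c1 = strrep("G", 25))
  gs <- enumerateGuides(g, whole_ranges(g), pamSpec("NGG"),
                        guideLength = 20)
  df <- as.data.frame(gs)
  ## 20-mer + NGG (23 bp) fits at starts 1..3; no CC on the reverse
  expect_equal(df$start, 1:3)
  expect_true(all(df$strand == "+"))
})

test_that("a single planted site is recovered exactly once", {
  proto <- "ATCTGATCAGTCAGATCTAT"  # no GG/CC anywhere nearby
  g <- toy_genome(c1 = paste0("TATATATATA", proto, "AGG", "TATATATATA"))
  gs <- enumerateGuides(g, whole_ranges(g), pamSpec("NGG"),
                        guideLength = 20)
  expect_equal(length(gs), 1L)
  df <- as.data.frame(gs)
  expect_equal(df$strand, "+")
  expect_equal(df$protospacer, proto)
  expect_equal(df$pam_seq, "AGG")
  expect_equal(df$start, 11L)
  ## modeled blunt cut 3 bp 5' of the PAM
  expect_equal(df$cut_pos, df$end - 3L)
})

test_that("5'-anchored PAMs put the protospacer 3' of the PAM", {
  proto <- "ACGAAGTCGATCGATTCGAC"
  g <- toy_genome(c1 = paste0("GAGAGA", "TTTA", proto, "GAGAGA"))
  gs <- enumerateGuides(g, whole_ranges(g),
                        pamSpec("TTTN", anchor = "5prime"),
                        guideLength = 20)
  df <- as.data.frame(gs)
  fwd <- df[df$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$pam_seq, "TTTA")
  expect_equal(fwd$protospacer, proto)
  expect_equal(fwd$start, 11L)  # protospacer starts after the PAM
})

test_that("every candidate re-validates against the genome", {
  fx <- makeFixture(31, length = 4000, nGuides = 2, clean = FALSE)
  gs <- enumerateGuides(fx$genome, whole_ranges(fx$genome), fx$pam, 20)
  df <- as.data.frame(gs)
  for (i in seq_len(nrow(df))) {
    r <- GRanges(df$contig[i], IRanges::IRanges(df$start[i], df$end[i]),
                 strand = df$strand[i])
    expect_equal(extractRegion(fx$genome, r), df$protospacer[i])
  }
  expect_true(all(iupacMatch("NGG", df$pam_seq)))
  expect_true(all(nchar(df$protospacer) == 20L))
})

test_that("enumeration agrees with the expand-and-slide oracle", {
  for (seed in c(41, 42)) {
    fx <- makeFixture(seed, length = 2500, gc = 0.55, nGuides = 1,
                      clean = FALSE)
    for (spec in list(c("NGG", "3prime"), c("NNGRRT", "3prime"),
                      c("TTTN", "5prime"))) {
      pam <- pamSpec(spec[1], anchor = spec[2])
      gs <- enumerateGuides(fx$genome, whole_ranges(fx$genome), pam, 20)
      df <- as.data.frame(gs)
      orc <- oracle_sites(fx$genome, spec[1], spec[2], 20)
      expect_equal(nrow(df), nrow(orc))
      expect_equal(df$start, orc$start)
      expect_equal(df$strand, orc$strand)
      expect_equal(df$protospacer, orc$proto)
    }
  }
})

test_that("enumeration is strand-symmetric under genome reflection", {
  fx <- makeFixture(43, length = 2000, nGuides = 1, clean = FALSE)
  n <- Biostrings::width(fx$genome)[1]
  rcg <- Biostrings::DNAStringSet(
    structure(rc_chr(as.character(fx$genome[[1]])), names = "chr1"))
  gs1 <- as.data.frame(enumerateGuides(fx$genome, whole_ranges(fx$genome),
                                       fx$pam, 20))
  gs2 <- as.data.frame(enumerateGuides(rcg, whole_ranges(rcg),
                                       fx$pam, 20))
  ## reflect gs2 coordinates back onto the forward genome
  refl <- data.frame(start = n - gs2$end + 1L,
                     strand = ifelse(gs2$strand == "+", "-", "+"),
                     protospacer = gs2$protospacer)
  refl <- refl[order(refl$start, refl$strand), ]
  expect_equal(refl$start, gs1$start)
  expect_equal(refl$strand, gs1$strand)
  expect_equal(refl$protospacer, gs1$protospacer)
})

test_that("edge candidates keep full protospacer+PAM and pad context", {
  ## site flush against the contig start: no upstream context available
  g <- toy_genome(c1 = paste0("ATCTGATCAGTCAGATCTAT", "AGG", "TATATA"))
  gs <- enumerateGuides(g, whole_ranges(g), pamSpec("NGG"),
                        guideLength = 20)
  df <- as.data.frame(gs)
  expect_equal(df$start, 1L)
  expect_true(df$partial_context)
  ctx <- S4Vectors::mcols(guideRanges(gs))$context
  expect_equal(nchar(ctx), 30L)
  expect_equal(substr(ctx, 1, 4), "NNNN")
})

toy_model <- function() {
  ## + strand transcript on a 3 kb contig: exons 201-400, 801-1000,
  ## 1401-1600; CDS 301-1500
  ex <- GRanges("c1", IRanges::IRanges(c(201, 801, 1401),
                                       c(400, 1000, 1600)),
                strand = "+")
  new("GeneModel", name = "toy",
      txRegion = GRanges("c1", IRanges::IRanges(201, 1600),
                         strand = "+"),
      exons = ex,
      cds = GRanges("c1", IRanges::IRanges(301, 1500), strand = "+"),
      tss = 201L)
}

test_that("region modes resolve to the expected sub-regions", {
  m <- toy_model()
  whole <- resolveRegion(m, "whole")
  expect_equal(GenomicRanges::start(whole), 201L)
  expect_equal(GenomicRanges::end(whole), 1600L)

  cds <- resolveRegion(m, "cds")
  expect_equal(GenomicRanges::start(cds), c(301L, 801L, 1401L))
  expect_equal(GenomicRanges::end(cds), c(400L, 1000L, 1500L))

  utr5 <- resolveRegion(m, "utr5")
  expect_equal(GenomicRanges::start(utr5), 201L)
  expect_equal(GenomicRanges::end(utr5), 300L)
  utr3 <- resolveRegion(m, "utr3")
  expect_equal(GenomicRanges::start(utr3), 1501L)
  expect_equal(GenomicRanges::end(utr3), 1600L)

  ex2 <- resolveRegion(m, "exon", exonIndex = 2)
  expect_equal(GenomicRanges::start(ex2), 801L)
  expect_error(resolveRegion(m, "exon", exonIndex = 4), "out of range")

  prom <- resolveRegion(m, "promoter", promoterUp = 2000,
                        promoterDown = 500)
  expect_equal(GenomicRanges::start(prom), 1L)      # clipped at contig
  expect_equal(GenomicRanges::end(prom), 700L)      # tss + 500 - 1
})

test_that("splice mode returns flank windows at internal boundaries", {
  ## two-exon model, flank 20: one junction, two boundaries
  ex <- GRanges("c1", IRanges::IRanges(c(101, 301), c(200, 400)),
                strand = "+")
  m <- new("GeneModel", name = "two",
           txRegion = GRanges("c1", IRanges::IRanges(101, 400),
                              strand = "+"),
           exons = ex, cds = GRanges(), tss = 101L)
  sp <- resolveRegion(m, "splice", spliceFlank = 20)
  expect_equal(length(sp), 2L)
  expect_equal(GenomicRanges::width(sp), c(40L, 40L))
  ## donor boundary at exon1 end (200): window 181-220
  expect_equal(GenomicRanges::start(sp)[1], 181L)
  expect_equal(GenomicRanges::end(sp)[1], 220L)
  ## acceptor boundary at exon2 start (301): window 281-320
  expect_equal(GenomicRanges::start(sp)[2], 281L)
  expect_equal(GenomicRanges::end(sp)[2], 320L)
})

test_that("cds modes refuse non-coding models", {
  ex <- GRanges("c1", IRanges::IRanges(101, 400), strand = "+")
  nc <- new("GeneModel", name = "nc",
            txRegion = GRanges("c1", IRanges::IRanges(101, 400),
                               strand = "+"),
            exons = ex, cds = GRanges(), tss = 101L)
  expect_error(resolveRegion(nc, "cds"), "non-coding")
  expect_error(resolveRegion(nc, "utr5"), "non-coding")
})

test_that("overlapping regions de-duplicate candidates", {
  proto <- "ATCTGATCAGTCAGATCTAT"
  g <- toy_genome(c1 = paste0("TATATATATA", proto, "AGG", "TATATATATA"))
  rr <- GRanges("c1", IRanges::IRanges(c(1, 5), c(43, 43)))
  gs <- enumerateGuides(g, rr, pamSpec("NGG"), guideLength = 20)
  expect_equal(length(gs), 1L)
})
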