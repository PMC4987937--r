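## A hand-built 6-guide fixture exercising every ranking key.
rank_fixture <- function() {
  proto <- c(a = "ATCTGATCAGTCAGATCGCC",  # 45% GC, ends C
             b = "ATCTGATCAGTCAGATCGCG",
             c = "ATCTGATCAGTCAGATCGGG",
             d = "ATCTGATCAGTCAGATCGCA",
             e = "ATCTGATCAGTCAGATCGCT",
             f = "ATCTGATCAGTCAGATCGTT")
  gr <- GenomicRanges::GRanges("c1",
          IRanges::IRanges(seq(1, by = 100, length.out = 6), width = 20),
          strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = names(proto), protospacer = unname(proto),
    pam_seq = rep("AGG", 6), cut_pos = GenomicRanges::end(gr) - 3L,
    context = rep(strrep("A", 30), 6), pad_left = rep(0L, 6),
    pad_right = rep(0L, 6), partial_context = rep(FALSE, 6))
  gs <- new("GuideSet", guides = gr, pam = pamSpec("NGG"),
            guideLength = 20L, contextFlank = c(4L, 3L))
  scores <- S4Vectors::DataFrame(
    id = names(proto),
    gc_fraction = rep(0.5, 6),
    gc_ideal = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    pam_proximal_g = rep(FALSE, 6),
    selfcomp = c(0L, 0L, 0L, 0L, 0L, 1L),
    efficiency = c(0.9, 0.7, 0.7, 0.9, 0.8, 0.8),
    model_name = rep("t", 6))
  ot <- S4Vectors::DataFrame(
    mm0 = c(0L, 0L, 1L, 0L, 0L, 0L),
    mm1 = c(0L, 1L, 0L, 0L, 0L, 0L),
    mm2 = c(0L, 0L, 0L, 0L, 0L, 0L),
    mm3 = c(2L, 0L, 0L, 2L, 0L, 0L))
  list(gs = gs, scores = scores, ot = ot)
}

test_that("ranking follows the documented key and color policy", {
  fx <- rank_fixture()
  r <- rankGuides(fx$gs, fx$scores, fx$ot)
  ## hand-derived order:
  ##  e (0,0,0,0 eff .8), f (0,0,0,0 eff .8, selfcomp 1 loses to e),
  ##  a (0,0,0,2 eff .9 beats d by position), d, b (mm1), c (mm0)
  expect_equal(r$id, c("e", "f", "a", "d", "b", "c"))
  expect_equal(r$rank, 1:6)
  expect_equal(r$color[r$id == "c"], "red")      # mm0 > 0
  expect_equal(r$color[r$id == "e"], "amber")    # gc not ideal
  expect_equal(r$color[r$id == "f"], "amber")    # selfcomp > 0
  expect_equal(r$color[r$id == "b"], "amber")    # mm1 > 0
  expect_equal(r$color[r$id == "a"], "green")
  expect_equal(r$color[r$id == "d"], "green")
})

test_that("dominant mm0 key outranks everything else", {
  fx <- rank_fixture()
  ## two identical guides except mm0
  keep <- fx$scores$id %in% c("a", "c")
  r <- rankGuides(fx$gs[which(keep)], fx$scores[keep, ],
                  fx$ot[keep, ])
  expect_equal(r$id[1], "a")
  expect_equal(r$color, c("green", "red"))
})

test_that("outputs have the documented schema and are reproducible", {
  fx <- makeFixture(81, length = 5000, nGuides = 2,
                    offtargetMm = list(c(1)))
  res <- designGuides(fx$genome)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeOutputs(res$table, d1)
  writeOutputs(res$table, d2)
  for (f in c("results.tsv", "targets.bed", "guides.fasta")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  tab <- read.delim(file.path(d1, "results.tsv"))
  expect_equal(colnames(tab),
               c("id", "location", "strand", "protospacer", "pam",
                 "gc_pct", "selfcomp", "efficiency", "mm0", "mm1",
                 "mm2", "mm3", "color", "restriction_count",
                 "primer_left", "primer_right", "primer_product"))
  ## BED spans re-extract to each protospacer
  bed <- rtracklayer::import(file.path(d1, "targets.bed"))
  fa <- Biostrings::readDNAStringSet(file.path(d1, "guides.fasta"))
  for (i in seq_along(bed)) {
    expect_equal(extractRegion(fx$genome, bed[i]),
                 as.character(fa[[S4Vectors::mcols(bed)$name[i]]]))
  }
  ## ranks are a permutation
  expect_setequal(S4Vectors::mcols(bed)$score, seq_along(bed))
})

test_that("empty result sets write header-only outputs", {
  g <- toy_genome(c1 = strrep("AT", 200))
  res <- designGuides(g)
  d <- withr::local_tempdir()
  writeOutputs(res$table, d)
  expect_equal(length(readLines(file.path(d, "results.tsv"))), 1L)
  expect_equal(length(readLines(file.path(d, "guides.fasta"))), 0L)
})

test_that("fixtures are deterministic and self-consistent", {
  a <- makeFixture(91, length = 4000, nGuides = 2,
                   offtargetMm = list(c(1, 3)), nickaseOffsets = 20)
  b <- makeFixture(91, length = 4000, nGuides = 2,
                   offtargetMm = list(c(1, 3)), nickaseOffsets = 20)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  ## different seed, different genome
  c <- makeFixture(92, length = 4000, nGuides = 2,
                   offtargetMm = list(c(1, 3)), nickaseOffsets = 20)
  expect_false(identical(as.character(a$genome),
                         as.character(c$genome)))
  ## every truth row re-extracts from the genome
  for (i in seq_len(nrow(a$truth))) {
    r <- GRanges(a$truth$contig[i],
                 IRanges::IRanges(a$truth$start[i], a$truth$end[i]),
                 strand = a$truth$strand[i])
    expect_equal(extractRegion(a$genome, r), a$truth$protospacer[i])
  }
  ## written files are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  makeFixture(93, length = 2000, nGuides = 1, dir = d1)
  makeFixture(93, length = 2000, nGuides = 1, dir = d2)
  for (f in c("genome.fa", "truth.tsv", "features.bed"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("clean fixtures contain exactly the planted candidates", {
  fx <- makeFixture(94, length = 6000, nGuides = 2,
                    nickaseOffsets = c(15))
  gs <- enumerateGuides(fx$genome, whole_ranges(fx$genome), fx$pam, 20)
  df <- as.data.frame(gs)
  expect_equal(nrow(df), nrow(fx$truth))
  expect_setequal(paste(df$start, df$strand),
                  paste(fx$truth$start, fx$truth$strand))
  expect_setequal(df$protospacer, fx$truth$protospacer)
})

test_that("the pipeline ties all modules together", {
  fx <- makeFixture(95, length = 6000, nGuides = 2,
                    nickaseOffsets = c(20))
  model <- system.file("extdata", "example_model.tsv",
                       package = "guideForge")
  res <- designGuides(fx$genome, scoreModel = model, nickase = TRUE)
  expect_s4_class(res$guides, "GuideSet")
  expect_equal(nrow(res$table), length(res$guides))
  expect_true(all(!is.na(res$table$efficiency)))
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$offset, 20L)
  expect_equal(res$pairs$paired_offtargets, 0L)
  ## target restriction: only guides inside the window
  tgt <- sprintf("chr1:%d-%d", fx$truth$start[1] - 30L,
                 fx$truth$end[1] + 30L)
  res2 <- designGuides(fx$genome, target = tgt)
  expect_equal(nrow(res2$table), 1L)
  expect_equal(res2$table$start, fx$truth$start[1])
})
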