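test_that("gcFraction and the inclusive ideal window behave as specified", {
  expect_equal(gcFraction("GCGCGCGCGCGCGCGCGCGC"), 1.0)
  expect_false(gcIdeal(1.0))
  expect_equal(gcFraction("ATATATATATATATATATAT"), 0.0)
  expect_false(gcIdeal(0.0))
  g8 <- paste0(strrep("G", 8), strrep("A", 12))     # 8/20 = 40%
  expect_equal(gcFraction(g8), 0.40)
  expect_true(gcIdeal(g8))                          # boundary inclusive
  g16 <- paste0(strrep("G", 16), strrep("A", 4))    # 80%
  expect_true(gcIdeal(g16))
  expect_error(gcFraction("ACGN"), "ACGT")
  ## invariant under reversal
  set.seed(21)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    rev <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(gcFraction(s), gcFraction(rev))
  }
})

test_that("PAM-proximal G flag reads only the final spacer base", {
  expect_true(pamProximalG(paste0(strrep("A", 19), "G")))
  expect_false(pamProximalG(paste0(strrep("A", 19), "A")))
  ## truncated 18-nt guide: position 18 is PAM-proximal
  expect_true(pamProximalG(paste0(strrep("A", 17), "G")))
  ## not applicable for 5'-anchored effectors
  expect_true(is.na(pamProximalG("ACGTACGTACGTACGTACGT",
                                 anchor = "5prime")))
})

test_that("selfComp counts maximal intramolecular stems", {
  ## single 4-bp stem with a 12-nt loop
  expect_equal(selfComp(paste0("GGGG", strrep("A", 12), "CCCC"),
                        backbone = ""), 1L)
  ## no 4-mer reverse-complemented elsewhere in this guide
  expect_equal(selfComp("ACGACGACGACGACGACGAC", backbone = ""), 0L)
  ## 3-bp repeat does not register; 4-bp does
  expect_equal(selfComp(paste0("GGG", strrep("A", 12), "CCC"),
                        backbone = ""), 0L)
  ## a 5-bp stem counts once (maximal), not as two 4-bp windows
  expect_equal(selfComp(paste0("CCCCG", strrep("A", 10), "CGGGG"),
                        backbone = ""), 1L)
  ## shifted pairing registers of a homopolymeric block are distinct
  ## maximal duplexes and each counts
  expect_equal(selfComp(paste0("GGGGG", strrep("A", 10), "CCCCC"),
                        backbone = ""), 3L)
  ## loop shorter than minLoop suppresses the stem
  expect_equal(selfComp(paste0("GGGG", "AA", "CCCC"), backbone = ""), 0L)
  expect_error(selfComp("ACGT", minStem = 1), "minStem")
})

test_that("selfComp counts guide-backbone duplexes", {
  guide <- paste0("TTAGCT", strrep("A", 14))
  expect_gte(selfComp(guide, backbone = "CCCAGCTAACCC"), 1L)
  ## short guide with empty backbone can never form a stem
  expect_equal(selfComp("ACGTACGTAC", backbone = ""), 0L)
})

test_that("selfComp matches the brute-force duplex oracle", {
  set.seed(22)
  bb <- "GTTTTAGAGCTAGAAATAGC"
  for (i in 1:40) {
    g <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    expect_equal(selfComp(g, backbone = ""), oracle_stems(g),
                 info = g)
    expect_equal(selfComp(g, backbone = bb),
                 oracle_stems(g, backbone = bb), info = g)
    expect_equal(selfComp(g, backbone = bb, wobble = TRUE),
                 oracle_stems(g, backbone = bb, wobble = TRUE), info = g)
  }
})

test_that("wobble pairing never decreases the stem count", {
  set.seed(23)
  for (i in 1:25) {
    g <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    expect_gte(selfComp(g, wobble = TRUE), selfComp(g, wobble = FALSE))
  }
})

test_that("efficiency model files load, validate and round-trip", {
  path <- system.file("extdata", "example_model.tsv",
                      package = "guideForge")
  m <- loadEfficiencyModel(path)
  expect_equal(m@window, c(4L, 20L, 3L, 3L))
  expect_equal(nrow(m@features), 5L)
  expect_equal(m@link, "identity")

  out <- tempfile(fileext = ".tsv")
  writeEfficiencyModel(m, out)
  m2 <- loadEfficiencyModel(out)
  expect_equal(m2@features$weight, m@features$weight)
  expect_equal(m2@intercept, m@intercept)
  unlink(out)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("# name=bad", "# window=4,20,3,3", "# link=identity",
               "# intercept=0", "31\tA\t1.0"), bad)
  expect_error(loadEfficiencyModel(bad), "line 5")
  writeLines(c("# name=bad", "# window=4,20,3,3", "# link=identity",
               "# intercept=0", "1\tA\tx"), bad)
  expect_error(loadEfficiencyModel(bad), "non-numeric")
  unlink(bad)
})

test_that("efficiencyScore is the feature-matched linear predictor", {
  mk <- function(feats, link = "identity", intercept = 0)
    new("EfficiencyModel", name = "t", window = c(0L, 4L, 0L, 0L),
        intercept = intercept, features = feats, link = link)
  one <- data.frame(offset = 1L, kmer = "A", weight = 1.0)
  expect_equal(efficiencyScore("ACGT", mk(one)), 1.0)
  expect_equal(efficiencyScore("CCGT", mk(one)), 0.0)
  expect_equal(efficiencyScore("ACGT", mk(one, link = "logistic")),
               1 / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("efficiencyScore equals a brute-force matcher on random 30-mers", {
  set.seed(24)
  feats <- data.frame(
    offset = sample(1:29, 12, replace = TRUE),
    kmer = vapply(1:12, function(i)
      paste(sample(c("A", "C", "G", "T"), sample(1:2, 1), TRUE),
            collapse = ""), character(1)),
    weight = round(rnorm(12), 3))
  feats$offset <- pmin(feats$offset, 30L - nchar(feats$kmer) + 1L)
  m <- new("EfficiencyModel", name = "rand", window = c(4L, 20L, 3L, 3L),
           intercept = 0.7, features = feats, link = "identity")
  for (i in 1:1000) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    want <- 0.7
    for (j in seq_len(nrow(feats))) {
      obs <- substr(ctx, feats$offset[j],
                    feats$offset[j] + nchar(feats$kmer[j]) - 1L)
      if (obs == feats$kmer[j]) want <- want + feats$weight[j]
    }
    expect_equal(efficiencyScore(ctx, m), want)
  }
})

test_that("models refuse mismatched window geometry and padded features", {
  g <- toy_genome(c1 = paste0("ATCTGATCAGTCAGATCTAT", "AGG", "TATATA"))
  gs <- enumerateGuides(g, whole_ranges(g), pamSpec("NGG"),
                        guideLength = 20)   # partial 5' context
  m <- loadEfficiencyModel(system.file("extdata", "example_model.tsv",
                                       package = "guideForge"))
  ## feature at offset 1 reads the N-padded upstream flank -> NA
  expect_true(is.na(efficiencyScore(gs, m)))
  short <- new("EfficiencyModel", name = "s", window = c(4L, 18L, 3L, 3L),
               intercept = 0, features = m@features[0, ],
               link = "identity")
  expect_error(efficiencyScore(gs, short), "18-nt")
})

test_that("scoreGuides assembles the full metric set", {
  fx <- makeFixture(25, length = 3000, nGuides = 2)
  gs <- enumerateGuides(fx$genome, whole_ranges(fx$genome), fx$pam, 20)
  sc <- scoreGuides(gs)
  expect_equal(nrow(sc), length(gs))
  expect_true(all(sc$gc_fraction >= 0 & sc$gc_fraction <= 1))
  expect_true(all(sc$selfcomp >= 0))
  expect_true(all(is.na(sc$efficiency)))  # no model supplied
})
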