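## Independent brute-force oracles used to cross-check the package's
## implementations on small inputs.  These deliberately avoid the
## package's internal helpers: matching is done through expanded
## concrete sequences and plain string comparison.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

toy_genome <- function(...) Biostrings::DNAStringSet(c(...))

whole_ranges <- function(genome)
  GenomicRanges::GRanges(names(genome),
                         IRanges::IRanges(1L, Biostrings::width(genome)))

rc_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## All (start, strand) protospacer positions where guideLen-mer + PAM
## occurs, by sliding every concrete expansion of the PAM over both
## strands with plain substring equality.
oracle_sites <- function(genome, pattern, anchor, guideLen) {
  pams <- guideForge::expandIupac(pattern)
  m <- nchar(pattern)
  out <- list()
  for (ct in names(genome)) {
    fwd <- as.character(genome[[ct]])
    n <- nchar(fwd)
    for (st in c("+", "-")) {
      s <- if (st == "+") fwd else rc_chr(fwd)
      T <- guideLen + m
      for (i in seq_len(max(0L, n - T + 1L))) {
        win <- substr(s, i, i + T - 1L)
        if (grepl("N", win, fixed = TRUE)) next
        pamseq <- if (anchor == "3prime")
          substr(win, guideLen + 1L, T) else substr(win, 1L, m)
        if (!pamseq %in% pams) next
        proto <- if (anchor == "3prime") substr(win, 1L, guideLen)
                 else substr(win, m + 1L, T)
        protoRel <- if (anchor == "3prime") i else i + m
        ## convert strand-local protospacer start to + coordinates
        start <- if (st == "+") protoRel
                 else n - (protoRel + guideLen - 1L) + 1L
        out[[length(out) + 1L]] <- data.frame(
          contig = ct, strand = st, start = start, proto = proto,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), strand = character(0),
                      start = integer(0), proto = character(0)))
  df <- do.call(rbind, out)
  df[order(df$contig, df$start, df$strand), , drop = FALSE]
}

hamming <- function(a, b)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

## Off-target hits of one guide against an oracle_sites table.
oracle_offtargets <- function(guideProto, sites, maxMm, selfContig,
                              selfStart, selfStrand) {
  mm <- vapply(sites$proto, hamming, integer(1), a = guideProto,
               USE.NAMES = FALSE)
  keep <- mm <= maxMm &
    !(sites$contig == selfContig & sites$start == selfStart &
        sites$strand == selfStrand)
  cbind(sites[keep, c("contig", "strand", "start")], mm = mm[keep])
}

## Count maximal self-complementary stems by examining every candidate
## duplex (i, j, len) directly.
oracle_stems <- function(guide, backbone = "", minStem = 4L,
                         minLoop = 3L, wobble = FALSE) {
  pairs <- function(a, b) {
    wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
    if (wobble) wc <- wc | (a == "G" & b == "T") | (a == "T" & b == "G")
    wc
  }
  g <- strsplit(guide, "")[[1]]
  n <- length(g)
  count <- 0L
  ## intramolecular: pairing (x, y), x < y, run extends (x+1, y-1)
  for (x in seq_len(n)) for (y in seq_len(n)) {
    if (y <= x) next
    if (!pairs(g[x], g[y]) || y - x - 1 < minLoop) next
    ## must be the OUTERMOST pair of a maximal run
    if (x > 1 && y < n && pairs(g[x - 1], g[y + 1]) &&
        (y + 1) - (x - 1) - 1 >= minLoop) next
    len <- 0L
    while (x + len < y - len && pairs(g[x + len], g[y - len]) &&
           (y - len) - (x + len) - 1 >= minLoop) len <- len + 1L
    if (len >= minStem) count <- count + 1L
  }
  if (nzchar(backbone)) {
    b <- strsplit(backbone, "")[[1]]
    nb <- length(b)
    for (x in seq_len(n)) for (y in seq_len(nb)) {
      if (!pairs(g[x], b[y])) next
      if (x > 1 && y < nb && pairs(g[x - 1], b[y + 1])) next
      len <- 0L
      while (x + len <= n && y - len >= 1 && pairs(g[x + len], b[y - len]))
        len <- len + 1L
      if (len >= minStem) count <- count + 1L
    }
  }
  count
}

## Simple restriction-site oracle: expand each motif and gregexpr both
## strands.
oracle_restriction <- function(amplicon, name, motif) {
  hitsOf <- function(pat) {
    n <- nchar(amplicon); w <- nchar(pat)
    if (w > n) return(integer(0))
    expanded <- guideForge::expandIupac(pat)
    which(vapply(seq_len(n - w + 1L), function(i)
      substr(amplicon, i, i + w - 1L) %in% expanded, logical(1)))
  }
  fwd <- hitsOf(motif)
  rcm <- rc_chr_iupac(motif)
  rev <- if (identical(rcm, motif)) integer(0) else hitsOf(rcm)
  list(fwd = fwd, rev = rev)
}

rc_chr_iupac <- function(s) guideForge::revcomp(s)
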