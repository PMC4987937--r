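#' @include AllClasses.R AllGenerics.R iupac.R seqio.R
NULL

## Scan regions on both strands for PAM-adjacent guide-length windows.
## Returns a data.frame (contig, strand, start, end, site_start,
## site_end, proto, pam_seq): proto/pam strings are 5'->3' in guide
## orientation; start/end span the protospacer, site_* span
## protospacer+PAM on the reference.  Protospacer and PAM must lie fully
## inside the region; windows containing N never match (the composite
## pattern carries N at every protospacer position, and genomic N
## matches no code).
#' @noRd
.scanSites <- function(genome, regions, pam, guideLen) {
  L <- as.integer(guideLen)
  m <- nchar(pam@pattern)
  encPam <- .encodePattern(pam@pattern)
  encPamRC <- .encodePattern(revcomp(pam@pattern))
  protoN <- rep(15L, L)
  if (pam@anchor == "3prime") {
    fwdPat <- c(protoN, encPam);   fwdOff <- 0L
    revPat <- c(encPamRC, protoN); revOff <- m
  } else {
    fwdPat <- c(encPam, protoN);   fwdOff <- m
    revPat <- c(protoN, encPamRC); revOff <- 0L
  }
  res <- list()
  for (i in seq_along(regions)) {
    contig <- as.character(GenomicRanges::seqnames(regions))[i]
    if (!contig %in% names(genome))
      stop("contig '", contig, "' not present in genome", call. = FALSE)
    rs <- GenomicRanges::start(regions)[i]
    re <- GenomicRanges::end(regions)[i]
    n <- length(genome[[contig]])
    if (rs < 1L || re > n)
      stop("region ", contig, ":", rs, "-", re, " out of bounds (contig ",
           "length ", n, ")", call. = FALSE)
    enc <- .encodeSubject(as.character(
      Biostrings::subseq(genome[[contig]], rs, re)))
    for (st in c("+", "-")) {
      hits <- .scanEncoded(enc, if (st == "+") fwdPat else revPat)
      if (!length(hits)) next
      off <- if (st == "+") fwdOff else revOff
      ps <- rs + hits - 1L + off
      res[[length(res) + 1L]] <- data.frame(
        contig = contig, strand = st,
        start = ps, end = ps + L - 1L,
        site_start = rs + hits - 1L,
        site_end = rs + hits - 1L + L + m - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(contig = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      site_start = integer(0), site_end = integer(0),
                      proto = character(0), pam_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, res)
  df <- df[!duplicated(df[c("contig", "start", "strand")]), , drop = FALSE]
  df <- df[order(df$contig, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  ## sequence strings, vectorized per contig
  df$proto <- NA_character_
  df$pam_seq <- NA_character_
  for (contig in unique(df$contig)) {
    sel <- df$contig == contig
    cs <- as.character(genome[[contig]])
    proto <- substring(cs, df$start[sel], df$end[sel])
    pamL <- df$start[sel] == df$site_start[sel]  # proto on left of site
    pam_s <- ifelse(pamL, df$end[sel] + 1L, df$site_start[sel])
    pam_e <- ifelse(pamL, df$site_end[sel], df$start[sel] - 1L)
    pamstr <- substring(cs, pam_s, pam_e)
    neg <- df$strand[sel] == "-"
    if (any(neg)) {
      proto[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(proto[neg])))
      pamstr[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(pamstr[neg])))
    }
    df$proto[sel] <- proto
    df$pam_seq[sel] <- pamstr
  }
  df
}

#' Enumerate guide candidates in target regions
#'
#' Scans both strands of the given regions for every position where the
#' PAM pattern matches adjacent to a full-length protospacer, with both
#' protospacer and PAM fully inside the region.  Overlapping candidates
#' are all kept; duplicates arising from overlapping regions are
#' de-duplicated by (contig, protospacer start, strand), and the result
#' is in deterministic (contig, start, strand) order.  Candidates whose
#' protospacer or PAM contains \code{N} are skipped.  The scoring
#' context window may extend beyond the region and is N-padded (with
#' \code{partial_context = TRUE}) where it runs off the contig.
#'
#' @param genome Named \code{DNAStringSet} (see
#'   \code{\link{readGenomeFasta}}).
#' @param regions \code{GRanges} of target regions (1-based inclusive);
#'   strand is ignored -- both strands are always scanned.
#' @param pam A \linkS4class{PamSpec} or \linkS4class{EffectorPreset}.
#' @param guideLength Spacer length in nt (>= 10); defaults to the
#'   preset's length when \code{pam} is an \linkS4class{EffectorPreset}.
#' @param contextFlank Integer pair: context bases kept 5' and 3' of the
#'   protospacer+PAM block in guide orientation (default \code{c(4, 3)},
#'   i.e. a 30-mer for 20-nt guides with a 3-nt PAM).
#' @param cutOffset Modeled cut distance in bp from the PAM-proximal
#'   protospacer end; defaults to the preset's value, else 3 for
#'   3'-anchored and 18 for 5'-anchored PAMs.
#' @return A \linkS4class{GuideSet}.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "TTTTACGTACGTACGTACGTACGTAGGTTTT"))
#' gs <- enumerateGuides(g, GenomicRanges::GRanges("chr", IRanges::IRanges(1, 31)),
#'                       pamSpec("NGG"), guideLength = 20)
#' protospacers(gs)
#' @export
enumerateGuides <- function(genome, regions, pam, guideLength = NULL,
                            contextFlank = c(4L, 3L), cutOffset = NULL) {
  if (is(pam, "EffectorPreset")) {
    if (is.null(guideLength)) guideLength <- pam@guideLength
    if (is.null(cutOffset)) cutOffset <- pam@cutOffset
    pam <- pam@pam
  }
  if (is.null(guideLength))
    stop("'guideLength' is required when 'pam' is a PamSpec", call. = FALSE)
  guideLength <- as.integer(guideLength)
  if (guideLength < 10L)
    stop("'guideLength' must be >= 10", call. = FALSE)
  if (is.null(cutOffset))
    cutOffset <- if (pam@anchor == "3prime") 3L else 18L
  cutOffset <- as.integer(cutOffset)
  contextFlank <- as.integer(contextFlank)

  df <- .scanSites(genome, regions, pam, guideLength)
  gr <- .sitesToGuides(df, genome, pam, guideLength, contextFlank,
                       cutOffset)
  new("GuideSet", guides = gr, pam = pam, guideLength = guideLength,
      contextFlank = contextFlank)
}

## Build the GuideSet GRanges from a .scanSites data.frame.
#' @noRd
.sitesToGuides <- function(df, genome, pam, guideLength, contextFlank,
                           cutOffset) {
  if (nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      id = character(0), protospacer = character(0),
      pam_seq = character(0), cut_pos = integer(0),
      context = character(0), pad_left = integer(0),
      pad_right = integer(0), partial_context = logical(0))
    return(gr)
  }
  neg <- df$strand == "-"
  ## cut position: reference base after which the cut falls (+ strand
  ## numbering), cutOffset bp from the PAM-proximal protospacer end
  pamProxLeft <- xor(neg, pam@anchor == "5prime")
  cut_pos <- ifelse(pamProxLeft, df$start + cutOffset - 1L,
                    df$end - cutOffset)
  ## context window: contextFlank[1] 5' and contextFlank[2] 3' of the
  ## protospacer+PAM block in guide orientation
  gl <- ifelse(neg, contextFlank[2L], contextFlank[1L])  # genomic-left ext
  gr_ <- ifelse(neg, contextFlank[1L], contextFlank[2L])
  clen <- vapply(df$contig, function(ct) length(genome[[ct]]), integer(1L))
  availL <- pmin(gl, df$site_start - 1L)
  availR <- pmin(gr_, clen - df$site_end)
  ctx <- character(nrow(df))
  for (contig in unique(df$contig)) {
    sel <- df$contig == contig
    cs <- as.character(genome[[contig]])
    ctx[sel] <- substring(cs, df$site_start[sel] - availL[sel],
                          df$site_end[sel] + availR[sel])
  }
  if (any(neg))
    ctx[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(ctx[neg])))
  padGL <- gl - availL
  padGR <- gr_ - availR
  pad_left <- ifelse(neg, padGR, padGL)    # guide-orientation 5' pad
  pad_right <- ifelse(neg, padGL, padGR)
  ctx <- paste0(strrep("N", pad_left), ctx, strrep("N", pad_right))
  gr <- GenomicRanges::GRanges(df$contig,
          IRanges::IRanges(df$start, df$end), strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = sprintf("%s_%d_%s", df$contig, df$start,
                 ifelse(neg, "rev", "fwd")),
    protospacer = df$proto, pam_seq = df$pam_seq,
    cut_pos = as.integer(cut_pos), context = ctx,
    pad_left = as.integer(pad_left), pad_right = as.integer(pad_right),
    partial_context = pad_left + pad_right > 0L)
  gr
}

#' Resolve a region mode against a gene model
#'
#' Translates a targeting mode into concrete genomic regions on a
#' \linkS4class{GeneModel}: \code{"whole"} (transcript span),
#' \code{"cds"} (exonic coding sequence), \code{"utr5"}/\code{"utr3"}
#' (exonic untranslated regions), \code{"splice"} (windows of
#' \code{spliceFlank} bp on each side of every internal exon boundary),
#' \code{"exon"} (the \code{exonIndex}-th exon in transcript 5'->3'
#' order) and \code{"promoter"} (\code{promoterUp} bp upstream to
#' \code{promoterDown} bp downstream of the TSS, strand-aware).
#' Defaults: splice flank 20 bp, promoter window 2000 bp up / 500 bp
#' down.  Results are reduced to disjoint regions, clipped to the contig
#' when \code{genome} is supplied.
#'
#' @param model A \linkS4class{GeneModel}.
#' @param mode One of \code{"whole"}, \code{"cds"}, \code{"utr5"},
#'   \code{"utr3"}, \code{"splice"}, \code{"exon"}, \code{"promoter"}.
#' @param exonIndex Exon number (transcript order) for \code{mode="exon"}.
#' @param spliceFlank Half-window around internal exon boundaries, bp.
#' @param promoterUp,promoterDown Promoter window extent, bp.
#' @param genome Optional \code{DNAStringSet} used to clip at contig ends.
#' @return \code{GRanges} of disjoint target regions.
#' @export
resolveRegion <- function(model,
                          mode = c("whole", "cds", "utr5", "utr3",
                                   "splice", "exon", "promoter"),
                          exonIndex = NULL, spliceFlank = 20L,
                          promoterUp = 2000L, promoterDown = 500L,
                          genome = NULL) {
  mode <- match.arg(mode)
  tx <- model@txRegion
  contig <- as.character(GenomicRanges::seqnames(tx))
  strand <- as.character(GenomicRanges::strand(tx))
  needCds <- function() {
    if (length(model@cds) == 0L)
      stop("mode '", mode, "' requires a CDS, but gene model '",
           model@name, "' has none (non-coding record)", call. = FALSE)
  }
  ex <- model@exons
  out <- switch(mode,
    whole = GenomicRanges::granges(tx),
    cds = {
      needCds()
      GenomicRanges::intersect(GenomicRanges::granges(ex),
                               GenomicRanges::granges(model@cds),
                               ignore.strand = TRUE)
    },
    utr5 = , utr3 = {
      needCds()
      cs <- GenomicRanges::start(model@cds)
      ce <- GenomicRanges::end(model@cds)
      upstreamSide <- (mode == "utr5") == (strand == "+")
      span <- if (upstreamSide) {
        if (cs <= GenomicRanges::start(tx)) GenomicRanges::GRanges()
        else GenomicRanges::GRanges(contig,
               IRanges::IRanges(GenomicRanges::start(tx), cs - 1L))
      } else {
        if (ce >= GenomicRanges::end(tx)) GenomicRanges::GRanges()
        else GenomicRanges::GRanges(contig,
               IRanges::IRanges(ce + 1L, GenomicRanges::end(tx)))
      }
      if (length(span) == 0L) GenomicRanges::GRanges()
      else GenomicRanges::intersect(GenomicRanges::granges(ex), span,
                                    ignore.strand = TRUE)
    },
    splice = {
      if (length(ex) < 2L)
        stop("mode 'splice' needs at least two exons; gene model '",
             model@name, "' has ", length(ex), call. = FALSE)
      stopifnot(spliceFlank >= 1L)
      k <- length(ex)
      donors <- GenomicRanges::end(ex)[-k]       # exon end | intron
      acceptors <- GenomicRanges::start(ex)[-1L] # intron | exon start
      GenomicRanges::GRanges(contig, IRanges::IRanges(
        start = c(donors - spliceFlank + 1L, acceptors - spliceFlank),
        end = c(donors + spliceFlank, acceptors + spliceFlank - 1L)))
    },
    exon = {
      if (is.null(exonIndex))
        stop("mode 'exon' requires 'exonIndex'", call. = FALSE)
      if (exonIndex < 1L || exonIndex > length(ex))
        stop("exonIndex ", exonIndex, " out of range (transcript has ",
             length(ex), " exons)", call. = FALSE)
      i <- if (strand == "-") length(ex) - exonIndex + 1L else exonIndex
      GenomicRanges::granges(ex[i])
    },
    promoter = {
      stopifnot(promoterUp >= 1L, promoterDown >= 1L)
      t <- model@tss
      if (strand == "-")
        GenomicRanges::GRanges(contig,
          IRanges::IRanges(t - promoterDown + 1L, t + promoterUp))
      else
        GenomicRanges::GRanges(contig,
          IRanges::IRanges(t - promoterUp, t + promoterDown - 1L))
    })
  out <- GenomicRanges::reduce(out)
  if (length(out)) {
    GenomicRanges::start(out) <- pmax(1L, GenomicRanges::start(out))
    if (!is.null(genome) && contig %in% names(genome))
      GenomicRanges::end(out) <-
        pmin(length(genome[[contig]]), GenomicRanges::end(out))
  }
  out
}
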