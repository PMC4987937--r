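#' @include AllClasses.R AllGenerics.R iupac.R enumerate.R
NULL

#' Build a seed-hashed index of candidate off-target sites
#'
#' Enumerates every PAM-adjacent guide-length window on both strands of
#' the genome (sites containing N are skipped; the PAM must satisfy the
#' degenerate pattern exactly) and hashes each site under
#' \code{nSeeds} contiguous spacer fragments.  By the pigeonhole
#' principle a site within \code{nSeeds - 1} mismatches of a query
#' matches at least one fragment exactly, so lookups retrieve a small
#' candidate set which is then verified by full Hamming comparison.
#' Spacers shorter than \code{2 * nSeeds} cannot be split into usable
#' fragments; the index then falls back to verifying every site
#' (a notice is emitted).
#'
#' @param genome Named \code{DNAStringSet}.
#' @param pam \linkS4class{PamSpec} or \linkS4class{EffectorPreset}.
#' @param guideLength Spacer length to index (defaults to the preset's).
#' @param nSeeds Number of seed fragments (default 4: supports up to 3
#'   mismatches).
#' @return A \linkS4class{SiteIndex}.
#' @export
buildSiteIndex <- function(genome, pam, guideLength = NULL, nSeeds = 4L) {
  if (is(pam, "EffectorPreset")) {
    if (is.null(guideLength)) guideLength <- pam@guideLength
    pam <- pam@pam
  }
  guideLength <- as.integer(guideLength)
  nSeeds <- as.integer(nSeeds)
  regions <- GenomicRanges::GRanges(names(genome),
    IRanges::IRanges(1L, Biostrings::width(genome)))
  sites <- .scanSites(genome, regions, pam, guideLength)
  naive <- guideLength < 2L * nSeeds
  tab <- new.env(hash = TRUE, parent = emptyenv())
  bounds <- matrix(integer(0), 0L, 2L)
  if (!naive && nrow(sites)) {
    cuts <- floor(seq(0L, guideLength, length.out = nSeeds + 1L))
    bounds <- cbind(cuts[-(nSeeds + 1L)] + 1L, cuts[-1L])
    for (s in seq_len(nSeeds)) {
      keys <- paste0(s, "_",
                     substring(sites$proto, bounds[s, 1L], bounds[s, 2L]))
      byKey <- split(seq_len(nrow(sites)), keys)
      for (k in names(byKey)) {
        prev <- tab[[k]]
        tab[[k]] <- if (is.null(prev)) byKey[[k]] else c(prev, byKey[[k]])
      }
    }
  } else if (naive) {
    message("guide length ", guideLength, " too short for ", nSeeds,
            " seeds; index will verify all sites (naive fallback)")
  }
  new("SiteIndex", sites = sites, pam = pam, guideLength = guideLength,
      nSeeds = nSeeds, seedBounds = bounds, table = tab, naive = naive)
}

## Verify candidate site rows against one guide; returns a GRanges of
## hits with mismatch annotations, in (contig, start, strand) order.
#' @noRd
.verifyHits <- function(guideProto, siteRows, maxMm, selfContig,
                        selfStart, selfStrand, mat = NULL) {
  L <- nchar(guideProto)
  emptyHits <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      mismatches = integer(0),
      mismatch_positions = IRanges::IntegerList(),
      pam_seq = character(0))
    gr
  }
  if (nrow(siteRows) == 0L) return(emptyHits())
  gch <- strsplit(guideProto, "", fixed = TRUE)[[1L]]
  if (is.null(mat))
    mat <- matrix(unlist(strsplit(siteRows$proto, "", fixed = TRUE)),
                  nrow = L)
  neq <- mat != gch
  mm <- colSums(neq)
  keep <- mm <= maxMm &
    !(siteRows$contig == selfContig & siteRows$start == selfStart &
        siteRows$strand == selfStrand)
  if (!any(keep)) return(emptyHits())
  siteRows <- siteRows[keep, , drop = FALSE]
  mmk <- as.integer(mm[keep])
  pos <- lapply(which(keep), function(j) which(neq[, j]))
  gr <- GenomicRanges::GRanges(siteRows$contig,
          IRanges::IRanges(siteRows$start, siteRows$end),
          strand = siteRows$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    mismatches = mmk,
    mismatch_positions = IRanges::IntegerList(pos),
    pam_seq = siteRows$pam_seq)
  gr
}

## GRangesList construction requires identical seqlevels across
## elements; harmonize them to the sorted union first.
#' @noRd
.asGRangesList <- function(lst) {
  lev <- sort(unique(unlist(lapply(lst, GenomeInfoDb::seqlevels))))
  lst <- lapply(lst, function(x) {
    GenomeInfoDb::seqlevels(x) <- lev
    x
  })
  GenomicRanges::GRangesList(lst)
}

#' Find bounded-Hamming off-targets for guide candidates
#'
#' Returns every genomic site with a valid PAM whose protospacer differs
#' from the guide's at no more than \code{maxMm} positions, on either
#' strand.  Mismatches are counted over the protospacer only; the PAM
#' must satisfy the run's degenerate pattern (a site with a
#' non-matching PAM is not an off-target at any distance).  The guide's
#' own locus -- same contig, start and strand -- is excluded, so a
#' second exact copy elsewhere counts as an mm0 off-target.  Searches
#' beyond three mismatches are refused: predicted sites at four or more
#' mismatches are almost never cleaved and would swamp the report.
#'
#' @param gs A \linkS4class{GuideSet}.
#' @param index A \linkS4class{SiteIndex} built with the same PAM and
#'   guide length.
#' @param maxMm Maximum mismatches, 0-3 (default 3).
#' @return \code{GRangesList}, one element per guide (named by id), each
#'   a \code{GRanges} of hits with metadata \code{mismatches},
#'   \code{mismatch_positions} (1-based guide positions),
#'   \code{pam_seq}, in deterministic (contig, start, strand) order.
#' @export
findOfftargets <- function(gs, index, maxMm = 3L) {
  stopifnot(is(gs, "GuideSet"), is(index, "SiteIndex"))
  maxMm <- as.integer(maxMm)
  if (maxMm < 0L) stop("'maxMm' must be >= 0", call. = FALSE)
  if (maxMm > 3L)
    stop("off-target search is capped at 3 mismatches", call. = FALSE)
  if (index@guideLength != gs@guideLength)
    stop("index was built for ", index@guideLength, "-nt guides; ",
         "candidates are ", gs@guideLength, " nt", call. = FALSE)
  if (!index@naive && maxMm > index@nSeeds - 1L)
    stop("index with ", index@nSeeds, " seeds supports at most ",
         index@nSeeds - 1L, " mismatches", call. = FALSE)
  g <- gs@guides
  out <- lapply(seq_along(g), function(i) {
    proto <- S4Vectors::mcols(g)$protospacer[i]
    if (index@naive) {
      cand <- seq_len(nrow(index@sites))
    } else {
      cand <- integer(0)
      for (s in seq_len(index@nSeeds)) {
        key <- paste0(s, "_", substring(proto, index@seedBounds[s, 1L],
                                        index@seedBounds[s, 2L]))
        cand <- c(cand, index@table[[key]])
      }
      cand <- sort(unique(cand))
    }
    .verifyHits(proto, index@sites[cand, , drop = FALSE], maxMm,
                as.character(GenomicRanges::seqnames(g))[i],
                GenomicRanges::start(g)[i],
                as.character(GenomicRanges::strand(g))[i])
  })
  names(out) <- S4Vectors::mcols(g)$id
  .asGRangesList(out)
}

#' @rdname findOfftargets
#' @details \code{findOfftargetsNaive} is the reference implementation:
#'   a full scan that compares every PAM-valid window in the genome
#'   against each guide without any seed filtering.  It is used as the
#'   equivalence oracle for the indexed search and as the fallback for
#'   very short spacers.
#' @param genome Named \code{DNAStringSet} (naive variant only).
#' @export
findOfftargetsNaive <- function(gs, genome, maxMm = 3L) {
  stopifnot(is(gs, "GuideSet"))
  maxMm <- as.integer(maxMm)
  if (maxMm > 3L)
    stop("off-target search is capped at 3 mismatches", call. = FALSE)
  regions <- GenomicRanges::GRanges(names(genome),
    IRanges::IRanges(1L, Biostrings::width(genome)))
  sites <- .scanSites(genome, regions, gs@pam, gs@guideLength)
  mat <- if (nrow(sites))
    matrix(unlist(strsplit(sites$proto, "", fixed = TRUE)),
           nrow = gs@guideLength)
  else NULL
  g <- gs@guides
  out <- lapply(seq_along(g), function(i) {
    .verifyHits(S4Vectors::mcols(g)$protospacer[i], sites, maxMm,
                as.character(GenomicRanges::seqnames(g))[i],
                GenomicRanges::start(g)[i],
                as.character(GenomicRanges::strand(g))[i], mat = mat)
  })
  names(out) <- S4Vectors::mcols(g)$id
  .asGRangesList(out)
}

#' Summarize off-target hits into mismatch buckets
#'
#' @param hits A \code{GRanges} of hits for one guide, or the
#'   \code{GRangesList} returned by \code{\link{findOfftargets}}.
#' @return \code{DataFrame} with columns \code{mm0}..\code{mm3} (one row
#'   per guide).  \code{mm0} counts additional exact-copy loci only; the
#'   on-target locus itself is never included.
#' @export
summarizeOfftargets <- function(hits) {
  one <- function(h) {
    mm <- S4Vectors::mcols(h)$mismatches
    vapply(0:3, function(k) sum(mm == k), integer(1L))
  }
  if (is(hits, "GRangesList") || is.list(hits)) {
    m <- t(vapply(hits, one, integer(4L)))
    out <- S4Vectors::DataFrame(mm0 = unname(m[, 1L]),
                                mm1 = unname(m[, 2L]),
                                mm2 = unname(m[, 3L]),
                                mm3 = unname(m[, 4L]))
    rownames(out) <- names(hits)
    out
  } else {
    v <- one(hits)
    S4Vectors::DataFrame(mm0 = v[1L], mm1 = v[2L], mm2 = v[3L],
                         mm3 = v[4L])
  }
}
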