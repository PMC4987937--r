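#' @include AllClasses.R AllGenerics.R offtarget.R
NULL

## Offset between a minus-strand (left, PAM at genomic left) and a
## plus-strand (right, PAM at genomic right) protospacer: the gap in bp
## between their facing, PAM-distal edges.  Negative when they overlap.
#' @noRd
.pairOffset <- function(leftEnd, rightStart) rightStart - leftEnd - 1L

#' Pair opposite-strand candidates into nickase designs
#'
#' Pairs every minus-strand candidate (PAM at the genomic left) with
#' every plus-strand candidate (PAM at the genomic right) on the same
#' contig -- the PAM-out orientation required for a paired-nickase
#' double-strand break -- whose offset lies within
#' \code{[minOffset, maxOffset]}, bounds inclusive.  The offset is
#' defined as the gap in bp between the two protospacers' facing
#' (PAM-distal) edges; this definition is printed in output headers.
#' The default window of 10-31 bp is the binding-distance constraint for
#' efficient paired nicking.  A candidate may appear in several pairs.
#' Only 3'-anchored (Cas9-type) effectors support nickase mode.
#'
#' @param gs A \linkS4class{GuideSet} from one enumeration run.
#' @param minOffset,maxOffset Accepted offset window in bp (defaults 10
#'   and 31, inclusive).
#' @return \code{DataFrame} with one row per accepted pair --
#'   \code{left_id}, \code{right_id}, \code{contig}, \code{offset},
#'   \code{break_start}/\code{break_end} (the region between the two
#'   protospacers), plus the four protospacer bounds -- ordered by
#'   (left start, right start).
#' @export
pairNicks <- function(gs, minOffset = 10L, maxOffset = 31L) {
  stopifnot(is(gs, "GuideSet"))
  if (gs@pam@anchor != "3prime")
    stop("nickase pairing requires a 3'-anchored (Cas9-type) effector; ",
         "PAM '", gs@pam@pattern, "' is 5'-anchored", call. = FALSE)
  minOffset <- as.integer(minOffset)
  maxOffset <- as.integer(maxOffset)
  g <- gs@guides
  strand <- as.character(GenomicRanges::strand(g))
  contig <- as.character(GenomicRanges::seqnames(g))
  li <- which(strand == "-")
  ri <- which(strand == "+")
  rows <- list()
  for (i in li) {
    j <- ri[contig[ri] == contig[i]]
    if (!length(j)) next
    off <- .pairOffset(GenomicRanges::end(g)[i],
                       GenomicRanges::start(g)[j])
    j <- j[off >= minOffset & off <= maxOffset]
    if (!length(j)) next
    off <- .pairOffset(GenomicRanges::end(g)[i],
                       GenomicRanges::start(g)[j])
    rows[[length(rows) + 1L]] <- data.frame(
      left_idx = i, right_idx = j, offset = off,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(S4Vectors::DataFrame(
      left_id = character(0), right_id = character(0),
      contig = character(0), offset = integer(0),
      left_start = integer(0), left_end = integer(0),
      right_start = integer(0), right_end = integer(0),
      break_start = integer(0), break_end = integer(0)))
  }
  df <- do.call(rbind, rows)
  ls <- GenomicRanges::start(g)[df$left_idx]
  le <- GenomicRanges::end(g)[df$left_idx]
  rs <- GenomicRanges::start(g)[df$right_idx]
  re <- GenomicRanges::end(g)[df$right_idx]
  ord <- order(ls, rs)
  df <- df[ord, , drop = FALSE]
  ls <- ls[ord]; le <- le[ord]; rs <- rs[ord]; re <- re[ord]
  S4Vectors::DataFrame(
    left_id = S4Vectors::mcols(g)$id[df$left_idx],
    right_id = S4Vectors::mcols(g)$id[df$right_idx],
    contig = contig[df$left_idx],
    offset = df$offset,
    left_start = ls, left_end = le,
    right_start = rs, right_end = re,
    break_start = le + 1L, break_end = rs - 1L)
}

#' Paired off-targets of a nickase pair
#'
#' Evaluates where the two nicks of a pair could both bind elsewhere in
#' the genome and jointly produce a double-strand break: the two guides'
#' single-nick off-target hits (each within \code{perNickMaxMm}
#' mismatches) are combined, either guide taking either side, and kept
#' when the two half-sites sit on opposite strands in PAM-out
#' orientation on the same contig with an offset inside
#' \code{otWindow}.  The on-target pair itself is excluded.
#'
#' @param gs The \linkS4class{GuideSet} the pair came from.
#' @param pair One row of the \code{\link{pairNicks}} result.
#' @param index A \linkS4class{SiteIndex} over the genome.
#' @param perNickMaxMm Per-nick mismatch cap (default 3).
#' @param otWindow Accepted paired off-target offset window, bp
#'   (default \code{c(10, 31)}, the on-target window; independently
#'   settable because relaxed spacings may still nick and join).
#' @return \code{DataFrame} of paired off-targets -- contig, both
#'   half-site spans, per-side guide ids and mismatch counts,
#'   \code{offset} and \code{total_mismatches} -- ordered by (contig,
#'   left start, right start).
#' @export
pairedOfftargets <- function(gs, pair, index, perNickMaxMm = 3L,
                             otWindow = c(10L, 31L)) {
  stopifnot(is(gs, "GuideSet"))
  ids <- guideIds(gs)
  gi <- match(c(pair$left_id, pair$right_id), ids)
  if (anyNA(gi))
    stop("pair ids not found in the guide set", call. = FALSE)
  sub <- gs[gi]
  hits <- findOfftargets(sub, index, maxMm = perNickMaxMm)
  ## half-site pools: minus-strand hits can take the left nick,
  ## plus-strand hits the right nick, from either guide
  pool <- function(want) {
    parts <- lapply(seq_along(hits), function(k) {
      h <- hits[[k]]
      h <- h[as.character(GenomicRanges::strand(h)) == want]
      if (!length(h)) return(NULL)
      data.frame(guide = c(pair$left_id, pair$right_id)[k],
                 contig = as.character(GenomicRanges::seqnames(h)),
                 start = GenomicRanges::start(h),
                 end = GenomicRanges::end(h),
                 mm = S4Vectors::mcols(h)$mismatches,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  }
  lp <- pool("-")
  rp <- pool("+")
  empty <- S4Vectors::DataFrame(
    contig = character(0), left_guide = character(0),
    left_start = integer(0), left_end = integer(0), left_mm = integer(0),
    right_guide = character(0), right_start = integer(0),
    right_end = integer(0), right_mm = integer(0),
    offset = integer(0), total_mismatches = integer(0))
  if (is.null(lp) || is.null(rp)) return(empty)
  cmb <- merge(lp, rp, by = "contig", suffixes = c("_l", "_r"))
  if (!nrow(cmb)) return(empty)
  cmb$offset <- .pairOffset(cmb$end_l, cmb$start_r)
  cmb <- cmb[cmb$offset >= otWindow[1L] & cmb$offset <= otWindow[2L], ,
             drop = FALSE]
  ## the on-target pair itself (both half-sites at the pair's own loci)
  cmb <- cmb[!(cmb$start_l == pair$left_start &
                 cmb$start_r == pair$right_start &
                 cmb$contig == pair$contig), , drop = FALSE]
  if (!nrow(cmb)) return(empty)
  cmb <- cmb[order(cmb$contig, cmb$start_l, cmb$start_r,
                   cmb$guide_l, cmb$guide_r), , drop = FALSE]
  S4Vectors::DataFrame(
    contig = cmb$contig,
    left_guide = cmb$guide_l, left_start = cmb$start_l,
    left_end = cmb$end_l, left_mm = cmb$mm_l,
    right_guide = cmb$guide_r, right_start = cmb$start_r,
    right_end = cmb$end_r, right_mm = cmb$mm_r,
    offset = cmb$offset,
    total_mismatches = cmb$mm_l + cmb$mm_r)
}
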