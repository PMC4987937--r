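#' @include AllClasses.R AllGenerics.R scoring.R offtarget.R
NULL

#' Rank and color scored guide candidates
#'
#' Produces the final ranked table.  The sort key is specificity first,
#' then efficiency: \code{mm0}, \code{mm1}, \code{mm2}, \code{mm3}
#' ascending, efficiency descending (unavailable scores sort last),
#' self-complementarity ascending, genomic position as the final
#' tiebreak; the sort is stable, so ranks are reproducible.  Colors
#' summarize quality at a glance: \emph{green} (best) requires no
#' off-targets at 0 or 1 mismatches, ideal GC and no stems; \emph{red}
#' (worst) flags any additional exact-match locus (\code{mm0 > 0});
#' everything else is \emph{amber}.  The thresholds are arguments, not
#' constants.
#'
#' @param gs A \linkS4class{GuideSet}.
#' @param scores \code{DataFrame} from \code{\link{scoreGuides}}.
#' @param otSummary \code{DataFrame} from
#'   \code{\link{summarizeOfftargets}} (rows aligned with \code{gs}).
#' @param greenMaxMm0,greenMaxMm1,greenMaxSelfcomp Color-policy
#'   constants (defaults 0, 0, 0).
#' @return \code{DataFrame}: one row per candidate in rank order, with
#'   candidate coordinates, sequences, all scores, mismatch buckets,
#'   \code{rank} (a permutation of 1..N) and \code{color}.
#' @export
rankGuides <- function(gs, scores, otSummary, greenMaxMm0 = 0L,
                       greenMaxMm1 = 0L, greenMaxSelfcomp = 0L) {
  stopifnot(is(gs, "GuideSet"))
  n <- length(gs)
  stopifnot(nrow(scores) == n, nrow(otSummary) == n)
  g <- gs@guides
  df <- S4Vectors::DataFrame(
    id = S4Vectors::mcols(g)$id,
    contig = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    protospacer = S4Vectors::mcols(g)$protospacer,
    pam_seq = S4Vectors::mcols(g)$pam_seq,
    cut_pos = S4Vectors::mcols(g)$cut_pos,
    gc_fraction = scores$gc_fraction,
    gc_ideal = scores$gc_ideal,
    pam_proximal_g = scores$pam_proximal_g,
    selfcomp = scores$selfcomp,
    efficiency = scores$efficiency,
    mm0 = otSummary$mm0, mm1 = otSummary$mm1,
    mm2 = otSummary$mm2, mm3 = otSummary$mm3)
  effKey <- ifelse(is.na(df$efficiency), -Inf, df$efficiency)
  ord <- order(df$mm0, df$mm1, df$mm2, df$mm3, -effKey, df$selfcomp,
               df$contig, df$start, df$strand)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(n)
  df$color <- ifelse(df$mm0 > 0L, "red",
               ifelse(df$mm0 <= greenMaxMm0 & df$mm1 <= greenMaxMm1 &
                        df$gc_ideal &
                        df$selfcomp <= greenMaxSelfcomp,
                      "green", "amber"))
  rownames(df) <- NULL
  df
}

#' Write ranked designs to TSV, BED and FASTA
#'
#' Writes the three flat-file outputs: \code{results.tsv} with the
#' fixed, documented column order (id, 1-based location, strand,
#' protospacer, PAM, GC\%, self-complementarity, efficiency, MM0-MM3,
#' color, restriction-site count, primer columns);
#' \code{targets.bed} (BED6 of protospacer spans, score = rank); and
#' \code{guides.fasta} of protospacers.  Output bytes depend only on the
#' input, so repeat runs on identical input are identical.
#'
#' @param ranked \code{DataFrame} from \code{\link{rankGuides}},
#'   optionally carrying \code{restriction_count},
#'   \code{primer_left}/\code{primer_right}/\code{primer_product}
#'   columns (reported as \code{NA}/"." when absent).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeOutputs <- function(ranked, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "results.tsv")
  bed <- file.path(dir, "targets.bed")
  fa <- file.path(dir, "guides.fasta")
  n <- nrow(ranked)
  opt <- function(col) if (col %in% colnames(ranked)) ranked[[col]]
                       else rep(NA, n)
  tab <- data.frame(
    id = ranked$id,
    location = sprintf("%s:%d-%d", ranked$contig, ranked$start,
                       ranked$end),
    strand = ranked$strand,
    protospacer = ranked$protospacer,
    pam = ranked$pam_seq,
    gc_pct = sprintf("%.1f", 100 * ranked$gc_fraction),
    selfcomp = ranked$selfcomp,
    efficiency = ifelse(is.na(ranked$efficiency), "NA",
                        sprintf("%.4f", ranked$efficiency)),
    mm0 = ranked$mm0, mm1 = ranked$mm1, mm2 = ranked$mm2,
    mm3 = ranked$mm3,
    color = ranked$color,
    restriction_count = opt("restriction_count"),
    primer_left = opt("primer_left"),
    primer_right = opt("primer_right"),
    primer_product = opt("primer_product"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gr <- GenomicRanges::GRanges(ranked$contig,
          IRanges::IRanges(ranked$start, ranked$end),
          strand = ranked$strand)
  S4Vectors::mcols(gr)$name <- ranked$id
  S4Vectors::mcols(gr)$score <- ranked$rank
  rtracklayer::export(gr, bed, format = "bed")
  seqs <- Biostrings::DNAStringSet(
    structure(as.character(ranked$protospacer), names = ranked$id))
  Biostrings::writeXStringSet(seqs, fa)
  invisible(c(results = tsv, targets = bed, guides = fa))
}
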