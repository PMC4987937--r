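#' @include AllClasses.R enumerate.R scoring.R offtarget.R nickase.R
#' @include accessory.R report.R
NULL

## Parse "contig:start-end" (1-based inclusive) into a GRanges.
#' @noRd
.parseTarget <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1L]]
  if (length(m) != 4L)
    stop("cannot parse target '", spec,
         "'; expected contig:start-end (1-based)", call. = FALSE)
  GenomicRanges::GRanges(m[2L],
    IRanges::IRanges(as.integer(m[3L]), as.integer(m[4L])))
}

#' Run the full guide-design pipeline
#'
#' Drives enumeration, scoring, off-target counting, optional nickase
#' pairing, and ranking in one call.  The target is either an explicit
#' region (\code{target}), a gene from a BED12 file (\code{bed} +
#' \code{gene} + \code{mode}), or the whole genome.
#'
#' @param genome Named \code{DNAStringSet}, or a path to a FASTA file.
#' @param target Region as \code{GRanges} or \code{"contig:start-end"}
#'   (1-based), or NULL.
#' @param bed,gene Path to a BED12 file and the transcript name in it.
#' @param mode Region mode for gene targeting (see
#'   \code{\link{resolveRegion}}).
#' @param effector Preset name (default \code{"SpCas9"}); ignored when
#'   \code{pam} is given.
#' @param pam Optional custom \linkS4class{PamSpec} overriding the
#'   preset.
#' @param guideLength Optional spacer-length override.
#' @param scoreModel Optional path to an efficiency-model TSV, or an
#'   \linkS4class{EfficiencyModel}.
#' @param maxMismatches Off-target depth, 0-3 (default 3).
#' @param nickase Also pair candidates into nickase designs.
#' @param nickaseWindow On-target pairing offset window (default
#'   \code{c(10, 31)}).
#' @param ... Passed to \code{\link{resolveRegion}} (e.g.
#'   \code{exonIndex}, \code{spliceFlank}, \code{promoterUp}).
#' @return List: \code{guides} (\linkS4class{GuideSet}),
#'   \code{table} (ranked \code{DataFrame}), \code{offtargets}
#'   (\code{GRangesList}), and \code{pairs} (nickase \code{DataFrame}
#'   or NULL).
#' @export
designGuides <- function(genome, target = NULL, bed = NULL, gene = NULL,
                         mode = "whole", effector = "SpCas9", pam = NULL,
                         guideLength = NULL, scoreModel = NULL,
                         maxMismatches = 3L, nickase = FALSE,
                         nickaseWindow = c(10L, 31L), ...) {
  if (is.character(genome)) genome <- readGenomeFasta(genome)
  if (is.null(pam)) {
    preset <- effectorPreset(effector)
    pam <- preset@pam
    if (is.null(guideLength)) guideLength <- preset@guideLength
    cutOffset <- preset@cutOffset
  } else {
    cutOffset <- NULL
  }
  regions <- if (!is.null(target)) {
    if (is.character(target)) .parseTarget(target) else target
  } else if (!is.null(bed)) {
    if (is.null(gene))
      stop("'gene' is required together with 'bed'", call. = FALSE)
    models <- readBed12(bed)
    if (!gene %in% names(models))
      stop("gene '", gene, "' not found in ", bed, call. = FALSE)
    resolveRegion(models[[gene]], mode = mode, genome = genome, ...)
  } else {
    GenomicRanges::GRanges(names(genome),
      IRanges::IRanges(1L, Biostrings::width(genome)))
  }
  gs <- enumerateGuides(genome, regions, pam, guideLength = guideLength,
                        cutOffset = cutOffset)
  model <- if (is.null(scoreModel)) NULL
           else if (is(scoreModel, "EfficiencyModel")) scoreModel
           else loadEfficiencyModel(scoreModel)
  scores <- scoreGuides(gs, model = model)
  index <- buildSiteIndex(genome, gs@pam, gs@guideLength)
  hits <- findOfftargets(gs, index, maxMm = maxMismatches)
  summ <- summarizeOfftargets(hits)
  ranked <- rankGuides(gs, scores, summ)
  pairs <- NULL
  if (nickase) {
    pairs <- pairNicks(gs, nickaseWindow[1L], nickaseWindow[2L])
    if (nrow(pairs)) {
      npo <- vapply(seq_len(nrow(pairs)), function(i)
        nrow(pairedOfftargets(gs, pairs[i, ], index,
                              perNickMaxMm = maxMismatches,
                              otWindow = nickaseWindow)), integer(1L))
      pairs$paired_offtargets <- npo
      ## rank pairs: fewest paired OTs, then single-guide OT burden,
      ## then mean efficiency
      ids <- guideIds(gs)
      burden <- rowSums(as.data.frame(summ[, c("mm0", "mm1", "mm2",
                                               "mm3")]))
      eff <- scores$efficiency
      li <- match(pairs$left_id, ids); ri <- match(pairs$right_id, ids)
      meanEff <- rowMeans(cbind(eff[li], eff[ri]), na.rm = TRUE)
      ord <- order(pairs$paired_offtargets, burden[li] + burden[ri],
                   -ifelse(is.nan(meanEff), -Inf, meanEff),
                   pairs$left_start, pairs$right_start)
      pairs <- pairs[ord, , drop = FALSE]
    }
  }
  list(guides = gs, table = ranked, offtargets = hits, pairs = pairs)
}
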