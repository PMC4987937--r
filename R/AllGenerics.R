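#' @include AllClasses.R
NULL

#' Accessors for guideForge objects
#'
#' Small accessor generics: \code{protospacers} and \code{pamSeqs} return
#' the spacer and PAM strings (5'->3', guide orientation) as a
#' \link[Biostrings]{DNAStringSet}; \code{guideIds} the stable candidate
#' labels; \code{cutSites} the modeled cut coordinates (the reference
#' base after which the cut falls, plus strand); \code{guideRanges} the
#' protospacer spans as \code{GRanges}; \code{pamOf} and
#' \code{guideLength} the enumeration parameters.
#'
#' @param x A \linkS4class{GuideSet}, \linkS4class{EffectorPreset} or
#'   \linkS4class{PamSpec}, as applicable.
#' @return See individual descriptions above.
#' @name guide-accessors
#' @aliases protospacers pamSeqs guideIds cutSites guideRanges pamOf
#'   guideLength
NULL

#' @rdname guide-accessors
#' @export
setGeneric("protospacers", function(x) standardGeneric("protospacers"))

#' @rdname guide-accessors
#' @export
setGeneric("pamSeqs", function(x) standardGeneric("pamSeqs"))

#' @rdname guide-accessors
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' @rdname guide-accessors
#' @export
setGeneric("cutSites", function(x) standardGeneric("cutSites"))

#' @rdname guide-accessors
#' @export
setGeneric("guideRanges", function(x) standardGeneric("guideRanges"))

#' @rdname guide-accessors
#' @export
setGeneric("pamOf", function(x) standardGeneric("pamOf"))

#' @rdname guide-accessors
#' @export
setGeneric("guideLength", function(x) standardGeneric("guideLength"))

#' Accessors for GeneModel objects
#'
#' @param x A \linkS4class{GeneModel}.
#' @return \code{geneName}: the transcript id; \code{txRegion} /
#'   \code{exons} / \code{cdsRegion}: \code{GRanges}; \code{tss}: the
#'   1-based strand-aware transcription start coordinate.
#' @name genemodel-accessors
#' @aliases geneName txRegion exons cdsRegion tss
NULL

#' @rdname genemodel-accessors
#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))

#' @rdname genemodel-accessors
#' @export
setGeneric("txRegion", function(x) standardGeneric("txRegion"))

#' @rdname genemodel-accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname genemodel-accessors
#' @export
setGeneric("cdsRegion", function(x) standardGeneric("cdsRegion"))

#' @rdname genemodel-accessors
#' @export
setGeneric("tss", function(x) standardGeneric("tss"))

#' @rdname guide-accessors
setMethod("protospacers", "GuideSet", function(x)
  Biostrings::DNAStringSet(structure(S4Vectors::mcols(x@guides)$protospacer,
                                     names = S4Vectors::mcols(x@guides)$id)))

#' @rdname guide-accessors
setMethod("pamSeqs", "GuideSet", function(x)
  Biostrings::DNAStringSet(structure(S4Vectors::mcols(x@guides)$pam_seq,
                                     names = S4Vectors::mcols(x@guides)$id)))

#' @rdname guide-accessors
setMethod("guideIds", "GuideSet", function(x)
  S4Vectors::mcols(x@guides)$id)

#' @rdname guide-accessors
setMethod("cutSites", "GuideSet", function(x)
  structure(S4Vectors::mcols(x@guides)$cut_pos,
            names = S4Vectors::mcols(x@guides)$id))

#' @rdname guide-accessors
setMethod("guideRanges", "GuideSet", function(x) x@guides)

#' @rdname guide-accessors
setMethod("pamOf", "GuideSet", function(x) x@pam)

#' @rdname guide-accessors
setMethod("pamOf", "EffectorPreset", function(x) x@pam)

#' @rdname guide-accessors
setMethod("guideLength", "GuideSet", function(x) x@guideLength)

#' @rdname guide-accessors
setMethod("guideLength", "EffectorPreset", function(x) x@guideLength)

#' @rdname genemodel-accessors
setMethod("geneName", "GeneModel", function(x) x@name)

#' @rdname genemodel-accessors
setMethod("txRegion", "GeneModel", function(x) x@txRegion)

#' @rdname genemodel-accessors
setMethod("exons", "GeneModel", function(x) x@exons)

#' @rdname genemodel-accessors
setMethod("cdsRegion", "GeneModel", function(x) x@cds)

#' @rdname genemodel-accessors
setMethod("tss", "GeneModel", function(x) x@tss)
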