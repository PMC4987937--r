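#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
NULL

## ---------------------------------------------------------------------
## PamSpec
## ---------------------------------------------------------------------

#' PamSpec: a degenerate PAM pattern with a 5' or 3' anchor
#'
#' Describes the protospacer adjacent motif an effector requires: an IUPAC
#' pattern plus the side of the protospacer it sits on -- \code{"3prime"}
#' for Cas9-type effectors (PAM follows the spacer) and \code{"5prime"}
#' for Cpf1-type effectors (PAM precedes it).
#'
#' @slot pattern Uppercase IUPAC string (U is folded to T on construction).
#' @slot anchor \code{"3prime"} or \code{"5prime"}.
#' @slot name Free-text label.
#' @aliases PamSpec
#' @exportClass PamSpec
setClass("PamSpec",
  representation(pattern = "character", anchor = "character",
                 name = "character"))

setValidity("PamSpec", function(object) {
  msg <- character(0)
  if (length(object@pattern) != 1L || !nzchar(object@pattern))
    msg <- c(msg, "'pattern' must be a single non-empty string")
  else {
    chars <- strsplit(object@pattern, "", fixed = TRUE)[[1L]]
    bad <- chars[!chars %in% names(.IUPAC_BITS)]
    if (length(bad))
      msg <- c(msg, paste0("invalid IUPAC code '", bad[1L], "' in PAM pattern"))
  }
  if (length(object@anchor) != 1L ||
      !object@anchor %in% c("3prime", "5prime"))
    msg <- c(msg, "'anchor' must be \"3prime\" or \"5prime\"")
  if (length(msg)) msg else TRUE
})

#' Construct (parse) a PAM specification
#'
#' Uppercases the pattern, folds RNA \code{U} to \code{T}, and validates
#' every character against the IUPAC alphabet; the first offending
#' character is named in the error.
#'
#' @param pattern IUPAC PAM string, e.g. \code{"NGG"} or \code{"TTTN"}.
#' @param anchor Side of the protospacer the PAM sits on:
#'   \code{"3prime"} (Cas9-like, default) or \code{"5prime"} (Cpf1-like).
#' @param name Label for the spec.
#' @return A \linkS4class{PamSpec}.
#' @examples
#' pamSpec("NGG")                       # SpCas9-style
#' pamSpec("TTTN", anchor = "5prime")   # Cpf1-style
#' @export
pamSpec <- function(pattern, anchor = c("3prime", "5prime"),
                    name = "custom") {
  anchor <- match.arg(anchor)
  pattern <- chartr("u", "t", pattern)
  pattern <- toupper(pattern)
  pattern <- chartr("U", "T", pattern)
  .encodePattern(pattern)  # errors name the offending character
  new("PamSpec", pattern = pattern, anchor = anchor, name = name)
}

#' @export
setMethod("show", "PamSpec", function(object) {
  cat("PamSpec '", object@name, "': ", object@pattern, " (",
      if (object@anchor == "3prime") "3' of protospacer"
      else "5' of protospacer", ")\n", sep = "")
})

## ---------------------------------------------------------------------
## EffectorPreset
## ---------------------------------------------------------------------

#' EffectorPreset: a named effector with PAM, guide length and cut offset
#'
#' @slot name Preset label (e.g. \code{"SpCas9"}).
#' @slot pam The effector's \linkS4class{PamSpec}.
#' @slot guideLength Default spacer length in nt (>= 10).
#' @slot cutOffset Distance in bp of the modeled cut from the PAM-proximal
#'   protospacer end, measured into the protospacer (3 for blunt Cas9
#'   cuts, 18 for Cpf1-style staggered cuts; a documented, overridable
#'   convention -- see the package vignette).
#' @aliases EffectorPreset
#' @exportClass EffectorPreset
setClass("EffectorPreset",
  representation(name = "character", pam = "PamSpec",
                 guideLength = "integer", cutOffset = "integer"))

setValidity("EffectorPreset", function(object) {
  if (length(object@guideLength) != 1L || object@guideLength < 10L)
    return("'guideLength' must be a single integer >= 10")
  TRUE
})

#' @export
setMethod("show", "EffectorPreset", function(object) {
  cat("EffectorPreset ", object@name, ": PAM ", object@pam@pattern, " (",
      object@pam@anchor, "), guide ", object@guideLength,
      " nt, cut offset ", object@cutOffset, " bp\n", sep = "")
})

## ---------------------------------------------------------------------
## GeneModel
## ---------------------------------------------------------------------

#' GeneModel: one transcript with exon structure, CDS and TSS
#'
#' @slot name Transcript identifier.
#' @slot txRegion Length-1 \link[GenomicRanges]{GRanges} spanning the
#'   transcript (strand set).
#' @slot exons \code{GRanges} of exons, stored in ascending genomic order.
#' @slot cds \code{GRanges} of length 0 (non-coding) or 1 (the
#'   thick/CDS interval).
#' @slot tss Integer: strand-aware transcription start (1-based).
#' @aliases GeneModel
#' @exportClass GeneModel
setClass("GeneModel",
  representation(name = "character", txRegion = "GRanges",
                 exons = "GRanges", cds = "GRanges", tss = "integer"))

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (length(object@txRegion) != 1L)
    msg <- c(msg, "'txRegion' must have length 1")
  if (length(object@exons)) {
    s <- GenomicRanges::start(object@exons)
    e <- GenomicRanges::end(object@exons)
    if (is.unsorted(s) || any(s[-1L] <= e[-length(e)]))
      msg <- c(msg, "exons must be sorted and non-overlapping")
  }
  if (length(object@cds) > 1L)
    msg <- c(msg, "'cds' must have length 0 or 1")
  if (length(object@cds) == 1L && length(object@txRegion) == 1L) {
    if (GenomicRanges::start(object@cds) <
          GenomicRanges::start(object@txRegion) ||
        GenomicRanges::end(object@cds) >
          GenomicRanges::end(object@txRegion))
      msg <- c(msg, "cds interval must lie within the transcript span")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "GeneModel", function(object) {
  cds <- if (length(object@cds))
    paste0(GenomicRanges::start(object@cds), "-",
           GenomicRanges::end(object@cds)) else "none"
  cat("GeneModel ", object@name, ": ",
      as.character(GenomicRanges::seqnames(object@txRegion)), ":",
      GenomicRanges::start(object@txRegion), "-",
      GenomicRanges::end(object@txRegion), " (",
      as.character(GenomicRanges::strand(object@txRegion)), "), ",
      length(object@exons), " exon(s), CDS ", cds,
      ", TSS ", object@tss, "\n", sep = "")
})

## ---------------------------------------------------------------------
## GuideSet
## ---------------------------------------------------------------------

#' GuideSet: enumerated guide candidates for one effector configuration
#'
#' A container holding one \code{GRanges} of protospacer spans (metadata
#' columns \code{id}, \code{protospacer}, \code{pam_seq}, \code{cut_pos},
#' \code{context}, \code{pad_left}, \code{pad_right},
#' \code{partial_context}) together with the \linkS4class{PamSpec},
#' spacer length and scoring-context geometry they were enumerated under.
#' Protospacer and PAM strings are reported 5'->3' in guide orientation.
#'
#' @slot guides \code{GRanges} of protospacer spans with the metadata
#'   columns above.
#' @slot pam The \linkS4class{PamSpec} used for enumeration.
#' @slot guideLength Spacer length in nt.
#' @slot contextFlank Integer pair: bases of genomic context kept 5' and
#'   3' of the protospacer+PAM block (guide orientation).
#' @aliases GuideSet
#' @exportClass GuideSet
setClass("GuideSet",
  representation(guides = "GRanges", pam = "PamSpec",
                 guideLength = "integer", contextFlank = "integer"))

.GUIDE_MCOLS <- c("id", "protospacer", "pam_seq", "cut_pos", "context",
                  "pad_left", "pad_right", "partial_context")

setValidity("GuideSet", function(object) {
  msg <- character(0)
  miss <- setdiff(.GUIDE_MCOLS, colnames(S4Vectors::mcols(object@guides)))
  if (length(miss))
    msg <- c(msg, paste0("missing guide column(s): ",
                         paste(miss, collapse = ", ")))
  if (length(object@guides) &&
      !all(GenomicRanges::width(object@guides) == object@guideLength))
    msg <- c(msg, "all protospacer spans must equal guideLength")
  if (length(object@contextFlank) != 2L || any(object@contextFlank < 0L))
    msg <- c(msg, "'contextFlank' must be two non-negative integers")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "GuideSet", function(object) {
  cat("GuideSet with ", length(object@guides), " candidate(s): ",
      object@guideLength, "-nt guides, PAM ", object@pam@pattern,
      " (", object@pam@anchor, ")\n", sep = "")
  if (length(object@guides)) {
    df <- utils::head(as.data.frame(object), 6L)
    print(df)
    if (length(object@guides) > 6L)
      cat("... and ", length(object@guides) - 6L, " more\n", sep = "")
  }
})

#' @export
setMethod("length", "GuideSet", function(x) length(x@guides))

#' @export
setMethod("[", "GuideSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x, guides = x@guides[i])
})

#' @export
as.data.frame.GuideSet <- function(x, ...) {
  g <- x@guides
  data.frame(
    id = S4Vectors::mcols(g)$id,
    contig = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    protospacer = S4Vectors::mcols(g)$protospacer,
    pam_seq = S4Vectors::mcols(g)$pam_seq,
    cut_pos = S4Vectors::mcols(g)$cut_pos,
    partial_context = S4Vectors::mcols(g)$partial_context,
    stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------
## EfficiencyModel
## ---------------------------------------------------------------------

#' EfficiencyModel: a linear position-feature cutting-efficiency model
#'
#' A loadable model of predicted cutting efficiency: an intercept plus a
#' sum of weights for 1- or 2-nt features matched at fixed offsets within
#' a context window laid out as upstream flank | guide | PAM | downstream
#' flank (guide orientation; for 5'-anchored effectors the PAM block
#' precedes the guide block, the window tuple keeps the same meaning).
#' An optional logistic link squashes the linear predictor to (0,1).
#'
#' @slot name Model label.
#' @slot window Integer 4-tuple \code{(upstream, guide, pam, downstream)}
#'   in bp; guides of a different length refuse the model.
#' @slot intercept Numeric intercept.
#' @slot features \code{data.frame} with columns \code{offset} (1-based
#'   position within the context window), \code{kmer} (1-2 nt A/C/G/T),
#'   \code{weight} (numeric).
#' @slot link \code{"identity"} or \code{"logistic"}.
#' @aliases EfficiencyModel
#' @exportClass EfficiencyModel
setClass("EfficiencyModel",
  representation(name = "character", window = "integer",
                 intercept = "numeric", features = "data.frame",
                 link = "character"))

setValidity("EfficiencyModel", function(object) {
  msg <- character(0)
  if (length(object@window) != 4L || any(object@window < 0L))
    msg <- c(msg, "'window' must be four non-negative integers")
  if (!object@link %in% c("identity", "logistic"))
    msg <- c(msg, "'link' must be \"identity\" or \"logistic\"")
  f <- object@features
  if (!all(c("offset", "kmer", "weight") %in% colnames(f)))
    msg <- c(msg, "features need columns offset, kmer, weight")
  else if (nrow(f)) {
    W <- sum(object@window)
    if (any(f$offset < 1L | f$offset + nchar(f$kmer) - 1L > W))
      msg <- c(msg, "feature offsets must lie within the context window")
    if (any(!nchar(f$kmer) %in% 1:2) || any(grepl("[^ACGT]", f$kmer)))
      msg <- c(msg, "feature kmers must be 1-2 nt over A/C/G/T")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "EfficiencyModel", function(object) {
  cat("EfficiencyModel '", object@name, "': window ",
      paste(object@window, collapse = "+"), " bp, ",
      nrow(object@features), " feature(s), ", object@link,
      " link, intercept ", format(object@intercept), "\n", sep = "")
})

## ---------------------------------------------------------------------
## SiteIndex
## ---------------------------------------------------------------------

#' SiteIndex: seed-hashed index of all PAM-adjacent windows in a genome
#'
#' Supports bounded-Hamming off-target lookup by the pigeonhole
#' principle: the spacer is split into \code{nSeeds} contiguous
#' fragments, so any site within \code{nSeeds - 1} mismatches of a query
#' matches at least one fragment exactly and is retrieved through the
#' hash, then verified by full comparison.
#'
#' @slot sites \code{data.frame} of every candidate site (contig, strand,
#'   start, end, proto, pam_seq), in (contig, start, strand) order.
#' @slot pam \linkS4class{PamSpec} the index was built under.
#' @slot guideLength Spacer length indexed.
#' @slot nSeeds Number of seed fragments (mismatch capacity + 1).
#' @slot seedBounds Integer matrix (nSeeds x 2) of fragment bounds.
#' @slot table Hash environment: \code{"<seed>_<fragment>"} -> site rows.
#' @slot naive TRUE when the spacer was too short to split into seeds and
#'   lookups fall back to a full scan.
#' @aliases SiteIndex
#' @exportClass SiteIndex
setClass("SiteIndex",
  representation(sites = "data.frame", pam = "PamSpec",
                 guideLength = "integer", nSeeds = "integer",
                 seedBounds = "matrix", table = "environment",
                 naive = "logical"))

#' @export
setMethod("show", "SiteIndex", function(object) {
  cat("SiteIndex: ", nrow(object@sites), " PAM-adjacent site(s), ",
      object@guideLength, "-nt windows, PAM ", object@pam@pattern,
      if (object@naive) " [naive fallback]" else
        paste0(", ", object@nSeeds, " seeds"),
      "\n", sep = "")
})
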