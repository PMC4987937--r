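#' @include AllClasses.R iupac.R seqio.R enumerate.R
NULL

.BASES <- c("A", "C", "G", "T")

## Break every PAM-pattern occurrence in 's' that is not in the intended
## sets, mutating only unprotected positions.  Returns the scrubbed
## string, or NULL when a stray occurrence has no mutable position.
#' @noRd
.scrubStrays <- function(s, protected, pam, intendedFwd = integer(0),
                         intendedRev = integer(0), maxPasses = 50L) {
  encPat <- .encodePattern(pam@pattern)
  rcPat <- revcomp(pam@pattern)
  encRc <- .encodePattern(rcPat)
  palindromic <- identical(pam@pattern, rcPat)
  m <- length(encPat)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (pass in seq_len(maxPasses)) {
    enc <- unname(.SUBJECT_BITS[ch])
    f <- setdiff(.scanEncoded(enc, encPat), intendedFwd)
    r <- if (palindromic) integer(0)
         else setdiff(.scanEncoded(enc, encRc), intendedRev)
    strays <- rbind(if (base::length(f)) cbind(f, 1L),
                    if (base::length(r)) cbind(r, 2L))
    if (is.null(strays)) break
    touched <- FALSE
    for (r in seq_len(nrow(strays))) {
      p <- strays[r, 1L]
      pat <- if (strays[r, 2L] == 1L) encPat else encRc
      ## verify still a match (an earlier fix this pass may have broken it)
      here <- unname(.SUBJECT_BITS[ch[p:(p + m - 1L)]])
      if (!all(bitwAnd(here, pat) > 0L)) next
      fixable <- which(pat != 15L & !protected[p:(p + m - 1L)])
      if (!length(fixable)) next
      j <- fixable[1L]
      allowed <- .BASES[bitwAnd(pat[j], c(1L, 2L, 4L, 8L)) > 0L]
      ch[p + j - 1L] <- sample(setdiff(.BASES, allowed), 1L)
      touched <- TRUE
    }
    if (!touched) return(NULL)  # strays remain but nothing is mutable
  }
  enc <- unname(.SUBJECT_BITS[ch])
  ok <- length(setdiff(.scanEncoded(enc, encPat), intendedFwd)) == 0L &&
    (palindromic ||
       length(setdiff(.scanEncoded(enc, encRc), intendedRev)) == 0L)
  if (!ok) return(NULL)
  paste(ch, collapse = "")
}

## Draw one concrete PAM instance from a degenerate pattern.
#' @noRd
.samplePamInstance <- function(pam) {
  enc <- .encodePattern(pam@pattern)
  paste(vapply(enc, function(b) {
    allowed <- .BASES[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1L)), collapse = "")
}

#' Generate a deterministic synthetic genome with planted CRISPR features
#'
#' Builds a seeded random genome and plants recoverable features in it:
#' on-target guide sites, off-target copies at chosen Hamming distances,
#' and PAM-out nickase half-site pairs at chosen offsets.  With
#' \code{clean = TRUE} (default) every PAM occurrence outside the
#' planted features is destroyed, so enumeration and off-target search
#' over the fixture recover exactly the truth table; with
#' \code{clean = FALSE} the background keeps its natural PAM density
#' (useful for search-equivalence stress tests).  The same seed always
#' produces byte-identical output.
#'
#' @param seed Integer RNG seed.
#' @param length Genome length in bp (default 50000).
#' @param gc Background GC fraction (default 0.5).
#' @param pam \linkS4class{PamSpec} (default NGG, 3'-anchored).
#' @param guideLength Spacer length (default 20).
#' @param nGuides Number of planted on-target guides.
#' @param offtargetMm List: element \code{i} is an integer vector of
#'   Hamming distances at which to plant copies of guide \code{i} (e.g.
#'   \code{list(c(0, 1, 2, 3))}).
#' @param nickaseOffsets Integer vector: one PAM-out half-site pair is
#'   planted per element, with that inter-protospacer offset in bp.
#' @param clean Scrub stray PAM occurrences (see above).
#' @param pad Buffer of scrubbable background bases kept on each side of
#'   every planted segment (default 6).
#' @param contig Contig name (default "chr1").
#' @param dir If non-NULL, write \code{genome.fa}, \code{truth.tsv} and
#'   \code{features.bed} there.
#' @return List with \code{genome} (\code{DNAStringSet}), \code{truth}
#'   (\code{data.frame}: type, id, guide_id, contig, start, end, strand,
#'   protospacer, pam_seq, mm, pair_id, offset), \code{pam},
#'   \code{guideLength}, and \code{paths} (when written).
#' @export
makeFixture <- function(seed, length = 50000L, gc = 0.5,
                        pam = pamSpec("NGG"), guideLength = 20L,
                        nGuides = 1L, offtargetMm = list(),
                        nickaseOffsets = integer(0), clean = TRUE,
                        pad = 6L, contig = "chr1", dir = NULL) {
  stopifnot(guideLength >= 10L, length >= 200L)
  if (base::length(offtargetMm) > nGuides)
    stop("'offtargetMm' has more elements than guides", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))

  L <- as.integer(guideLength)
  m <- nchar(pam@pattern)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE,
                                      prob = probs), collapse = "")

  segs <- list()   # each: list(str, truth = data.frame of features with
                   # relative coords, pamFwd/pamRev relative starts)
  addSeg <- function(str, truth, pamFwd, pamRev)
    segs[[base::length(segs) + 1L]] <<- list(str = str, truth = truth,
                                             pamFwd = pamFwd,
                                             pamRev = pamRev)
  protoFeature <- function(type, id, guide_id, relStart, strand, proto,
                           pamInst, mm = NA_integer_,
                           pair_id = NA_character_,
                           offset = NA_integer_)
    data.frame(type = type, id = id, guide_id = guide_id,
               rel_start = relStart, strand = strand,
               protospacer = proto, pam_seq = pamInst, mm = mm,
               pair_id = pair_id, offset = offset,
               stringsAsFactors = FALSE)

  ## ---- planted on-target guides (plus strand, PAM per anchor) -------
  guideProtos <- character(nGuides)
  for (i in seq_len(nGuides)) {
    repeat {
      proto <- randSeq(L)
      pamInst <- .samplePamInstance(pam)
      body <- if (pam@anchor == "3prime") paste0(proto, pamInst)
              else paste0(pamInst, proto)
      str <- paste0(randSeq(pad), body, randSeq(pad))
      pamRel <- pad + (if (pam@anchor == "3prime") L else 0L) + 1L
      protected <- rep(FALSE, nchar(str))
      protected[pamRel:(pamRel + m - 1L)] <- TRUE
      scr <- .scrubStrays(str, protected, pam, intendedFwd = pamRel)
      if (is.null(scr)) next
      protoRel <- pad + (if (pam@anchor == "3prime") 0L else m) + 1L
      proto <- substr(scr, protoRel, protoRel + L - 1L)
      guideProtos[i] <- proto
      addSeg(scr,
             protoFeature("guide", paste0("g", i), paste0("g", i),
                          protoRel, "+", proto, pamInst),
             pamFwd = pamRel, pamRev = integer(0))
      break
    }
  }

  ## ---- off-target copies at chosen Hamming distances ----------------
  for (i in seq_along(offtargetMm)) {
    for (k in seq_along(offtargetMm[[i]])) {
      mm <- as.integer(offtargetMm[[i]][k])
      stopifnot(mm >= 0L, mm <= L)
      repeat {
        copy <- strsplit(guideProtos[i], "", fixed = TRUE)[[1L]]
        if (mm > 0L) {
          at <- sample(L, mm)
          for (p in at) copy[p] <- sample(setdiff(.BASES, copy[p]), 1L)
        }
        copy <- paste(copy, collapse = "")
        pamInst <- .samplePamInstance(pam)
        body <- if (pam@anchor == "3prime") paste0(copy, pamInst)
                else paste0(pamInst, copy)
        str <- paste0(randSeq(pad), body, randSeq(pad))
        pamRel <- pad + (if (pam@anchor == "3prime") L else 0L) + 1L
        protoRel <- pad + (if (pam@anchor == "3prime") 0L else m) + 1L
        protected <- rep(FALSE, nchar(str))
        protected[pamRel:(pamRel + m - 1L)] <- TRUE
        protected[protoRel:(protoRel + L - 1L)] <- TRUE  # keep mm exact
        scr <- .scrubStrays(str, protected, pam, intendedFwd = pamRel)
        if (is.null(scr)) next
        addSeg(scr,
               protoFeature("offtarget", paste0("g", i, "_ot", k),
                            paste0("g", i), protoRel, "+", copy,
                            pamInst, mm = mm),
               pamFwd = pamRel, pamRev = integer(0))
        break
      }
    }
  }

  ## ---- PAM-out nickase half-site pairs ------------------------------
  if (base::length(nickaseOffsets) && pam@anchor != "3prime")
    stop("nickase fixtures require a 3'-anchored PAM", call. = FALSE)
  for (q in seq_along(nickaseOffsets)) {
    off <- as.integer(nickaseOffsets[q])
    stopifnot(off >= 0L)
    repeat {
      protoL <- randSeq(L); protoR <- randSeq(L)
      pamL <- .samplePamInstance(pam); pamR <- .samplePamInstance(pam)
      str <- paste0(randSeq(pad), revcomp(pamL), revcomp(protoL),
                    randSeq(off), protoR, pamR, randSeq(pad))
      pamLrel <- pad + 1L
      lProtoRel <- pad + m + 1L
      rProtoRel <- pad + m + L + off + 1L
      pamRrel <- rProtoRel + L
      protected <- rep(FALSE, nchar(str))
      protected[pamLrel:(pamLrel + m - 1L)] <- TRUE
      protected[pamRrel:(pamRrel + m - 1L)] <- TRUE
      scr <- .scrubStrays(str, protected, pam, intendedFwd = pamRrel,
                          intendedRev = pamLrel)
      if (is.null(scr)) next
      protoL <- revcomp(substr(scr, lProtoRel, lProtoRel + L - 1L))
      protoR <- substr(scr, rProtoRel, rProtoRel + L - 1L)
      pid <- paste0("np", q)
      addSeg(scr, rbind(
        protoFeature("nickase_left", paste0(pid, "_left"),
                     paste0(pid, "_left"), lProtoRel, "-", protoL,
                     pamL, pair_id = pid, offset = off),
        protoFeature("nickase_right", paste0(pid, "_right"),
                     paste0(pid, "_right"), rProtoRel, "+", protoR,
                     pamR, pair_id = pid, offset = off)),
        pamFwd = pamRrel, pamRev = pamLrel)
      break
    }
  }

  ## ---- assemble: segments evenly spaced in background ---------------
  nSeg <- base::length(segs)
  segLens <- vapply(segs, function(s) nchar(s$str), integer(1L))
  avail <- length - sum(segLens)
  gap <- if (nSeg) (avail %/% (nSeg + 1L)) else avail
  if (nSeg && gap < 2L * L)
    stop("planted features do not fit in a ", length,
         "-bp genome without crowding", call. = FALSE)
  bg <- randSeq(length)
  pieces <- character(0)
  truth <- list()
  pamFwdAbs <- integer(0); pamRevAbs <- integer(0)
  cursor <- 0L       # bases emitted so far
  bgUsed <- 0L
  for (i in seq_len(nSeg)) {
    pieces <- c(pieces, substr(bg, bgUsed + 1L, bgUsed + gap))
    bgUsed <- bgUsed + gap
    cursor <- cursor + gap
    tr <- segs[[i]]$truth
    tr$start <- cursor + tr$rel_start
    tr$end <- tr$start + L - 1L
    truth[[i]] <- tr
    pamFwdAbs <- c(pamFwdAbs, cursor + segs[[i]]$pamFwd)
    pamRevAbs <- c(pamRevAbs, cursor + segs[[i]]$pamRev)
    pieces <- c(pieces, segs[[i]]$str)
    cursor <- cursor + segLens[i]
  }
  pieces <- c(pieces, substr(bg, bgUsed + 1L, bgUsed + (length - cursor)))
  gseq <- paste(pieces, collapse = "")
  stopifnot(nchar(gseq) == length)

  truth <- if (nSeg) do.call(rbind, truth) else
    data.frame(type = character(0), id = character(0),
               guide_id = character(0), rel_start = integer(0),
               strand = character(0), protospacer = character(0),
               pam_seq = character(0), mm = integer(0),
               pair_id = character(0), offset = integer(0),
               start = integer(0), end = integer(0))

  ## ---- genome-level scrub of stray PAMs -----------------------------
  if (clean) {
    protected <- rep(FALSE, length)
    for (r in seq_len(nrow(truth)))
      protected[truth$start[r]:truth$end[r]] <- TRUE
    for (p in pamFwdAbs) protected[p:(p + m - 1L)] <- TRUE
    for (p in pamRevAbs) protected[p:(p + m - 1L)] <- TRUE
    gseq <- .scrubStrays(gseq, protected, pam, intendedFwd = pamFwdAbs,
                         intendedRev = pamRevAbs, maxPasses = 200L)
    if (is.null(gseq))
      stop("could not scrub stray PAM sites around planted features; ",
           "try a different seed or more padding", call. = FALSE)
    ## planted protospacers are untouched by construction; re-verify
    for (r in seq_len(nrow(truth))) {
      obs <- substr(gseq, truth$start[r], truth$end[r])
      if (truth$strand[r] == "-") obs <- revcomp(obs)
      stopifnot(identical(obs, truth$protospacer[r]))
    }
  }

  truth$contig <- rep(contig, nrow(truth))
  truth <- truth[, c("type", "id", "guide_id", "contig", "start", "end",
                     "strand", "protospacer", "pam_seq", "mm",
                     "pair_id", "offset")]
  genome <- Biostrings::DNAStringSet(structure(gseq, names = contig))
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    tt <- file.path(dir, "truth.tsv")
    bed <- file.path(dir, "features.bed")
    Biostrings::writeXStringSet(genome, fa)
    utils::write.table(truth, tt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    gr <- GenomicRanges::GRanges(truth$contig,
            IRanges::IRanges(truth$start, truth$end),
            strand = truth$strand)
    S4Vectors::mcols(gr)$name <- truth$id
    S4Vectors::mcols(gr)$score <- 0L
    rtracklayer::export(gr, bed, format = "bed")
    paths <- c(genome = fa, truth = tt, features = bed)
  }
  list(genome = genome, truth = truth, pam = pam, guideLength = L,
       paths = paths)
}
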