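#' @include AllClasses.R iupac.R seqio.R
NULL

#' Default restriction enzyme table
#'
#' Reads the editable enzyme table shipped with the package (columns
#' \code{name}, \code{motif}; IUPAC motifs) or a user table in the same
#' format.
#'
#' @param path Optional path to an alternative enzyme TSV.
#' @return \code{data.frame} with columns \code{name}, \code{motif}.
#' @export
defaultEnzymes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.tsv", package = "guideForge",
                        mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Find restriction sites in an amplicon
#'
#' Scans the amplicon on both strands for every IUPAC-motif match.
#' Palindromic motifs (equal to their reverse complement under IUPAC
#' complementation) are reported once per position; non-palindromic
#' motifs are reported per strand.  An enzyme is flagged
#' \code{unique_in_amplicon} when it matches exactly once, which makes
#' it usable for RFLP validation; when \code{cutPos} is given (the base
#' after which the nuclease cut falls, amplicon coordinates),
#' \code{overlaps_cut} flags sites spanning the cut.
#'
#' @param amplicon DNA string (A/C/G/T/N).
#' @param enzymes \code{data.frame} with columns \code{name},
#'   \code{motif} (default \code{\link{defaultEnzymes}()}); malformed
#'   motifs are skipped with a warning.
#' @param cutPos Optional cut position (1-based; cut after this base).
#' @return \code{DataFrame} with columns \code{enzyme}, \code{motif},
#'   \code{pos} (1-based match start), \code{strand},
#'   \code{unique_in_amplicon}, \code{overlaps_cut}.
#' @export
findRestrictionSites <- function(amplicon, enzymes = defaultEnzymes(),
                                 cutPos = NULL) {
  stopifnot(is.character(amplicon), length(amplicon) == 1L)
  amplicon <- toupper(amplicon)
  enc <- .encodeSubject(amplicon)
  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    motif <- toupper(enzymes$motif[i])
    encM <- tryCatch(.encodePattern(motif), error = function(e) NULL)
    if (is.null(encM)) {
      warning("skipping enzyme ", enzymes$name[i],
              ": malformed motif '", enzymes$motif[i], "'", call. = FALSE)
      next
    }
    if (nchar(motif) > nchar(amplicon)) next
    fwd <- .scanEncoded(enc, encM)
    rcM <- revcomp(motif)
    rev <- if (identical(motif, rcM)) integer(0)
           else .scanEncoded(enc, .encodePattern(rcM))
    k <- length(fwd) + length(rev)
    if (k == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      enzyme = enzymes$name[i], motif = motif,
      pos = c(fwd, rev),
      strand = c(rep("+", length(fwd)), rep("-", length(rev))),
      unique_in_amplicon = k == 1L,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(S4Vectors::DataFrame(
      enzyme = character(0), motif = character(0), pos = integer(0),
      strand = character(0), unique_in_amplicon = logical(0),
      overlaps_cut = logical(0)))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$pos, df$enzyme, df$strand), , drop = FALSE]
  df$overlaps_cut <- if (is.null(cutPos)) NA else
    df$pos <= cutPos & (df$pos + nchar(df$motif) - 1L) >= cutPos + 1L
  S4Vectors::DataFrame(df, row.names = NULL)
}

## Nearest-neighbor parameter table, cached per session.
.nnCache <- new.env(parent = emptyenv())

#' @noRd
.nnParams <- function() {
  if (!is.null(.nnCache$tab)) return(.nnCache$tab)
  path <- system.file("extdata", "nn_thermo.tsv", package = "guideForge",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  .nnCache$tab <- tab
  tab
}

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature from nearest-neighbor thermodynamics
#' (unified DNA/DNA parameter set, shipped as an editable table in
#' \code{extdata/nn_thermo.tsv}): the stacking enthalpies/entropies of
#' all dinucleotide steps plus terminal initiation terms, an entropic
#' salt correction of \eqn{0.368 (N-1) \ln[Na^+]}, and
#' \eqn{T_m = \Delta H / (\Delta S + R \ln(C_T/4)) - 273.15}.
#' Because the parameters describe the duplex, a primer and its reverse
#' complement have identical Tm.
#'
#' @param primer DNA string, 10-40 nt, A/C/G/T.
#' @param conc Total strand concentration in M (default 2.5e-7, i.e.
#'   250 nM primer).
#' @param na Monovalent cation concentration in M (default 0.05).
#' @return Melting temperature in degrees Celsius.
#' @export
meltingTemp <- function(primer, conc = 2.5e-7, na = 0.05) {
  stopifnot(is.character(primer), length(primer) == 1L)
  primer <- toupper(primer)
  n <- nchar(primer)
  if (n < 10L || n > 40L)
    stop("primer length must be 10-40 nt (got ", n, ")", call. = FALSE)
  if (grepl("[^ACGT]", primer))
    stop("primer must be an A/C/G/T string", call. = FALSE)
  tab <- .nnParams()
  steps <- substring(primer, 1:(n - 1L), 2:n)
  idx <- match(steps, tab$step)
  dH <- sum(tab$dH_kcal[idx])          # kcal/mol
  dS <- sum(tab$dS_cal[idx])           # cal/(mol K)
  ends <- substring(primer, c(1L, n), c(1L, n))
  for (e in ends) {
    init <- if (e %in% c("G", "C")) "init_GC" else "init_AT"
    j <- match(init, tab$step)
    dH <- dH + tab$dH_kcal[j]
    dS <- dS + tab$dS_cal[j]
  }
  dS <- dS + 0.368 * (n - 1L) * log(na)
  dH * 1000 / (dS + 1.987 * log(conc / 4)) - 273.15
}

#' Design flanking primers around a cut site
#'
#' Exhaustively scans candidate left and right primers around
#' \code{cutPos} subject to length, melting-temperature and
#' product-size constraints, requiring the product to contain the cut
#' with at least \code{minMargin} bp on each side.  Pairs are ranked by
#' Tm balance (\code{|Tm_left - Tm_right|}), then by closeness of the
#' product size to the midpoint of \code{productRange}.  This internal
#' designer keeps the package dependency-free; an external
#' Primer3-compatible engine can be plugged in through the
#' \code{engine} argument, which must return the same columns.
#'
#' @param genome Named \code{DNAStringSet}.
#' @param contig Contig name.
#' @param cutPos Cut position (1-based; cut after this base).
#' @param lenRange Primer length range, nt (default \code{c(18, 25)}).
#' @param tmRange Primer Tm band, Celsius (default \code{c(57, 63)}).
#' @param productRange Amplicon size range, bp (default
#'   \code{c(200, 600)}).
#' @param minMargin Minimum distance of the cut from each product end,
#'   bp (default 50).
#' @param maxPairs Maximum number of ranked pairs to return (default
#'   100).
#' @param engine Optional replacement designer,
#'   \code{function(seq, cutPos, ...)}.
#' @return \code{DataFrame} of ranked pairs with columns
#'   \code{left_seq}, \code{right_seq}, \code{left_tm}, \code{right_tm},
#'   \code{left_start}, \code{right_end} (genomic), \code{product_size};
#'   zero rows when the constraints are unsatisfiable.
#' @export
designPrimers <- function(genome, contig, cutPos,
                          lenRange = c(18L, 25L), tmRange = c(57, 63),
                          productRange = c(200L, 600L), minMargin = 50L,
                          maxPairs = 100L, engine = NULL) {
  stopifnot(contig %in% names(genome))
  seqStr <- as.character(genome[[contig]])
  n <- nchar(seqStr)
  if (!is.null(engine))
    return(engine(seqStr, cutPos, lenRange = lenRange, tmRange = tmRange,
                  productRange = productRange, minMargin = minMargin))
  empty <- S4Vectors::DataFrame(
    left_seq = character(0), right_seq = character(0),
    left_tm = numeric(0), right_tm = numeric(0),
    left_start = integer(0), right_end = integer(0),
    product_size = integer(0))
  if (productRange[1L] < 2L * minMargin) {
    ## a product this small cannot hold the cut with both margins unless
    ## the minimum size is raised; geometry may still be satisfiable
    ## with larger products, so only the truly infeasible case aborts
    if (productRange[2L] < 2L * minMargin) return(empty)
  }
  if (cutPos - minMargin < 1L || cutPos + minMargin > n)
    stop("cut site at ", contig, ":", cutPos, " is too close to the ",
         "contig end for a ", minMargin, "-bp margin", call. = FALSE)
  ## candidate left primers: substrings starting in
  ## [cutPos - (productMax - margin) .. cutPos - margin]
  scanSide <- function(startMin, startMax, right) {
    cand <- list()
    for (len in lenRange[1L]:lenRange[2L]) {
      ss <- max(1L, startMin):max(1L, startMax)
      ss <- ss[ss + len - 1L <= n]
      if (!length(ss)) next
      sq <- substring(seqStr, ss, ss + len - 1L)
      keep <- !grepl("N", sq, fixed = TRUE)
      ss <- ss[keep]; sq <- sq[keep]
      if (!length(ss)) next
      if (right)
        sq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(sq)))
      tm <- vapply(sq, meltingTemp, numeric(1L), USE.NAMES = FALSE)
      ok <- tm >= tmRange[1L] & tm <= tmRange[2L]
      if (any(ok))
        cand[[length(cand) + 1L]] <- data.frame(
          start = ss[ok], end = ss[ok] + len - 1L, seq = sq[ok],
          tm = tm[ok], stringsAsFactors = FALSE)
    }
    if (length(cand)) do.call(rbind, cand) else NULL
  }
  lefts <- scanSide(cutPos - (productRange[2L] - minMargin),
                    cutPos - minMargin, right = FALSE)
  rights <- scanSide(cutPos + minMargin - lenRange[2L] + 1L,
                     cutPos + productRange[2L] - minMargin, right = TRUE)
  if (is.null(lefts) || is.null(rights)) return(empty)
  ## the right primer's genomic segment must END at the product end
  rights <- rights[rights$end >= cutPos + minMargin, , drop = FALSE]
  ## product-edge margins: product spans [left$start, right$end]
  lefts <- lefts[cutPos - lefts$start >= minMargin, , drop = FALSE]
  if (!nrow(lefts) || !nrow(rights)) return(empty)
  pairs <- list()
  for (i in seq_len(nrow(lefts))) {
    sz <- rights$end - lefts$start[i] + 1L
    ok <- sz >= productRange[1L] & sz <= productRange[2L] &
      rights$end - cutPos >= minMargin &
      rights$start > lefts$end[i]
    if (!any(ok)) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      left_seq = lefts$seq[i], right_seq = rights$seq[ok],
      left_tm = lefts$tm[i], right_tm = rights$tm[ok],
      left_start = lefts$start[i], right_end = rights$end[ok],
      product_size = sz[ok], stringsAsFactors = FALSE)
  }
  if (!length(pairs)) return(empty)
  df <- do.call(rbind, pairs)
  mid <- mean(productRange)
  ord <- order(abs(df$left_tm - df$right_tm),
               abs(df$product_size - mid),
               df$left_start, df$right_end)
  df <- df[ord, , drop = FALSE]
  if (nrow(df) > maxPairs) df <- df[seq_len(maxPairs), , drop = FALSE]
  S4Vectors::DataFrame(df, row.names = NULL)
}
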