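## Bitmask-encoded IUPAC matching.
##
## Every concrete base maps to one bit (A=1, C=2, G=4, T=8); a degenerate
## code maps to the union of its bases.  A pattern position matches a
## subject base iff their masks intersect.  Genomic N is deliberately
## encoded as 0 so that it matches NO pattern code, including N: assembly
## gaps never produce candidate or off-target sites.

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L,  Y = 10L, S = 6L,  W = 9L,
  K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L,
  N = 15L
)

.BASE_OF_BIT <- c(`1` = "A", `2` = "C", `4` = "G", `8` = "T")

#' @noRd
.encodePattern <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  bits <- unname(.IUPAC_BITS[chars])
  if (anyNA(bits)) {
    bad <- chars[is.na(bits)][1L]
    stop("invalid IUPAC code '", bad, "' in pattern '", pattern, "'",
         call. = FALSE)
  }
  bits
}

## Subject alphabet is A,C,G,T,N only; N encodes to 0 (matches nothing).
.SUBJECT_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 0L)

#' @noRd
.encodeSubject <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bits <- unname(.SUBJECT_BITS[chars])
  if (anyNA(bits)) {
    bad <- chars[is.na(bits)][1L]
    stop("subject sequence contains non-ACGTN character '", bad, "'",
         call. = FALSE)
  }
  bits
}

## All start positions (1-based) in an encoded subject where an encoded
## pattern matches.  O(m) vector sweeps over the subject.
#' @noRd
.scanEncoded <- function(encSubject, encPattern) {
  n <- length(encSubject)
  m <- length(encPattern)
  if (n < m) return(integer(0))
  k <- n - m + 1L
  ok <- rep(TRUE, k)
  for (j in seq_len(m)) {
    ok <- ok & bitwAnd(encSubject[j:(j + k - 1L)], encPattern[j]) > 0L
  }
  which(ok)
}

#' Match a degenerate IUPAC pattern against concrete sequences
#'
#' Tests whether each sequence in \code{x} is accepted by \code{pattern},
#' position by position, under the IUPAC ambiguity codes.  An \code{N} in
#' the \emph{subject} matches no pattern code (including pattern
#' \code{N}): unknown genomic bases are never treated as targets.
#'
#' @param pattern A single IUPAC string (e.g. \code{"NGG"}, \code{"NNGRRT"}).
#' @param x Character vector of concrete DNA strings (A/C/G/T/N), each the
#'   same length as \code{pattern}.
#' @return Logical vector, one element per sequence in \code{x}.
#' @examples
#' iupacMatch("NGG", c("AGG", "AGT"))     # TRUE FALSE
#' iupacMatch("NNGRRT", "CCGAGT")         # TRUE
#' @export
iupacMatch <- function(pattern, x) {
  ep <- .encodePattern(pattern)
  vapply(x, function(s) {
    es <- .encodeSubject(s)
    if (length(es) != length(ep))
      stop("pattern and sequence lengths differ (",
           length(ep), " vs ", length(es), ")", call. = FALSE)
    all(bitwAnd(es, ep) > 0L)
  }, logical(1L), USE.NAMES = FALSE)
}

#' Expand a degenerate IUPAC pattern into all concrete sequences
#'
#' @param pattern IUPAC string of length at most 12 (the expansion is the
#'   product of per-position code cardinalities; longer patterns are
#'   refused to avoid combinatorial blow-up).
#' @return Character vector of all A/C/G/T strings matching the pattern,
#'   in lexicographic per-position order.
#' @examples
#' expandIupac("NGG")  # AGG CGG GGG TGG
#' @export
expandIupac <- function(pattern) {
  if (nchar(pattern) > 12L)
    stop("pattern '", pattern, "' is longer than 12 positions; ",
         "expansion refused (up to 4^12 sequences)", call. = FALSE)
  ep <- .encodePattern(pattern)
  bitvals <- c(1L, 2L, 4L, 8L)
  sets <- lapply(ep, function(b)
    unname(.BASE_OF_BIT[as.character(bitvals[bitwAnd(b, bitvals) > 0L])]))
  if (length(sets) == 0L) return(character(0))
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}
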