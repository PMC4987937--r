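#' @include AllClasses.R iupac.R
NULL

#' Read a genome from FASTA
#'
#' Loads a (multi-)FASTA file into a named \link[Biostrings]{DNAStringSet}
#' restricted to the A/C/G/T/N alphabet.  Sequences are uppercased
#' (soft-masking is ignored) and any character outside A/C/G/T/N --
#' ambiguity codes included -- is replaced by \code{N} with a warning
#' reporting the substitution count; N is excluded from all downstream
#' matching, which is the conservative choice.
#'
#' @param path Path to a FASTA file.
#' @return Named \code{DNAStringSet}; names are the first whitespace-
#'   delimited token of each header.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(set) == 0L)
    stop("FASTA file '", path, "' contains no sequences", call. = FALSE)
  names(set) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(set))) {
    dup <- names(set)[duplicated(names(set))][1L]
    stop("duplicate FASTA header '", dup, "' in ", path, call. = FALSE)
  }
  if (any(Biostrings::width(set) == 0L)) {
    empty <- names(set)[Biostrings::width(set) == 0L][1L]
    stop("empty sequence for header '", empty, "' in ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  nonACGTN <- vapply(seqs, function(s)
    sum(strsplit(gsub("[ACGTN]", "", s), "", fixed = TRUE)[[1L]] != ""),
    integer(1L))
  if (sum(nonACGTN) > 0L) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(sum(nonACGTN), " non-ACGTN character(s) replaced by N in ",
            path, call. = FALSE)
  }
  Biostrings::DNAStringSet(structure(seqs, names = names(set)))
}

#' Write a genome to FASTA
#'
#' @param genome Named \code{DNAStringSet} (or named character vector).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, filepath = path, format = "fasta")
  invisible(path)
}

#' Reverse-complement an IUPAC nucleotide string
#'
#' IUPAC-aware: degenerate codes complement to their mirror codes
#' (R<->Y, K<->M, B<->V, D<->H; S, W and N are self-complementary).
#'
#' @param seq A single DNA string (IUPAC alphabet; U is read as T).
#' @return The reverse complement as a character string.
#' @examples
#' revcomp("NNGRRT")  # "AYYCNN"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  up <- toupper(chartr("Uu", "Tt", seq))
  if (grepl("[^ACGTRYSWKMBDHVN]", up)) {
    bad <- regmatches(up, regexpr("[^ACGTRYSWKMBDHVN]", up))
    stop("cannot reverse-complement character '", bad, "'", call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(up)))
}

#' Extract a (strand-aware) region from a genome
#'
#' @param genome Named \code{DNAStringSet}.
#' @param region Length-1 \code{GRanges} (1-based inclusive); a
#'   \code{"-"} strand returns the reverse complement.
#' @return Character string of length \code{width(region)}.
#' @export
extractRegion <- function(genome, region) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  contig <- as.character(GenomicRanges::seqnames(region))
  if (!contig %in% names(genome))
    stop("contig '", contig, "' not present in genome", call. = FALSE)
  s <- GenomicRanges::start(region)
  e <- GenomicRanges::end(region)
  n <- length(genome[[contig]])
  if (s < 1L || e > n)
    stop("region ", contig, ":", s, "-", e,
         " out of bounds (contig length ", n, ")", call. = FALSE)
  sub <- Biostrings::subseq(genome[[contig]], start = s, end = e)
  if (as.character(GenomicRanges::strand(region)) == "-")
    sub <- Biostrings::reverseComplement(sub)
  as.character(sub)
}

#' Read gene models from BED12
#'
#' Parses a BED12 file into \linkS4class{GeneModel} objects: blocks
#' become exons, the thick interval becomes the CDS (absent when
#' thickStart == thickEnd), and the TSS is the strand-aware transcript
#' start.  Block arithmetic is validated up front; an inconsistent
#' record is fatal and reports its line number.
#'
#' @param path Path to a tab-separated BED12 file.
#' @return Named list of \linkS4class{GeneModel} (names = column 4).
#' @export
readBed12 <- function(path) {
  if (!file.exists(path))
    stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("no records in BED file ", path, call. = FALSE)
  ## pre-validate block arithmetic with line numbers before handing the
  ## file to rtracklayer
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      stop("line ", lineno[i], " of ", path, ": expected 12 BED fields, got ",
           length(f), call. = FALSE)
    cs <- as.integer(f[2L]); ce <- as.integer(f[3L])
    nb <- as.integer(f[10L])
    sizes <- as.integer(strsplit(sub(",$", "", f[11L]), ",")[[1L]])
    starts <- as.integer(strsplit(sub(",$", "", f[12L]), ",")[[1L]])
    if (length(sizes) != nb || length(starts) != nb)
      stop("line ", lineno[i], " of ", path,
           ": blockCount disagrees with block lists", call. = FALSE)
    if (starts[1L] != 0L || cs + starts[nb] + sizes[nb] != ce)
      stop("line ", lineno[i], " of ", path,
           ": block arithmetic inconsistent with chromStart/chromEnd",
           call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "bed")
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    rec <- gr[i]
    contig <- as.character(GenomicRanges::seqnames(rec))
    strand <- as.character(GenomicRanges::strand(rec))
    s <- GenomicRanges::start(rec); e <- GenomicRanges::end(rec)
    blocks <- S4Vectors::mcols(rec)$blocks[[1L]]  # 1-based, relative
    ex <- GenomicRanges::GRanges(contig,
            IRanges::IRanges(start = s + IRanges::start(blocks) - 1L,
                             end = s + IRanges::end(blocks) - 1L),
            strand = strand)
    thick <- S4Vectors::mcols(rec)$thick
    cds <- if (is.null(thick) || length(thick) == 0L ||
               IRanges::width(thick)[1L] == 0L)
      GenomicRanges::GRanges()
    else
      GenomicRanges::GRanges(contig, thick, strand = strand)
    out[[i]] <- new("GeneModel",
      name = S4Vectors::mcols(rec)$name,
      txRegion = GenomicRanges::granges(rec),
      exons = ex,
      cds = cds,
      tss = if (strand == "-") e else s)
  }
  names(out) <- vapply(out, function(m) m@name, character(1L))
  out
}
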