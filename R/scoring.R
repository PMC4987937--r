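#' @include AllClasses.R AllGenerics.R iupac.R
NULL

#' GC fraction of a protospacer
#'
#' GC content is computed over the protospacer only (the PAM is
#' excluded).  The "ideal" window of 40-80 percent, bounds inclusive, is
#' available through \code{\link{gcIdeal}}.
#'
#' @param x Character vector of A/C/G/T protospacer strings.
#' @return Numeric vector of fractions in [0, 1].
#' @export
gcFraction <- function(x) {
  stopifnot(is.character(x), all(nzchar(x)))
  if (any(grepl("[^ACGT]", x)))
    stop("protospacer must be an ACGT string", call. = FALSE)
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' @rdname gcFraction
#' @param lower,upper Ideal-window bounds as fractions, inclusive
#'   (defaults 0.40 and 0.80).
#' @export
gcIdeal <- function(x, lower = 0.40, upper = 0.80) {
  gc <- if (is.numeric(x)) x else gcFraction(x)
  gc >= lower & gc <= upper
}

#' PAM-proximal G flag
#'
#' For 3'-anchored effectors, reports whether the PAM-adjacent spacer
#' base -- position 20 of a 20-nt guide, generalized to the final base
#' for other lengths -- is \code{G}.  For 5'-anchored effectors the
#' check does not apply and \code{NA} is returned.
#'
#' @param x Character vector of protospacers, 5'->3' in guide
#'   orientation.
#' @param anchor \code{"3prime"} (default) or \code{"5prime"}.
#' @return Logical vector (\code{NA} when not applicable).
#' @export
pamProximalG <- function(x, anchor = c("3prime", "5prime")) {
  anchor <- match.arg(anchor)
  if (anchor == "5prime") return(rep(NA, length(x)))
  substring(x, nchar(x), nchar(x)) == "G"
}

## Base pairing predicate matrices (rows/cols A,C,G,T).
.pairMatrix <- function(wobble = FALSE) {
  m <- matrix(FALSE, 4L, 4L, dimnames = list(c("A", "C", "G", "T"),
                                             c("A", "C", "G", "T")))
  m["A", "T"] <- m["T", "A"] <- TRUE
  m["C", "G"] <- m["G", "C"] <- TRUE
  if (wobble) m["G", "T"] <- m["T", "G"] <- TRUE
  m
}

## Count maximal runs of TRUE of length >= minLen.
.runCount <- function(valid, minLen) {
  if (!length(valid)) return(0L)
  r <- rle(valid)
  sum(r$values & r$lengths >= minLen)
}

#' Count self-complementarity stems
#'
#' Counts potential duplexes that could fold the spacer onto itself or
#' pair it with the invariant sgRNA scaffold ("backbone"), both of which
#' impair loading into the effector complex.  A stem is a maximal
#' antiparallel duplex of at least \code{minStem} consecutive base pairs
#' -- Watson-Crick, plus G:T(U) when \code{wobble = TRUE}.
#' Intramolecular stems additionally require at least \code{minLoop}
#' unpaired bases between the two halves.  Each maximal duplex counts
#' once (a 5-bp stem is one stem, not two 4-bp windows).
#'
#' @param guide Protospacer string (A/C/G/T), 5'->3'.
#' @param backbone Scaffold sequence as DNA (\code{""} to skip the
#'   cross-molecular count); default \code{\link{defaultBackbone}()}.
#' @param minStem Minimum duplex length in bp (default 4; values < 2 are
#'   refused).
#' @param minLoop Minimum intramolecular loop length in nt (default 3).
#' @param wobble Allow G:T(U) pairs (default \code{FALSE}).
#' @return Non-negative integer stem count (intramolecular + guide vs
#'   backbone).
#' @examples
#' selfComp(paste0("GGGG", strrep("A", 12), "CCCC"), backbone = "")  # 1
#' @export
selfComp <- function(guide, backbone = defaultBackbone(), minStem = 4L,
                     minLoop = 3L, wobble = FALSE) {
  stopifnot(is.character(guide), length(guide) == 1L, nzchar(guide))
  if (minStem < 2L)
    stop("'minStem' must be >= 2", call. = FALSE)
  pm <- .pairMatrix(wobble)
  g <- strsplit(toupper(guide), "", fixed = TRUE)[[1L]]
  gi <- match(g, c("A", "C", "G", "T"))  # NA (e.g. N) never pairs
  n <- length(gi)
  count <- 0L
  ## intramolecular: walk anti-diagonals x + y = s of the pairing
  ## matrix; a run of pairable (x, y) with y - x - 1 >= minLoop is a stem
  for (s in seq_len(2L * n - 1L) + 1L) {     # s = x + y, 3 .. 2n-1
    xs <- max(1L, s - n):min(n, s - 1L)
    xs <- xs[xs < s - xs]                     # x < y
    if (!length(xs)) next
    ys <- s - xs
    ok <- !is.na(gi[xs]) & !is.na(gi[ys]) &
      pm[cbind(gi[xs], gi[ys])] & (ys - xs - 1L >= minLoop)
    count <- count + .runCount(ok, minStem)
  }
  ## guide vs backbone: anti-diagonals of the cross pairing matrix
  if (nzchar(backbone)) {
    b <- strsplit(toupper(chartr("U", "T", backbone)), "",
                  fixed = TRUE)[[1L]]
    bi <- match(b, c("A", "C", "G", "T"))
    nb <- length(bi)
    for (s in 2L:(n + nb)) {                  # s = x + y
      xs <- max(1L, s - nb):min(n, s - 1L)
      ys <- s - xs
      ok <- !is.na(gi[xs]) & !is.na(bi[ys]) & pm[cbind(gi[xs], bi[ys])]
      count <- count + .runCount(ok, minStem)
    }
  }
  count
}

#' Default sgRNA scaffold sequence
#'
#' The invariant S. pyogenes sgRNA scaffold, DNA alphabet, read from the
#' editable resource file \code{extdata/backbone.txt} (override with any
#' file of the same one-sequence-per-line format).
#'
#' @param path Optional path to an alternative backbone file.
#' @return Character string.
#' @export
defaultBackbone <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "backbone.txt", package = "guideForge",
                        mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  toupper(chartr("U", "T", trimws(lines[1L])))
}

#' Load / write a position-feature efficiency model
#'
#' The model file is a TSV whose header comments carry the scalar keys
#' (\code{# name=...}, \code{# window=4,20,3,3}, \code{# link=identity},
#' \code{# intercept=0}), followed by one feature per row:
#' \code{offset<TAB>kmer<TAB>weight}.  Offsets are 1-based positions
#' within the context window; a feature contributes its weight when its
#' k-mer matches the context at that offset.
#'
#' @param path Path to a model TSV.
#' @return \code{loadEfficiencyModel}: an \linkS4class{EfficiencyModel};
#'   \code{writeEfficiencyModel}: \code{path}, invisibly.
#' @export
loadEfficiencyModel <- function(path) {
  if (!file.exists(path))
    stop("model file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getKey <- function(key, required = TRUE) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (!length(hit)) {
      if (required) stop("model file missing header key '", key, "'",
                         call. = FALSE)
      return(NA_character_)
    }
    trimws(sub(paste0("^#\\s*", key, "\\s*="), "", hit[1L]))
  }
  name <- getKey("name")
  window <- as.integer(strsplit(getKey("window"), ",")[[1L]])
  link <- getKey("link")
  intercept <- suppressWarnings(as.numeric(getKey("intercept")))
  if (is.na(intercept))
    stop("model intercept is not numeric", call. = FALSE)
  dataLineNos <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  ## tolerate an optional column-header line
  if (length(dataLineNos) &&
      grepl("^offset\\b", lines[dataLineNos[1L]]))
    dataLineNos <- dataLineNos[-1L]
  feats <- data.frame(offset = integer(0), kmer = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  W <- sum(window)
  for (ln in dataLineNos) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 3L)
      stop("model file row at line ", ln, ": expected 3 tab-separated ",
           "fields", call. = FALSE)
    offset <- suppressWarnings(as.integer(f[1L]))
    weight <- suppressWarnings(as.numeric(f[3L]))
    kmer <- toupper(f[2L])
    if (is.na(offset) || is.na(weight))
      stop("model file row at line ", ln, ": non-numeric offset or weight",
           call. = FALSE)
    if (offset < 1L || offset + nchar(kmer) - 1L > W)
      stop("model file row at line ", ln, ": feature offset ", offset,
           " (kmer ", kmer, ") outside the ", W, "-bp window", call. = FALSE)
    feats <- rbind(feats, data.frame(offset = offset, kmer = kmer,
                                     weight = weight,
                                     stringsAsFactors = FALSE))
  }
  new("EfficiencyModel", name = name, window = window,
      intercept = intercept, features = feats, link = link)
}

#' @rdname loadEfficiencyModel
#' @param model An \linkS4class{EfficiencyModel}.
#' @export
writeEfficiencyModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# name=", model@name),
    paste0("# window=", paste(model@window, collapse = ",")),
    paste0("# link=", model@link),
    paste0("# intercept=", format(model@intercept, digits = 17))), con)
  if (nrow(model@features))
    writeLines(sprintf("%d\t%s\t%s", model@features$offset,
                       model@features$kmer,
                       format(model@features$weight, digits = 17)), con)
  invisible(path)
}

#' Predicted cutting-efficiency score
#'
#' Evaluates a linear position-feature model on each candidate's scoring
#' context: intercept plus the weights of all features whose k-mer
#' matches the context at its offset, passed through the model's link
#' (logistic: \eqn{1/(1+e^{-s})}).  The model is refused unless its
#' window geometry (upstream, guide, PAM, downstream lengths) equals the
#' candidates'.  A candidate whose context is N-padded at positions any
#' feature would read scores \code{NA}.
#'
#' @param x A \linkS4class{GuideSet}, or a character vector of context
#'   windows of the model's total width.
#' @param model An \linkS4class{EfficiencyModel}.
#' @return Numeric vector of scores (\code{NA} = unavailable).
#' @export
efficiencyScore <- function(x, model) {
  stopifnot(is(model, "EfficiencyModel"))
  W <- sum(model@window)
  if (is(x, "GuideSet")) {
    if (model@window[2L] != x@guideLength)
      stop("model '", model@name, "' expects ", model@window[2L],
           "-nt guides; candidates are ", x@guideLength, " nt", call. = FALSE)
    if (model@window[3L] != nchar(x@pam@pattern))
      stop("model '", model@name, "' expects a ", model@window[3L],
           "-nt PAM; enumeration used ", nchar(x@pam@pattern), " nt",
           call. = FALSE)
    if (!all(model@window[c(1L, 4L)] == x@contextFlank))
      stop("model '", model@name, "' expects context flanks ",
           model@window[1L], "+", model@window[4L],
           "; candidates carry ", x@contextFlank[1L], "+",
           x@contextFlank[2L], call. = FALSE)
    ctx <- S4Vectors::mcols(x@guides)$context
    padL <- S4Vectors::mcols(x@guides)$pad_left
    padR <- S4Vectors::mcols(x@guides)$pad_right
  } else {
    ctx <- as.character(x)
    padL <- padR <- rep(0L, length(ctx))
  }
  if (length(ctx) && !all(nchar(ctx) == W))
    stop("context length does not match the model window (", W, " bp)",
         call. = FALSE)
  f <- model@features
  vapply(seq_along(ctx), function(i) {
    if (padL[i] + padR[i] > 0L && nrow(f)) {
      touches <- f$offset <= padL[i] |
        (f$offset + nchar(f$kmer) - 1L) > (W - padR[i])
      if (any(touches)) return(NA_real_)
    }
    s <- model@intercept
    if (nrow(f)) {
      obs <- substring(ctx[i], f$offset, f$offset + nchar(f$kmer) - 1L)
      s <- s + sum(f$weight[obs == f$kmer])
    }
    if (model@link == "logistic") 1 / (1 + exp(-s)) else s
  }, numeric(1L))
}

#' Score a set of guide candidates
#'
#' Convenience wrapper computing the per-guide quality metrics: GC
#' fraction and ideal-window flag, PAM-proximal G flag,
#' self-complementarity stem count, and (when a model is supplied) the
#' efficiency score.
#'
#' @param gs A \linkS4class{GuideSet}.
#' @param model Optional \linkS4class{EfficiencyModel}.
#' @param backbone Scaffold string for \code{\link{selfComp}}.
#' @param wobble Allow G:T pairs in stem counting.
#' @param gcBounds Ideal GC window (fractions, inclusive).
#' @param minStem,minLoop Stem-counting parameters.
#' @return \code{DataFrame} with columns \code{gc_fraction},
#'   \code{gc_ideal}, \code{pam_proximal_g}, \code{selfcomp},
#'   \code{efficiency}, \code{model_name}, one row per candidate.
#' @export
scoreGuides <- function(gs, model = NULL, backbone = defaultBackbone(),
                        wobble = FALSE, gcBounds = c(0.40, 0.80),
                        minStem = 4L, minLoop = 3L) {
  stopifnot(is(gs, "GuideSet"))
  proto <- S4Vectors::mcols(gs@guides)$protospacer
  gc <- if (length(proto)) gcFraction(proto) else numeric(0)
  sc <- vapply(proto, selfComp, integer(1L), backbone = backbone,
               minStem = minStem, minLoop = minLoop, wobble = wobble,
               USE.NAMES = FALSE)
  eff <- if (is.null(model)) rep(NA_real_, length(proto))
         else efficiencyScore(gs, model)
  S4Vectors::DataFrame(
    id = S4Vectors::mcols(gs@guides)$id,
    gc_fraction = gc,
    gc_ideal = gcIdeal(gc, gcBounds[1L], gcBounds[2L]),
    pam_proximal_g = pamProximalG(proto, gs@pam@anchor),
    selfcomp = sc,
    efficiency = eff,
    model_name = rep(if (is.null(model)) NA_character_ else model@name,
                     length(proto)))
}
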