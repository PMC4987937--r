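#' @include AllClasses.R AllGenerics.R iupac.R
NULL

#' Built-in effector presets
#'
#' Reads the editable preset table shipped with the package (or a
#' user-supplied table in the same format) into
#' \linkS4class{EffectorPreset} objects.  The shipped table covers the
#' commonly used Cas9 homologs and AsCpf1, with PAMs and default spacer
#' lengths taken from each effector's primary characterization
#' literature; every value can be overridden by editing a copy of the
#' TSV or by constructing a \linkS4class{PamSpec} directly.
#'
#' @param path Optional path to a preset TSV with columns \code{name},
#'   \code{pam}, \code{anchor} (\code{3prime}/\code{5prime}),
#'   \code{guide_length}, \code{cut_offset}.
#' @return Named list of \linkS4class{EffectorPreset}.
#' @examples
#' names(effectorPresets())
#' effectorPreset("SpCas9")
#' @export
effectorPresets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "effectors.tsv", package = "guideForge",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("name", "pam", "anchor", "guide_length", "cut_offset")
  if (!all(need %in% colnames(tab)))
    stop("preset table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$name))
    stop("duplicate preset name '",
         tab$name[duplicated(tab$name)][1L], "'", call. = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    new("EffectorPreset",
        name = tab$name[i],
        pam = pamSpec(tab$pam[i], anchor = tab$anchor[i],
                      name = tab$name[i]),
        guideLength = as.integer(tab$guide_length[i]),
        cutOffset = as.integer(tab$cut_offset[i])))
  names(out) <- tab$name
  out
}

#' @rdname effectorPresets
#' @param name Preset name (case-insensitive), e.g. \code{"SpCas9"}.
#' @export
effectorPreset <- function(name, path = NULL) {
  presets <- effectorPresets(path)
  hit <- match(tolower(name), tolower(names(presets)))
  if (is.na(hit))
    stop("unknown effector preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[hit]]
}
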