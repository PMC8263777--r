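#' Load a 27-entry SOC vocabulary table
#'
#' Reads a tab-separated table with columns \code{soc_code},
#' \code{soc_name} and \code{abbreviation} and validates it as the
#' analysis universe: exactly 27 system organ classes with unique codes
#' and abbreviations. The file's row order is preserved and fixes the
#' ordering of all downstream matrices.
#'
#' @param path path to a UTF-8 tab-separated file with a header row.
#' @return a \linkS4class{SOCVocabulary}.
#' @examples
#' vocab <- defaultSOCVocabulary()
#' socCodes(vocab)[1:5]
#' @export
loadSOCVocabulary <- function(path) {
    stopifnot(file.exists(path))
    e <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
    need <- c("soc_code", "soc_name", "abbreviation")
    if (!all(need %in% names(e)))
        stop("SOC vocabulary must have columns: ", paste(need, collapse = ", "))
    if (nrow(e) != 27L)
        stop("vocabulary-size error: expected 27 SOCs, got ", nrow(e))
    if (anyDuplicated(e$soc_code))
        stop("duplicate-entry error: repeated soc_code in vocabulary")
    if (anyDuplicated(e$abbreviation))
        stop("duplicate-entry error: repeated abbreviation in vocabulary")
    new("SOCVocabulary", entries = e[, need])
}

#' The packaged default 27-SOC vocabulary
#'
#' The 27 MedDRA system organ classes in alphabetical order, with the
#' short codes and abbreviations used throughout the package.
#'
#' @return a \linkS4class{SOCVocabulary} with 27 entries.
#' @export
defaultSOCVocabulary <- function() {
    loadSOCVocabulary(system.file("extdata", "soc_vocabulary.tsv",
                                  package = "socsafety", mustWork = TRUE))
}

#' @describeIn loadSOCVocabulary SOC codes, in vocabulary order.
#' @param vocab a \linkS4class{SOCVocabulary}.
#' @export
socCodes <- function(vocab) vocab@entries$soc_code

#' @describeIn loadSOCVocabulary full SOC names, in vocabulary order.
#' @export
socNames <- function(vocab) vocab@entries$soc_name

#' @describeIn loadSOCVocabulary SOC abbreviations, in vocabulary order.
#' @export
socAbbreviations <- function(vocab) vocab@entries$abbreviation
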