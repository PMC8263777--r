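#' Normalize a reaction or drug term for dictionary lookup
#'
#' FAERS reaction and drug strings vary in case, spacing and trailing
#' punctuation. Normalization case-folds, collapses internal whitespace,
#' and strips surrounding (not internal) punctuation, and is idempotent:
#' applying it twice gives the same key as applying it once.
#'
#' @param x character vector of raw terms; elements must be non-empty.
#' @return character vector of normalized keys.
#' @examples
#' normalizeTerm("  Cardiac   Arrest ")  # "cardiac arrest"
#' normalizeTerm("NAUSEA.")              # "nausea"
#' @export
normalizeTerm <- function(x) {
    if (length(x) == 0L) return(character())
    if (any(is.na(x)))
        stop("empty-term error: NA term")
    out <- tolower(x)
    out <- gsub("[[:space:]]+", " ", out)
    out <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", out)
    if (any(!nzchar(out)))
        stop("empty-term error: term empty after normalization")
    out
}

#' Load a MedDRA-like LLT/PT dictionary
#'
#' Reads a tab-separated table with columns \code{term_text},
#' \code{level} (\code{LLT} or \code{PT}), \code{parent_pt} (empty for
#' PTs) and \code{primary_soc} (empty for LLTs). Term text and parent
#' references are normalized on load; the hierarchy must be closed
#' (every LLT's parent is a PT in the table) and, when a vocabulary is
#' supplied, every PT's primary SOC must be one of its 27 codes.
#'
#' The real MedDRA distribution is licensed; this plain dialect carries
#' exactly the three facts the analysis needs: term, level, primary SOC.
#'
#' @param path path to the dictionary table.
#' @param vocab optional \linkS4class{SOCVocabulary} to check primary
#'   SOC codes against.
#' @param version_label free-text version tag stored on the object.
#' @return a \linkS4class{MedDRADictionary}.
#' @export
loadMedDRADictionary <- function(path, vocab = NULL, version_label = basename(path)) {
    stopifnot(file.exists(path))
    t <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           quote = "", comment.char = "",
                           na.strings = c("NA", ""))
    need <- c("term_text", "level", "parent_pt", "primary_soc")
    if (!all(need %in% names(t)))
        stop("dictionary must have columns: ", paste(need, collapse = ", "))
    t$term_text <- normalizeTerm(t$term_text)
    has_parent <- !is.na(t$parent_pt)
    t$parent_pt[has_parent] <- normalizeTerm(t$parent_pt[has_parent])
    if (!is.null(vocab)) {
        soc <- t$primary_soc[t$level == "PT"]
        bad <- setdiff(soc, socCodes(vocab))
        if (length(bad))
            stop("primary_soc not in SOC vocabulary: ",
                 paste(bad, collapse = ", "))
    }
    new("MedDRADictionary", terms = t[, need], version_label = version_label)
}

#' Map reaction terms to their primary SOC
#'
#' A PT resolves directly to its primary SOC; an LLT resolves through
#' its parent PT to that PT's primary SOC. Only the primary SOC is ever
#' returned, even though a PT may be cross-linked to several SOCs in
#' full MedDRA. Terms absent from the dictionary map to \code{NA}, the
#' unmapped marker; callers discard and count those, they are not
#' errors.
#'
#' @param term character vector of raw (or already normalized) terms.
#' @param dict a \linkS4class{MedDRADictionary}.
#' @return character vector of SOC codes, \code{NA} where unmapped.
#' @export
mapTermToSOC <- function(term, dict) {
    if (length(term) == 0L) return(character())
    key <- normalizeTerm(term)
    t <- dict@terms
    i <- match(key, t$term_text)
    soc <- t$primary_soc[i]
    is_llt <- !is.na(i) & t$level[i] == "LLT"
    if (any(is_llt)) {
        pi <- match(t$parent_pt[i[is_llt]], t$term_text)
        soc[is_llt] <- t$primary_soc[pi]
    }
    unname(soc)
}
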