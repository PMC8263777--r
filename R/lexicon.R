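.tokenize <- function(x) {
    strsplit(trimws(gsub("[^a-z0-9]+", " ", tolower(x))), " ", fixed = TRUE)
}

.buildLexicon <- function(entries) {
    entries$synonyms <- lapply(entries$synonyms,
                               function(s) unique(normalizeTerm(s)))
    idx <- data.frame(
        synonym = unlist(entries$synonyms, use.names = FALSE),
        drug_id = rep(entries$drug_id, lengths(entries$synonyms)),
        stringsAsFactors = FALSE)
    idx$tokens <- .tokenize(idx$synonym)
    idx$first <- vapply(idx$tokens, `[`, character(1), 1L)
    new("DrugLexicon", entries = entries, index = idx)
}

#' Build a drug lexicon from in-memory entries
#'
#' @param drug_id character vector of stable identifiers (unique).
#' @param preferred_name canonical names, one per drug.
#' @param synonyms list of character vectors (trade names, active
#'   ingredients, abbreviations); the preferred name is added if absent.
#' @param atc_codes list of character vectors of ATC codes (may be
#'   zero-length for drugs without an ATC assignment).
#' @return a \linkS4class{DrugLexicon}.
#' @export
drugLexicon <- function(drug_id, preferred_name, synonyms,
                        atc_codes = vector("list", length(drug_id))) {
    synonyms <- mapply(function(p, s) unique(c(p, s)), preferred_name,
                       synonyms, SIMPLIFY = FALSE)
    entries <- data.frame(drug_id = drug_id, preferred_name = preferred_name,
                          stringsAsFactors = FALSE)
    entries$synonyms <- synonyms
    entries$atc_codes <- lapply(atc_codes, function(a) toupper(a[nzchar(a)]))
    validObject(lex <- .buildLexicon(entries))
    lex
}

#' Load a drug lexicon table
#'
#' Reads a tab-separated table with columns \code{drug_id},
#' \code{preferred_name}, \code{synonyms} and \code{atc_codes}; the two
#' set-valued fields are packed with \code{"|"} separators and may be
#' empty for \code{atc_codes}. Synonyms are normalized on load, and a
#' synonym claimed by two different drugs aborts the load: silent
#' priority would corrupt every downstream count.
#'
#' @param path path to the lexicon table.
#' @return a \linkS4class{DrugLexicon}.
#' @export
loadDrugLexicon <- function(path) {
    stopifnot(file.exists(path))
    e <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           quote = "", comment.char = "",
                           na.strings = character())
    need <- c("drug_id", "preferred_name", "synonyms", "atc_codes")
    if (!all(need %in% names(e)))
        stop("lexicon must have columns: ", paste(need, collapse = ", "))
    drugLexicon(e$drug_id, e$preferred_name,
                strsplit(e$synonyms, "|", fixed = TRUE),
                strsplit(e$atc_codes, "|", fixed = TRUE))
}

#' @describeIn loadDrugLexicon drug identifiers in lexicon order.
#' @param lexicon a \linkS4class{DrugLexicon}.
#' @export
drugIds <- function(lexicon) lexicon@entries$drug_id

#' @describeIn loadDrugLexicon named list of ATC code sets per drug.
#' @export
atcCodes <- function(lexicon) {
    stats::setNames(lexicon@entries$atc_codes, lexicon@entries$drug_id)
}

#' Match free text against a drug lexicon
#'
#' Finds every drug any of whose synonyms occurs as a contiguous
#' whole-token phrase in the normalized text. Tokens are maximal
#' alphanumeric runs, so \code{"Lopinavir/Ritonavir"} yields two tokens
#' and matches both drugs, while \code{"chloroquine"} never fires inside
#' \code{"hydroxychloroquine"}: matching is token-exact, not substring.
#'
#' @param text a single character string (e.g. an intervention
#'   description or a verbatim FAERS drug name).
#' @param lexicon a \linkS4class{DrugLexicon}.
#' @return character vector of matched \code{drug_id}s (empty when
#'   nothing matches).
#' @examples
#' lex <- drugLexicon("D1", "hydroxychloroquine",
#'                    list(c("hydroxychloroquine sulfate", "plaquenil")))
#' matchDrug("Hydroxychloroquine Sulfate 200 mg", lex)
#' @export
matchDrug <- function(text, lexicon) {
    stopifnot(length(text) == 1L)
    tt <- .tokenize(text)[[1]]
    if (length(tt) == 0L || !nzchar(tt[1L])) return(character())
    idx <- lexicon@index
    cand <- which(idx$first %in% tt)
    if (!length(cand)) return(character())
    hit <- vapply(cand, function(k) {
        s <- idx$tokens[[k]]
        m <- length(s)
        if (m > length(tt)) return(FALSE)
        for (p in which(tt == s[1L])) {
            if (p + m - 1L <= length(tt) &&
                all(tt[p:(p + m - 1L)] == s)) return(TRUE)
        }
        FALSE
    }, logical(1))
    unique(idx$drug_id[cand[hit]])
}

#' Match many free-text strings at once
#'
#' @param texts character vector.
#' @param lexicon a \linkS4class{DrugLexicon}.
#' @return list of character vectors of matched drug ids, one per input.
#' @export
matchDrugs <- function(texts, lexicon) {
    lapply(texts, matchDrug, lexicon = lexicon)
}

#' First-level anatomical class of an ATC code
#'
#' The ATC classification's first level is the anatomical main group,
#' encoded by the code's first letter (14 groups). Full 7-character
#' codes and valid shorter prefixes (1, 3, 4 or 5 characters) are
#' accepted; anything else is a format error.
#'
#' @param atc_code character vector of ATC codes.
#' @return character vector of upper-case single-letter classes.
#' @examples
#' atcClassOf("J01FA10")  # "J"
#' @export
atcClassOf <- function(atc_code) {
    ok <- grepl("^[A-Za-z]([0-9]{2}([A-Za-z]([A-Za-z]([0-9]{2})?)?)?)?$",
                atc_code)
    if (any(!ok))
        stop("format error: malformed ATC code(s): ",
             paste(atc_code[!ok], collapse = ", "))
    toupper(substr(atc_code, 1L, 1L))
}
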