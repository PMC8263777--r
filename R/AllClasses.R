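#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom utils head
NULL

#' SOCVocabulary: the 27 MedDRA system organ classes
#'
#' An ordered table of the 27 system organ classes (SOCs) that form the
#' analysis universe. The row order is fixed at load time and defines the
#' column/row order of every downstream count matrix and Z-score matrix.
#'
#' @slot entries a \code{data.frame} with columns \code{soc_code},
#'   \code{soc_name} and \code{abbreviation}; exactly 27 rows, codes and
#'   abbreviations unique.
#'
#' @seealso [loadSOCVocabulary()], [defaultSOCVocabulary()]
#' @export
setClass("SOCVocabulary", representation(entries = "data.frame"))

setValidity("SOCVocabulary", function(object) {
    e <- object@entries
    msgs <- character()
    need <- c("soc_code", "soc_name", "abbreviation")
    if (!all(need %in% names(e)))
        return(paste("entries must have columns", paste(need, collapse = ", ")))
    if (nrow(e) != 27L)
        msgs <- c(msgs, sprintf("expected 27 SOC entries, got %d", nrow(e)))
    if (anyDuplicated(e$soc_code))
        msgs <- c(msgs, "duplicate soc_code entries")
    if (anyDuplicated(e$abbreviation))
        msgs <- c(msgs, "duplicate abbreviation entries")
    if (length(msgs)) msgs else TRUE
})

#' MedDRADictionary: two-level LLT/PT term hierarchy with primary SOCs
#'
#' A MedDRA-like dictionary restricted to the two levels the reaction
#' files use: lowest level terms (LLT), each pointing at a parent
#' preferred term (PT), and PTs, each carrying a primary SOC assignment.
#' Term text is stored normalized (see [normalizeTerm()]) and unique.
#'
#' @slot terms a \code{data.frame} with columns \code{term_text},
#'   \code{level} (\code{"LLT"} or \code{"PT"}), \code{parent_pt}
#'   (\code{NA} for PTs) and \code{primary_soc} (\code{NA} for LLTs,
#'   which inherit their parent PT's primary SOC).
#' @slot version_label free-text version tag of the dictionary table.
#'
#' @seealso [loadMedDRADictionary()], [mapTermToSOC()]
#' @export
setClass("MedDRADictionary",
    representation(terms = "data.frame", version_label = "character"))

setValidity("MedDRADictionary", function(object) {
    t <- object@terms
    msgs <- character()
    need <- c("term_text", "level", "parent_pt", "primary_soc")
    if (!all(need %in% names(t)))
        return(paste("terms must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(t$term_text))
        msgs <- c(msgs, "term_text keys not unique after normalization")
    if (!all(t$level %in% c("LLT", "PT")))
        msgs <- c(msgs, "level must be LLT or PT")
    pts <- t$term_text[t$level == "PT"]
    llt <- t[t$level == "LLT", , drop = FALSE]
    if (!all(llt$parent_pt %in% pts))
        msgs <- c(msgs, "every LLT parent_pt must resolve to a PT in the dictionary")
    if (any(is.na(t$primary_soc[t$level == "PT"])))
        msgs <- c(msgs, "every PT must carry a primary_soc")
    if (length(msgs)) msgs else TRUE
})

#' DrugLexicon: canonical drugs with synonym sets and ATC codes
#'
#' Each entry names a drug by a stable identifier and carries the set of
#' normalized synonyms (trade names, active-ingredient names,
#' abbreviations -- the preferred name is always among them) used for
#' free-text matching, plus zero or more ATC codes. A synonym mapping to
#' two different drugs is a load-time error: a wrong drug assignment
#' would corrupt every downstream count.
#'
#' @slot entries a \code{data.frame} with columns \code{drug_id},
#'   \code{preferred_name}, \code{synonyms} (list column of normalized
#'   character vectors) and \code{atc_codes} (list column, possibly
#'   zero-length).
#' @slot index a \code{data.frame} synonym index (\code{synonym},
#'   \code{drug_id}) precomputed for matching.
#'
#' @seealso [loadDrugLexicon()], [matchDrug()]
#' @export
setClass("DrugLexicon",
    representation(entries = "data.frame", index = "data.frame"))

setValidity("DrugLexicon", function(object) {
    e <- object@entries
    msgs <- character()
    if (anyDuplicated(e$drug_id))
        msgs <- c(msgs, "drug_id not unique")
    if (any(lengths(e$synonyms) == 0L))
        msgs <- c(msgs, "every drug needs at least one synonym")
    ok <- mapply(function(p, s) normalizeTerm(p) %in% s, e$preferred_name,
                 e$synonyms)
    if (!all(ok))
        msgs <- c(msgs, "preferred_name must be among the synonyms after normalization")
    idx <- object@index
    coll <- tapply(idx$drug_id, idx$synonym, function(d) length(unique(d)))
    if (any(coll > 1L))
        msgs <- c(msgs, paste("synonym collision across drugs:",
            paste(names(coll)[coll > 1L], collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' SOCProfileSet: per-drug adverse-event count profiles over the 27 SOCs
#'
#' A \linkS4class{SummarizedExperiment} whose rows are the 27 SOCs (in
#' vocabulary order) and whose columns are drugs. The \code{"counts"}
#' assay holds the tally of drug-event combinations per (SOC, drug);
#' [computeZscores()] adds a \code{"z"} assay. Column data carry the
#' per-drug total, mean and standard deviation once Z-scores have been
#' computed; \code{metadata()$stratum} records which sex stratum the
#' profiles summarize.
#'
#' @seealso [aggregateProfiles()], [computeZscores()]
#' @export
setClass("SOCProfileSet", contains = "SummarizedExperiment")

setValidity("SOCProfileSet", function(object) {
    msgs <- character()
    if (nrow(object) != 27L)
        msgs <- c(msgs, "a SOCProfileSet has exactly 27 SOC rows")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msgs <- c(msgs, "missing 'counts' assay")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0))
            msgs <- c(msgs, "counts must be non-negative")
    }
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "SOCVocabulary", function(object) {
    cat("SOCVocabulary with", nrow(object@entries), "system organ classes\n")
    cat("  codes:", paste(head(object@entries$soc_code, 6), collapse = ", "),
        "...\n")
})

setMethod("show", "MedDRADictionary", function(object) {
    t <- object@terms
    cat("MedDRADictionary", object@version_label, "\n")
    cat("  ", sum(t$level == "PT"), "PTs,", sum(t$level == "LLT"), "LLTs,",
        length(unique(t$primary_soc[t$level == "PT"])), "primary SOCs\n")
})

setMethod("show", "DrugLexicon", function(object) {
    e <- object@entries
    cat("DrugLexicon with", nrow(e), "drugs,",
        sum(lengths(e$synonyms)), "synonyms,",
        sum(lengths(e$atc_codes) > 0L), "drugs with ATC codes\n")
})
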