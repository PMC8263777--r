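#' Read a clinical-trials registry CSV export
#'
#' Expects a header row and (configurably named) columns for the trial
#' identifier, recruitment status and the packed interventions field.
#' The interventions cell follows the registry export convention:
#' entries separated by \code{"|"}, each of the form
#' \code{"Type: description"}; entries without a recognizable type
#' prefix are kept with type \code{NA} and never count as drug
#' interventions.
#'
#' @param path path to the CSV file.
#' @param id_col,status_col,interventions_col column names in the file.
#' @return a \code{data.frame} with columns \code{trial_id},
#'   \code{status} and a list column \code{interventions}, each element
#'   a \code{data.frame} with \code{type} and \code{description}.
#' @export
readTrials <- function(path, id_col = "trial_id", status_col = "status",
                       interventions_col = "interventions") {
    stopifnot(file.exists(path))
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = character())
    need <- c(id_col, status_col, interventions_col)
    if (!all(need %in% names(raw)))
        stop("trials file must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(raw[[id_col]]))
        stop("duplicate trial_id in trials file")
    out <- data.frame(trial_id = as.character(raw[[id_col]]),
                      status = raw[[status_col]],
                      stringsAsFactors = FALSE)
    out$interventions <- lapply(raw[[interventions_col]], .parseInterventions)
    out
}

.parseInterventions <- function(cell) {
    if (is.na(cell) || !nzchar(cell))
        return(data.frame(type = character(), description = character(),
                          stringsAsFactors = FALSE))
    parts <- strsplit(cell, "|", fixed = TRUE)[[1]]
    m <- regexpr("^\\s*([A-Za-z ]+?)\\s*:\\s*", parts)
    type <- ifelse(m > 0, trimws(sub(":.*$", "", parts)), NA_character_)
    desc <- ifelse(m > 0, substring(parts, attr(m, "match.length") + 1L),
                   parts)
    data.frame(type = type, description = trimws(desc),
               stringsAsFactors = FALSE)
}

#' Filter trials by recruitment status and intervention type
#'
#' Drops trials whose status is withdrawn, suspended or terminated
#' (case-insensitive; composite statuses such as
#' \code{"Terminated (halted)"} are excluded when they start with one of
#' the three words -- any other status passes through), then keeps only
#' trials with at least one intervention of type \code{"Drug"}.
#' Idempotent.
#'
#' @param trials a trials \code{data.frame} from [readTrials()].
#' @return the filtered \code{data.frame}.
#' @export
filterTrials <- function(trials) {
    st <- tolower(trimws(trials$status))
    excluded <- grepl("^(withdrawn|suspended|terminated)\\b", st)
    has_drug <- vapply(trials$interventions, function(iv) {
        any(!is.na(iv$type) & tolower(iv$type) == "drug")
    }, logical(1))
    trials[!excluded & has_drug, , drop = FALSE]
}

#' Resolve trial drug interventions to lexicon drugs
#'
#' Matches every \code{Drug}-type intervention description against the
#' lexicon with [matchDrug()]. A trial credits each matched drug once,
#' however many of its interventions mention it; trials matching no
#' lexicon drug are dropped from the assignments but tallied in the
#' \code{n_unmatched_trials} attribute (they typically name agents
#' outside the lexicon, e.g. traditional medicines or biologics).
#'
#' @param trials a filtered trials \code{data.frame}.
#' @param lexicon a \linkS4class{DrugLexicon}.
#' @return a \code{data.frame} with \code{drug_id}, \code{n_trials} and
#'   a list column \code{trial_ids}, sorted by \code{drug_id}; attribute
#'   \code{n_unmatched_trials} counts trials with zero matches.
#' @export
assignDrugs <- function(trials, lexicon) {
    per_trial <- lapply(seq_len(nrow(trials)), function(i) {
        iv <- trials$interventions[[i]]
        desc <- iv$description[!is.na(iv$type) & tolower(iv$type) == "drug"]
        unique(unlist(lapply(desc, matchDrug, lexicon = lexicon)))
    })
    n_unmatched <- sum(lengths(per_trial) == 0L)
    pairs <- data.frame(
        drug_id = unlist(per_trial),
        trial_id = rep(trials$trial_id, lengths(per_trial)),
        stringsAsFactors = FALSE)
    if (nrow(pairs) == 0L) {
        out <- data.frame(drug_id = character(), n_trials = integer(),
                          stringsAsFactors = FALSE)
        out$trial_ids <- list()
    } else {
        sp <- split(pairs$trial_id, pairs$drug_id)
        sp <- sp[order(names(sp))]
        out <- data.frame(drug_id = names(sp),
                          n_trials = lengths(sp),
                          stringsAsFactors = FALSE, row.names = NULL)
        out$trial_ids <- unname(sp)
    }
    attr(out, "n_unmatched_trials") <- n_unmatched
    out
}

#' Histogram of drugs by number of trials
#'
#' Bins drugs by how many trials test them: exactly one, two, three, or
#' more than three. The bins partition all drugs with at least one
#' assigned trial.
#'
#' @param assignments output of [assignDrugs()].
#' @return named integer vector \code{c("1", "2", "3", ">3")}.
#' @export
trialCountHistogram <- function(assignments) {
    n <- assignments$n_trials
    c("1" = sum(n == 1L), "2" = sum(n == 2L), "3" = sum(n == 3L),
      ">3" = sum(n > 3L))
}
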