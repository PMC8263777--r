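.readFaersTable <- function(path, need, sep) {
    stopifnot(file.exists(path))
    t <- utils::read.delim(path, sep = sep, quote = "", comment.char = "",
                           stringsAsFactors = FALSE, colClasses = "character",
                           na.strings = character())
    if (!all(need %in% names(t)))
        stop("format error: ", basename(path), " must have columns: ",
             paste(need, collapse = ", "))
    t
}

#' Read FAERS-dialect report files into case reports
#'
#' FAERS quarterly releases split each case across demographic, drug and
#' reaction tables joined on (case id, case version). This reader joins
#' the three files on that key; a key missing from one file yields an
#' incomplete report (absent sex, no drug mentions, or no reactions),
#' never an error. Rows with an unparseable case version or a role code
#' outside \{PS, SS, C, I\} are skipped and counted.
#'
#' @param demo_path file with columns \code{caseid}, \code{caseversion},
#'   \code{sex}.
#' @param drug_path file with columns \code{caseid}, \code{caseversion},
#'   \code{role_cod}, \code{drugname}.
#' @param reac_path file with columns \code{caseid}, \code{caseversion},
#'   \code{pt}.
#' @param sep field delimiter; FAERS ASCII uses \code{"$"}, plain-TSV
#'   fixtures can pass \code{"\t"}.
#' @return a \code{data.frame} with one row per (case id, version):
#'   columns \code{case_id}, \code{case_version}, \code{sex_code} and
#'   list columns \code{drug_names}, \code{drug_roles},
#'   \code{reactions}; attribute \code{n_malformed_rows} counts skipped
#'   input rows.
#' @export
readReports <- function(demo_path, drug_path, reac_path, sep = "$") {
    demo <- .readFaersTable(demo_path, c("caseid", "caseversion", "sex"), sep)
    drug <- .readFaersTable(drug_path,
                            c("caseid", "caseversion", "role_cod", "drugname"),
                            sep)
    reac <- .readFaersTable(reac_path, c("caseid", "caseversion", "pt"), sep)

    n_malformed <- 0L
    fixver <- function(t) {
        v <- suppressWarnings(as.integer(t$caseversion))
        bad <- is.na(v)
        n_malformed <<- n_malformed + sum(bad)
        t$caseversion <- v
        t[!bad, , drop = FALSE]
    }
    demo <- fixver(demo); drug <- fixver(drug); reac <- fixver(reac)
    badrole <- !(drug$role_cod %in% c("PS", "SS", "C", "I"))
    n_malformed <- n_malformed + sum(badrole)
    drug <- drug[!badrole, , drop = FALSE]

    key <- function(t) paste(t$caseid, t$caseversion, sep = "\x1f")
    keys <- unique(c(key(demo), key(drug), key(reac)))
    kd <- key(demo); kg <- key(drug); kr <- key(reac)

    parts <- strsplit(keys, "\x1f", fixed = TRUE)
    out <- data.frame(
        case_id = vapply(parts, `[`, character(1), 1L),
        case_version = as.integer(vapply(parts, `[`, character(1), 2L)),
        stringsAsFactors = FALSE)
    out$sex_code <- demo$sex[match(keys, kd)]
    gi <- split(seq_len(nrow(drug)), factor(kg, levels = keys))
    out$drug_names <- lapply(gi, function(i) drug$drugname[i])
    out$drug_roles <- lapply(gi, function(i) drug$role_cod[i])
    ri <- split(seq_len(nrow(reac)), factor(kr, levels = keys))
    out$reactions <- lapply(ri, function(i) reac$pt[i])
    rownames(out) <- NULL
    attr(out, "n_malformed_rows") <- n_malformed
    out
}

.isComplete <- function(reports) {
    nzchar(reports$case_id) &
        vapply(reports$drug_names, function(d) any(nzchar(d)), logical(1)) &
        vapply(reports$reactions, function(r) any(nzchar(r)), logical(1))
}

#' Drop incomplete case reports
#'
#' A report is complete when its case id, at least one drug name and at
#' least one reaction term could all be located; everything else is
#' removed, as spontaneous-reporting archives contain many partially
#' filled submissions.
#'
#' @param reports a reports \code{data.frame} from [readReports()].
#' @return \code{list(kept = data.frame, n_dropped = integer)}.
#' @export
dropIncomplete <- function(reports) {
    ok <- .isComplete(reports)
    list(kept = reports[ok, , drop = FALSE], n_dropped = sum(!ok))
}

.dedupKey <- function(reports) {
    dn <- vapply(reports$drug_names, function(d)
        paste(sort(unique(normalizeTerm(d[nzchar(d)]))), collapse = "\x1f"),
        character(1))
    rx <- vapply(reports$reactions, function(r)
        paste(sort(unique(normalizeTerm(r[nzchar(r)]))), collapse = "\x1f"),
        character(1))
    paste(reports$case_id, dn, rx, sep = "\x1e")
}

#' Deduplicate successive versions of the same case report
#'
#' Reports are grouped by case id together with the (order-insensitive)
#' sets of normalized drug names and reaction terms; within each group
#' only the highest case version survives. The same case id with a
#' different reaction set is a different group and is kept. A tied
#' highest version keeps the report appearing last in input order, with
#' a warning. Idempotent.
#'
#' @param reports complete reports from [dropIncomplete()].
#' @return \code{list(kept = data.frame, n_removed = integer)}.
#' @export
deduplicateReports <- function(reports) {
    if (nrow(reports) == 0L)
        return(list(kept = reports, n_removed = 0L))
    grp <- .dedupKey(reports)
    keep <- vapply(split(seq_len(nrow(reports)), grp), function(i) {
        top <- i[reports$case_version[i] == max(reports$case_version[i])]
        if (length(top) > 1L)
            warning("tied case_version within duplicate group; keeping the ",
                    "last in input order", call. = FALSE)
        top[length(top)]
    }, integer(1))
    keep <- sort(unname(keep))
    list(kept = reports[keep, , drop = FALSE],
         n_removed = nrow(reports) - length(keep))
}

#' Expand cleaned reports into drug-event records
#'
#' The counting unit is the drug-event combination: one record per
#' (suspect drug, mapped reaction) pair per retained report. Only
#' mentions with role PS (primary suspect) or SS (secondary suspect)
#' contribute; a drug mentioned as both PS and SS in one report counts
#' once per reaction. Duplicate identical reaction terms within a
#' report collapse to one before counting. Reactions that do not map to
#' a SOC and suspect names that match no lexicon drug are dropped and
#' tallied in the \code{counters} attribute. Sex strata: records are
#' \code{"female"} or \code{"male"} when the report carries the
#' corresponding code, otherwise \code{"unspecified"} -- excluded from
#' the sex tables but always present in the overall stream.
#'
#' @param reports deduplicated complete reports.
#' @param lexicon a \linkS4class{DrugLexicon}.
#' @param dict a \linkS4class{MedDRADictionary}.
#' @param vocab a \linkS4class{SOCVocabulary} (SOC codes are checked
#'   against it).
#' @param female_code,male_code sex codes defining the two strata.
#' @return a \code{data.frame} with columns \code{drug_id},
#'   \code{soc_code}, \code{sex_stratum}, \code{case_id}; attribute
#'   \code{counters} is a named integer vector with
#'   \code{unmatched_drug_mentions}, \code{unmapped_reaction_mentions}
#'   and \code{collapsed_duplicate_reactions}.
#' @export
explodeSuspectEvents <- function(reports, lexicon, dict, vocab,
                                 female_code = "F", male_code = "M") {
    empty <- data.frame(drug_id = character(), soc_code = character(),
                        sex_stratum = character(), case_id = character(),
                        stringsAsFactors = FALSE)
    counters <- c(unmatched_drug_mentions = 0L,
                  unmapped_reaction_mentions = 0L,
                  collapsed_duplicate_reactions = 0L)
    if (nrow(reports) == 0L) {
        attr(empty, "counters") <- counters
        return(empty)
    }
    suspect <- lapply(seq_len(nrow(reports)), function(i) {
        d <- reports$drug_names[[i]]
        r <- reports$drug_roles[[i]]
        unique(d[r %in% c("PS", "SS") & nzchar(d)])
    })
    # match/map each distinct verbatim string once, then look results up
    all_names <- unique(unlist(suspect))
    match_tab <- matchDrugs(all_names, lexicon)
    names(match_tab) <- all_names
    reacts <- lapply(reports$reactions, function(r) {
        r <- normalizeTerm(r[nzchar(r)])
        unique(r)
    })
    counters["collapsed_duplicate_reactions"] <-
        sum(lengths(lapply(reports$reactions, function(r) r[nzchar(r)]))) -
        sum(lengths(reacts))
    all_terms <- unique(unlist(reacts))
    soc_tab <- stats::setNames(mapTermToSOC(all_terms, dict), all_terms)
    bad_soc <- setdiff(stats::na.omit(unique(soc_tab)), socCodes(vocab))
    if (length(bad_soc))
        stop("dictionary maps to SOC codes outside the vocabulary: ",
             paste(bad_soc, collapse = ", "))

    strat <- ifelse(is.na(reports$sex_code), "unspecified",
             ifelse(reports$sex_code == female_code, "female",
             ifelse(reports$sex_code == male_code, "male", "unspecified")))

    pieces <- lapply(seq_len(nrow(reports)), function(i) {
        hits <- match_tab[suspect[[i]]]
        counters["unmatched_drug_mentions"] <<-
            counters["unmatched_drug_mentions"] + sum(lengths(hits) == 0L)
        ids <- unique(unlist(hits))
        socs <- soc_tab[reacts[[i]]]
        counters["unmapped_reaction_mentions"] <<-
            counters["unmapped_reaction_mentions"] + sum(is.na(socs))
        socs <- socs[!is.na(socs)]
        if (!length(ids) || !length(socs)) return(NULL)
        data.frame(drug_id = rep(ids, each = length(socs)),
                   soc_code = rep(unname(socs), times = length(ids)),
                   sex_stratum = strat[i],
                   case_id = reports$case_id[i],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(pieces, list(empty)))
    rownames(out) <- NULL
    attr(out, "counters") <- counters
    out
}
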