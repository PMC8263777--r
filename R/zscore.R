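#' Aggregate drug-event records into 27-SOC count profiles
#'
#' Tallies drug-event combinations per (drug, SOC) into a
#' \linkS4class{SOCProfileSet}: rows are the 27 SOCs in vocabulary
#' order, columns are the drugs with at least one record in the selected
#' stratum. \code{stratum = "overall"} keeps every record, including
#' those with unspecified sex; \code{"female"}/\code{"male"} keep only
#' the matching stratum.
#'
#' @param records a drug-event \code{data.frame} from
#'   [explodeSuspectEvents()].
#' @param vocab a \linkS4class{SOCVocabulary}.
#' @param stratum \code{"overall"}, \code{"female"} or \code{"male"}.
#' @return a \linkS4class{SOCProfileSet} with a \code{"counts"} assay.
#' @export
aggregateProfiles <- function(records, vocab,
                              stratum = c("overall", "female", "male")) {
    stratum <- match.arg(stratum)
    if (stratum != "overall")
        records <- records[records$sex_stratum == stratum, , drop = FALSE]
    bad <- setdiff(unique(records$soc_code), socCodes(vocab))
    if (length(bad))
        stop("records carry SOC codes outside the vocabulary: ",
             paste(bad, collapse = ", "))
    drugs <- sort(unique(records$drug_id))
    counts <- table(factor(records$soc_code, levels = socCodes(vocab)),
                    factor(records$drug_id, levels = drugs))
    counts <- matrix(as.integer(counts), nrow = 27L,
                     dimnames = list(socCodes(vocab), drugs))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(vocab@entries, row.names = socCodes(vocab)),
        colData = S4Vectors::DataFrame(drug_id = drugs, row.names = drugs))
    obj <- methods::new("SOCProfileSet", se)
    S4Vectors::metadata(obj)$stratum <- stratum
    obj
}

#' Z-scores of SOC adverse-event counts for a drug
#'
#' Standardizes a drug's 27 SOC counts against the drug's own
#' distribution: \eqn{Z_i = (N_i - \mu)/\sigma} where \eqn{\mu} is the
#' total count divided by 27 and \eqn{\sigma} is the standard deviation
#' of the 27 counts. A high Z flags a SOC whose adverse events are
#' reported disproportionately often relative to the drug's other SOCs.
#' With the default population divisor (27), every defined Z vector has
#' mean 0 and sum of squares 27, so \eqn{|Z| \le \sqrt{26}} and at most
#' 6 SOCs can exceed 2. When all 27 counts are equal (\eqn{\sigma = 0})
#' all Z are undefined and returned as \code{NA}.
#'
#' @param x a numeric vector of 27 counts, or a
#'   \linkS4class{SOCProfileSet}.
#' @param divisor \code{"population"} (divide the squared deviations by
#'   27, the default) or \code{"sample"} (26).
#' @param ... passed between methods.
#' @return for a numeric vector: the 27 Z values (names preserved). For
#'   a \linkS4class{SOCProfileSet}: the object with a \code{"z"} assay
#'   and per-drug \code{total}, \code{mu}, \code{sigma} in its column
#'   data.
#' @examples
#' z <- computeZscores(c(100, rep(0, 26)))
#' z[1]  # sqrt(26) = 5.09902...
#' @export
setGeneric("computeZscores", function(x, ...) standardGeneric("computeZscores"))

.zvec <- function(counts, divisor = c("population", "sample")) {
    divisor <- match.arg(divisor)
    if (length(counts) != 27L)
        stop("a profile has exactly 27 SOC counts")
    total <- sum(counts)
    if (total == 0)
        stop("empty-profile error: profile total is zero")
    mu <- total / 27
    denom <- if (divisor == "population") 27 else 26
    sigma <- sqrt(sum((counts - mu)^2) / denom)
    if (sigma == 0) return(rep(NA_real_, 27L))
    (counts - mu) / sigma
}

#' @rdname computeZscores
#' @export
setMethod("computeZscores", "numeric", function(x, divisor = "population", ...) {
    z <- .zvec(x, divisor)
    names(z) <- names(x)
    z
})

#' @rdname computeZscores
#' @export
setMethod("computeZscores", "SOCProfileSet", function(x, divisor = "population", ...) {
    cnt <- SummarizedExperiment::assay(x, "counts")
    z <- apply(cnt, 2L, .zvec, divisor = divisor)
    dimnames(z) <- dimnames(cnt)
    SummarizedExperiment::assay(x, "z") <- z
    total <- colSums(cnt)
    denom <- if (match.arg(divisor, c("population", "sample")) == "population")
        27 else 26
    SummarizedExperiment::colData(x)$total <- total
    SummarizedExperiment::colData(x)$mu <- total / 27
    SummarizedExperiment::colData(x)$sigma <-
        sqrt(colSums(sweep(cnt, 2L, total / 27)^2) / denom)
    x
})

.bandLevels <- c("significantly_frequent", "frequent", "slightly_frequent",
                 "likely_infrequent", "infrequent", "undefined")

#' Five-band safety categorization of Z-scores
#'
#' Maps Z to the five bands used for colour-coding safety tables:
#' significantly frequent (\eqn{Z > 2}), frequent (\eqn{1 < Z \le 2}),
#' slightly frequent (\eqn{0 < Z \le 1}), likely infrequent
#' (\eqn{-1 < Z \le 0}) and infrequent (\eqn{Z \le -1}). The
#' significance rule "\eqn{Z > 2}" is strict, so \eqn{Z = 2} falls in
#' the frequent band. Undefined Z (\code{NA}) passes through as
#' \code{"undefined"}.
#'
#' @param z numeric vector (or matrix) of Z-scores.
#' @return character vector (or matrix) of band labels.
#' @examples
#' zBand(c(3.7, 2.0, -0.03))
#' @export
zBand <- function(z) {
    out <- ifelse(is.na(z), "undefined",
           ifelse(z > 2, "significantly_frequent",
           ifelse(z > 1, "frequent",
           ifelse(z > 0, "slightly_frequent",
           ifelse(z > -1, "likely_infrequent", "infrequent")))))
    if (is.matrix(z)) dim(out) <- dim(z)
    dimnames(out) <- dimnames(z)
    out
}

#' SOCs with significantly frequent adverse events for a drug
#'
#' A SOC is called significant for a drug when its Z-score is strictly
#' greater than 2. Under the population divisor at most 6 of the 27
#' SOCs can qualify (since the squared Z-scores sum to 27).
#'
#' @param z a named numeric vector of 27 Z-scores.
#' @return character vector of SOC codes with \eqn{Z > 2}.
#' @export
significantSOCs <- function(z) {
    names(z)[!is.na(z) & z > 2]
}

#' Summaries of adverse events by first-level ATC class
#'
#' Groups drugs by the first letter of their ATC codes (the 14
#' anatomical main groups). A drug with codes in several classes
#' contributes its full totals to each distinct class; duplicate letters
#' within one drug collapse to a single membership. Drugs without any
#' ATC code are excluded.
#'
#' @param profiles a \linkS4class{SOCProfileSet} with Z-scores computed
#'   (see [computeZscores()]).
#' @param lexicon a \linkS4class{DrugLexicon} carrying ATC codes.
#' @return a \code{data.frame} with one row per class present:
#'   \code{atc_class}, \code{n_drugs}, \code{total_events},
#'   \code{mean_events_per_drug}, \code{total_significant_socs},
#'   \code{mean_significant_socs}.
#' @export
atcClassSummary <- function(profiles, lexicon) {
    if (ncol(profiles) == 0L)
        return(data.frame(atc_class = character(), n_drugs = integer(),
                          total_events = numeric(),
                          mean_events_per_drug = numeric(),
                          total_significant_socs = numeric(),
                          mean_significant_socs = numeric()))
    if (!"z" %in% SummarizedExperiment::assayNames(profiles))
        profiles <- computeZscores(profiles)
    cnt <- SummarizedExperiment::assay(profiles, "counts")
    z <- SummarizedExperiment::assay(profiles, "z")
    totals <- colSums(cnt)
    nsig <- colSums(!is.na(z) & z > 2)
    atc <- atcCodes(lexicon)
    classes <- lapply(colnames(cnt), function(d) {
        codes <- atc[[d]]
        if (is.null(codes) || length(codes) == 0L) character() else
            unique(atcClassOf(codes))
    })
    pairs <- data.frame(
        atc_class = unlist(classes),
        drug = rep(colnames(cnt), lengths(classes)),
        stringsAsFactors = FALSE)
    if (nrow(pairs) == 0L)
        return(data.frame(atc_class = character(), n_drugs = integer(),
                          total_events = numeric(),
                          mean_events_per_drug = numeric(),
                          total_significant_socs = numeric(),
                          mean_significant_socs = numeric()))
    sp <- split(pairs$drug, pairs$atc_class)
    out <- data.frame(
        atc_class = names(sp),
        n_drugs = lengths(sp),
        total_events = vapply(sp, function(d) sum(totals[d]), numeric(1)),
        total_significant_socs = vapply(sp, function(d) sum(nsig[d]),
                                        numeric(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    out$mean_events_per_drug <- out$total_events / out$n_drugs
    out$mean_significant_socs <- out$total_significant_socs / out$n_drugs
    out[, c("atc_class", "n_drugs", "total_events", "mean_events_per_drug",
            "total_significant_socs", "mean_significant_socs")]
}
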