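#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: input file locations, the
#' FAERS field delimiter, the standard-deviation divisor for the
#' Z-score, whether sex-stratified tables are produced, and the output
#' directory. All stages stream through files in the output directory,
#' so each stage is independently inspectable.
#'
#' @param trials,demo,drug,reac,dictionary,lexicon,vocabulary input
#'   file paths (see the module readers for the expected columns).
#' @param out_dir output directory.
#' @param faers_sep FAERS field delimiter (\code{"$"} for the quarterly
#'   ASCII convention; fixtures may use \code{"\t"}).
#' @param sd_divisor \code{"population"} or \code{"sample"}.
#' @param stratify produce female/male tables as well as overall.
#' @param female_code,male_code sex codes defining the strata.
#' @return a classed list (\code{PipelineConfig}).
#' @export
pipelineConfig <- function(trials, demo, drug, reac, dictionary, lexicon,
                           vocabulary = NULL, out_dir = ".",
                           faers_sep = "$", sd_divisor = "population",
                           stratify = TRUE, female_code = "F",
                           male_code = "M") {
    sd_divisor <- match.arg(sd_divisor, c("population", "sample"))
    cfg <- list(trials = trials, demo = demo, drug = drug, reac = reac,
                dictionary = dictionary, lexicon = lexicon,
                vocabulary = vocabulary, out_dir = out_dir,
                faers_sep = faers_sep, sd_divisor = sd_divisor,
                stratify = isTRUE(stratify), female_code = female_code,
                male_code = male_code)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file carries the same fields as [pipelineConfig()]; input
#' paths are resolved relative to the file's directory.
#'
#' @param path path to the YAML file.
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    rel <- function(p) if (is.null(p) || grepl("^/", p)) p else
        file.path(base, p)
    pipelineConfig(
        trials = rel(y$trials), demo = rel(y$demo), drug = rel(y$drug),
        reac = rel(y$reac), dictionary = rel(y$dictionary),
        lexicon = rel(y$lexicon), vocabulary = rel(y$vocabulary),
        out_dir = rel(y$out_dir %||% "."),
        faers_sep = y$faers_sep %||% "$",
        sd_divisor = y$sd_divisor %||% "population",
        stratify = y$stratify %||% TRUE,
        female_code = y$female_code %||% "F",
        male_code = y$male_code %||% "M")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.loadVocabularies <- function(config) {
    vocab <- if (is.null(config$vocabulary)) defaultSOCVocabulary() else
        loadSOCVocabulary(config$vocabulary)
    if (is.null(config$dictionary) || !file.exists(config$dictionary))
        stop("vocabulary error: dictionary file missing")
    if (is.null(config$lexicon) || !file.exists(config$lexicon))
        stop("vocabulary error: lexicon file missing")
    list(vocab = vocab,
         dict = loadMedDRADictionary(config$dictionary, vocab),
         lexicon = loadDrugLexicon(config$lexicon))
}

#' Run the trial-identification stage
#'
#' Reads the trials CSV, applies the status and intervention-type
#' filters, resolves interventions to lexicon drugs and writes
#' \code{trial_assignments.csv} and \code{trial_histogram.csv} to the
#' output directory.
#'
#' @param config a \code{PipelineConfig}.
#' @return invisibly, \code{list(assignments, histogram, funnel)} where
#'   \code{funnel} counts trials surviving each filter.
#' @export
runTrialsStage <- function(config) {
    v <- .loadVocabularies(config)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    trials <- readTrials(config$trials)
    kept <- filterTrials(trials)
    asg <- assignDrugs(kept, v$lexicon)
    hist <- trialCountHistogram(asg)
    funnel <- c(trials_read = nrow(trials),
                trials_after_filters = nrow(kept),
                trials_unmatched = attr(asg, "n_unmatched_trials"),
                drugs_assigned = nrow(asg))
    out <- data.frame(drug_id = asg$drug_id, n_trials = asg$n_trials,
                      trial_ids = vapply(asg$trial_ids, paste, character(1),
                                         collapse = "|"))
    utils::write.csv(out, file.path(config$out_dir, "trial_assignments.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(n_trials = names(hist),
                                n_drugs = as.integer(hist)),
                     file.path(config$out_dir, "trial_histogram.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(list(assignments = asg, histogram = hist, funnel = funnel))
}

.writeCleanReports <- function(reports, config) {
    n <- nrow(reports)
    demo <- data.frame(caseid = reports$case_id,
                       caseversion = reports$case_version,
                       sex = ifelse(is.na(reports$sex_code), "",
                                    reports$sex_code))
    drug <- data.frame(
        caseid = rep(reports$case_id, lengths(reports$drug_names)),
        caseversion = rep(reports$case_version, lengths(reports$drug_names)),
        role_cod = unlist(reports$drug_roles, use.names = FALSE),
        drugname = unlist(reports$drug_names, use.names = FALSE))
    reac <- data.frame(
        caseid = rep(reports$case_id, lengths(reports$reactions)),
        caseversion = rep(reports$case_version, lengths(reports$reactions)),
        pt = unlist(reports$reactions, use.names = FALSE))
    .writeFaers(demo, file.path(config$out_dir, "clean_demo.txt"))
    .writeFaers(drug, file.path(config$out_dir, "clean_drug.txt"))
    .writeFaers(reac, file.path(config$out_dir, "clean_reac.txt"))
}

#' Run the report-cleaning stage
#'
#' Reads the three FAERS-dialect files, drops incomplete reports,
#' deduplicates by (case id, drug-name set, reaction set) keeping the
#' latest version, and writes the surviving reports back out as
#' \code{clean_demo.txt} / \code{clean_drug.txt} / \code{clean_reac.txt}
#' plus a \code{cleaning_report.csv} of stage counters.
#'
#' @param config a \code{PipelineConfig}.
#' @return invisibly, \code{list(reports, counters)}.
#' @export
runCleanStage <- function(config) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    reports <- readReports(config$demo, config$drug, config$reac,
                           sep = config$faers_sep)
    inc <- dropIncomplete(reports)
    dd <- deduplicateReports(inc$kept)
    counters <- c(reports_read = nrow(reports),
                  malformed_rows_skipped = attr(reports, "n_malformed_rows"),
                  incomplete_dropped = inc$n_dropped,
                  duplicates_removed = dd$n_removed,
                  reports_retained = nrow(dd$kept))
    .writeCleanReports(dd$kept, config)
    utils::write.csv(data.frame(counter = names(counters),
                                value = as.integer(counters)),
                     file.path(config$out_dir, "cleaning_report.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(list(reports = dd$kept, counters = counters))
}

#' Run the mapping stage
#'
#' Reads the cleaned report files, expands suspect drug mentions and
#' mapped reactions into drug-event records, and writes
#' \code{drug_event_records.csv} and \code{mapping_report.csv}.
#'
#' @param config a \code{PipelineConfig}.
#' @return invisibly, \code{list(records, counters)}.
#' @export
runMapStage <- function(config) {
    v <- .loadVocabularies(config)
    reports <- readReports(file.path(config$out_dir, "clean_demo.txt"),
                           file.path(config$out_dir, "clean_drug.txt"),
                           file.path(config$out_dir, "clean_reac.txt"),
                           sep = "$")
    records <- explodeSuspectEvents(reports, v$lexicon, v$dict, v$vocab,
                                    female_code = config$female_code,
                                    male_code = config$male_code)
    counters <- attr(records, "counters")
    utils::write.csv(records,
                     file.path(config$out_dir, "drug_event_records.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(counter = names(counters),
                                value = as.integer(counters)),
                     file.path(config$out_dir, "mapping_report.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(list(records = records, counters = counters))
}

.writeMatrix <- function(m, vocab, path) {
    # drugs as rows, SOC abbreviations as columns
    out <- as.data.frame(t(m))
    colnames(out) <- socAbbreviations(vocab)
    out <- cbind(drug_id = rownames(out), out)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

.zTables <- function(records, vocab, stratum, config) {
    prof <- aggregateProfiles(records, vocab, stratum)
    if (ncol(prof) == 0L) return(list(profiles = prof, long = NULL))
    prof <- computeZscores(prof, divisor = config$sd_divisor)
    z <- SummarizedExperiment::assay(prof, "z")
    cnt <- SummarizedExperiment::assay(prof, "counts")
    tag <- stratum
    .writeMatrix(round(z, 6), vocab,
                 file.path(config$out_dir, sprintf("z_%s.csv", tag)))
    .writeMatrix(zBand(z), vocab,
                 file.path(config$out_dir, sprintf("bands_%s.csv", tag)))
    .writeMatrix(cnt, vocab,
                 file.path(config$out_dir, sprintf("counts_%s.csv", tag)))
    long <- data.frame(drug_id = rep(colnames(z), each = nrow(z)),
                       soc_code = rep(rownames(z), times = ncol(z)),
                       count = as.vector(cnt), z = as.vector(z),
                       band = as.vector(zBand(z)), stratum = stratum,
                       stringsAsFactors = FALSE)
    list(profiles = prof, long = long)
}

#' Run the Z-score stage
#'
#' Reads \code{drug_event_records.csv}, aggregates 27-SOC profiles
#' (overall and, when stratification is on, female and male), computes
#' Z-scores and bands, and writes the count/z/band matrices, the
#' long-format table and the ATC class summary.
#'
#' @param config a \code{PipelineConfig}.
#' @return invisibly, a list of \linkS4class{SOCProfileSet}s by stratum
#'   plus the long table and the ATC summary.
#' @export
runZscoreStage <- function(config) {
    v <- .loadVocabularies(config)
    path <- file.path(config$out_dir, "drug_event_records.csv")
    records <- utils::read.csv(path, stringsAsFactors = FALSE,
                               colClasses = "character")
    strata <- c("overall", if (config$stratify) c("female", "male"))
    res <- lapply(stats::setNames(strata, strata), .zTables,
                  records = records, vocab = v$vocab, config = config)
    if (ncol(res$overall$profiles) == 0L)
        warning("empty-result: no drug-event records survived the filters",
                call. = FALSE)
    long <- do.call(rbind, lapply(res, `[[`, "long"))
    if (!is.null(long)) {
        rownames(long) <- NULL
        utils::write.csv(long, file.path(config$out_dir, "long_table.csv"),
                         row.names = FALSE, quote = FALSE)
    }
    atc <- atcClassSummary(res$overall$profiles, v$lexicon)
    utils::write.csv(atc, file.path(config$out_dir, "atc_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(list(profiles = lapply(res, `[[`, "profiles"), long = long,
                   atc_summary = atc))
}

#' Generate a synthetic corpus (pipeline entry point)
#'
#' Validates the simulation section of the configuration and writes the
#' corpus plus its ground-truth manifest.
#'
#' @param sim_config a \code{SimulationConfig} (see
#'   [simulationConfig()]).
#' @param out_dir output directory.
#' @return invisibly, the [simulateCorpus()] result.
#' @export
cmdSynth <- function(sim_config, out_dir) {
    simulateCorpus(sim_config, out_dir)
}

#' Run the full pipeline end to end
#'
#' Executes the trials, cleaning, mapping and Z-score stages in order
#' and writes \code{run_summary.json}: a machine-readable record of
#' every filter's in/out counts, so the funnel from raw inputs to
#' analyzed drug-event records is reproducible on any input. Re-running
#' on identical inputs yields identical outputs.
#'
#' @param config a \code{PipelineConfig}.
#' @return invisibly, \code{list(trials, clean, map, zscore, summary)}.
#' @export
cmdRun <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    tr <- runTrialsStage(config)
    cl <- runCleanStage(config)
    mp <- runMapStage(config)
    zs <- runZscoreStage(config)
    rec <- mp$records
    summary <- list(
        trials = as.list(tr$funnel),
        trial_histogram = as.list(tr$histogram),
        cleaning = as.list(cl$counters),
        mapping = as.list(mp$counters),
        records = list(
            overall = nrow(rec),
            female = sum(rec$sex_stratum == "female"),
            male = sum(rec$sex_stratum == "male"),
            unspecified = sum(rec$sex_stratum == "unspecified")),
        drugs_with_records = length(unique(rec$drug_id)),
        sd_divisor = config$sd_divisor)
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(trials = tr, clean = cl, map = mp, zscore = zs,
                   summary = summary))
}
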