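#' Configuration for the synthetic spontaneous-report corpus
#'
#' Encodes the statistical structure the downstream analysis assumes:
#' each drug's adverse events are allocated over the 27 SOCs by a
#' categorical draw per reaction, with optional planted enrichments
#' (the SOC weight of a planted (drug, SOC) pair is multiplied by
#' \eqn{\lambda \ge 1} and the weights renormalized). Corruption
#' mirrors a self-reporting archive: duplicate re-submissions of a case
#' with an incremented version, and incomplete reports missing the case
#' id, the drug name or the reactions.
#'
#' @param n_drugs number of drugs in the lexicon.
#' @param n_reports_per_drug clean reports generated per drug.
#' @param baseline_soc_probs 27 non-negative weights summing to 1
#'   (default uniform).
#' @param enrichments \code{data.frame} with columns \code{drug_id},
#'   \code{soc_code}, \code{lambda} (each \eqn{\lambda \ge 1}).
#' @param duplicate_rate,incomplete_rate fractions in [0, 1): expected
#'   proportion of clean reports that get a duplicate re-submission /
#'   that are accompanied by an extra corrupted report.
#' @param sex_probs named weights over the sex codes \code{F},
#'   \code{M}, \code{UNK}.
#' @param reactions_lambda each report carries \code{1 + rpois(lambda)}
#'   reaction draws.
#' @param llt_fraction probability a reaction is reported as an LLT
#'   rather than its PT.
#' @param role_probs named weights over the index drug's role codes
#'   \code{PS}, \code{SS}, \code{C}; only PS/SS reports contribute to
#'   the ground-truth counts.
#' @param concomitant_rate probability a report additionally mentions a
#'   second drug with role \code{C}.
#' @param atc_rate probability a simulated drug carries ATC codes.
#' @param seed integer seed driving the single pseudo-random stream.
#' @return a validated \code{SimulationConfig} (a classed list).
#' @export
simulationConfig <- function(n_drugs = 20L,
                             n_reports_per_drug = 200L,
                             baseline_soc_probs = rep(1 / 27, 27),
                             enrichments = data.frame(
                                 drug_id = character(), soc_code = character(),
                                 lambda = numeric()),
                             duplicate_rate = 0.05,
                             incomplete_rate = 0.05,
                             sex_probs = c(F = 0.55, M = 0.40, UNK = 0.05),
                             reactions_lambda = 1,
                             llt_fraction = 0.5,
                             role_probs = c(PS = 0.75, SS = 0.20, C = 0.05),
                             concomitant_rate = 0.10,
                             atc_rate = 0.8,
                             seed = 1L) {
    cfg <- list(n_drugs = as.integer(n_drugs),
                n_reports_per_drug = as.integer(n_reports_per_drug),
                baseline_soc_probs = baseline_soc_probs,
                enrichments = enrichments,
                duplicate_rate = duplicate_rate,
                incomplete_rate = incomplete_rate,
                sex_probs = sex_probs,
                reactions_lambda = reactions_lambda,
                llt_fraction = llt_fraction,
                role_probs = role_probs,
                concomitant_rate = concomitant_rate,
                atc_rate = atc_rate,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

#' @describeIn simulationConfig validate a configuration; signals a
#'   configuration error on any invariant violation, returns the config
#'   invisibly otherwise.
#' @param config a \code{SimulationConfig}.
#' @export
validateSimulationConfig <- function(config) {
    with(config, {
        if (n_drugs < 1L || n_reports_per_drug < 1L)
            stop("configuration error: need at least one drug and one report")
        if (length(baseline_soc_probs) != 27L ||
            any(baseline_soc_probs < 0) ||
            abs(sum(baseline_soc_probs) - 1) > 1e-8)
            stop("configuration error: baseline_soc_probs must be 27 ",
                 "non-negative weights summing to 1")
        if (nrow(enrichments) &&
            (any(enrichments$lambda < 1) || any(is.na(enrichments$lambda))))
            stop("configuration error: enrichment factors must be >= 1")
        for (r in c(duplicate_rate, incomplete_rate))
            if (is.na(r) || r < 0 || r >= 1)
                stop("configuration error: rates must lie in [0, 1)")
        for (p in list(sex_probs, role_probs))
            if (any(p < 0) || sum(p) <= 0)
                stop("configuration error: invalid probability weights")
        if (llt_fraction < 0 || llt_fraction > 1 ||
            concomitant_rate < 0 || concomitant_rate > 1 ||
            atc_rate < 0 || atc_rate > 1)
            stop("configuration error: fractions must lie in [0, 1]")
        if (reactions_lambda < 0)
            stop("configuration error: reactions_lambda must be >= 0")
    })
    invisible(config)
}

#' Deterministic fixture dictionary over the full vocabulary
#'
#' Builds a synthetic two-level dictionary with \code{n_pts_per_soc}
#' PTs per SOC (named \code{"pt <code> <j>"}) and one LLT under each PT
#' (\code{"llt <code> <j>"}). Purely deterministic; used by the corpus
#' simulator and the test fixtures in place of the licensed dictionary.
#'
#' @param vocab a \linkS4class{SOCVocabulary}.
#' @param n_pts_per_soc PTs generated per SOC.
#' @return a \linkS4class{MedDRADictionary}.
#' @export
buildFixtureDictionary <- function(vocab, n_pts_per_soc = 4L) {
    codes <- socCodes(vocab)
    pt <- expand.grid(j = seq_len(n_pts_per_soc), soc = codes,
                      stringsAsFactors = FALSE)
    pts <- data.frame(term_text = sprintf("pt %s %d", tolower(pt$soc), pt$j),
                      level = "PT", parent_pt = NA_character_,
                      primary_soc = pt$soc, stringsAsFactors = FALSE)
    llts <- data.frame(term_text = sprintf("llt %s %d", tolower(pt$soc), pt$j),
                       level = "LLT", parent_pt = pts$term_text,
                       primary_soc = NA_character_, stringsAsFactors = FALSE)
    new("MedDRADictionary", terms = rbind(pts, llts),
        version_label = "synthetic-fixture")
}

.writeDictionary <- function(dict, path) {
    utils::write.table(dict@terms, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
}

.writeLexicon <- function(lexicon, path) {
    e <- lexicon@entries
    out <- data.frame(drug_id = e$drug_id,
                      preferred_name = e$preferred_name,
                      synonyms = vapply(e$synonyms, paste, character(1),
                                        collapse = "|"),
                      atc_codes = vapply(e$atc_codes, paste, character(1),
                                         collapse = "|"),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

.writeFaers <- function(df, path) {
    utils::write.table(df, path, sep = "$", quote = FALSE, row.names = FALSE,
                       na = "")
}

#' Simulate a complete synthetic corpus with a ground-truth manifest
#'
#' Generates every input the pipeline consumes -- trials CSV,
#' FAERS-dialect demographic/drug/reaction files, dictionary and
#' lexicon tables -- plus a manifest recording the realized per-drug
#' SOC counts (the counts a correct pipeline must recover), the planted
#' enrichments, and the keys of every injected duplicate and incomplete
#' report. A single seeded pseudo-random stream drives all draws in a
#' fixed, documented order (lexicon ATC codes, trials, reports in drug
#' order, corruption), so identical configurations yield byte-identical
#' files.
#'
#' @param config a \code{SimulationConfig} from [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, \code{list(paths, manifest, vocab, dict, lexicon)}.
#'   \code{manifest$soc_counts} is the 27 x n_drugs ground-truth count
#'   matrix; \code{manifest$trial_counts} the per-drug trial counts.
#' @export
simulateCorpus <- function(config, dir) {
    validateSimulationConfig(config)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    vocab <- defaultSOCVocabulary()
    codes <- socCodes(vocab)
    dict <- buildFixtureDictionary(vocab)
    n_pts <- sum(dict@terms$level == "PT") / 27L

    set.seed(config$seed)

    ## 1. lexicon (ATC draws)
    ids <- sprintf("D%03d", seq_len(config$n_drugs))
    pref <- sprintf("drug%03d", seq_len(config$n_drugs))
    letters14 <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P",
                   "R", "S", "V")
    atc <- lapply(seq_len(config$n_drugs), function(i) {
        if (stats::runif(1) > config$atc_rate) return(character())
        k <- sample(1:2, 1)
        paste0(sample(letters14, k), "01AA", sprintf("%02d", i %% 90 + 1))
    })
    syns <- lapply(seq_len(config$n_drugs), function(i)
        c(pref[i], sprintf("trade%03d", i), paste(pref[i], "sulfate")))
    lexicon <- drugLexicon(ids, pref, syns, atc)

    ## 2. trials
    n_trials <- 1L + stats::rpois(config$n_drugs, 1.5)
    trial_rows <- list(); tix <- 0L
    mk_trial <- function(status, interventions) {
        tix <<- tix + 1L
        data.frame(trial_id = sprintf("NCT%07d", tix), status = status,
                   interventions = interventions, stringsAsFactors = FALSE)
    }
    statuses <- c("Recruiting", "Completed", "Active, not recruiting",
                  "Enrolling by invitation")
    for (i in seq_len(config$n_drugs)) {
        for (k in seq_len(n_trials[i])) {
            syn <- sample(syns[[i]], 1)
            dose <- sample(c(50, 100, 200, 400), 1)
            iv <- sprintf("Drug: %s %d mg", syn, dose)
            if (stats::runif(1) < 0.3)
                iv <- paste0(iv, "|Other: Placebo")
            trial_rows[[length(trial_rows) + 1L]] <-
                mk_trial(sample(statuses, 1), iv)
        }
    }
    # distractors exercising the status / intervention-type / match filters
    trial_rows[[length(trial_rows) + 1L]] <-
        mk_trial("Withdrawn", sprintf("Drug: %s 100 mg", pref[1]))
    trial_rows[[length(trial_rows) + 1L]] <-
        mk_trial("Terminated (halted)", sprintf("Drug: %s 100 mg", pref[1]))
    trial_rows[[length(trial_rows) + 1L]] <-
        mk_trial("Suspended", sprintf("Drug: %s 100 mg",
                 pref[min(2L, config$n_drugs)]))
    trial_rows[[length(trial_rows) + 1L]] <-
        mk_trial("Recruiting", "Behavioral: breathing exercises")
    trial_rows[[length(trial_rows) + 1L]] <-
        mk_trial("Completed", "Drug: traditional herbal decoction")
    trials <- do.call(rbind, trial_rows)

    ## 3. reports, drug by drug
    probs <- matrix(rep(config$baseline_soc_probs, config$n_drugs),
                    nrow = 27L, dimnames = list(codes, ids))
    if (nrow(config$enrichments)) {
        for (r in seq_len(nrow(config$enrichments))) {
            en <- config$enrichments[r, ]
            if (!(en$drug_id %in% ids) || !(en$soc_code %in% codes))
                stop("configuration error: enrichment names unknown drug or SOC")
            probs[en$soc_code, en$drug_id] <-
                probs[en$soc_code, en$drug_id] * en$lambda
        }
        probs <- sweep(probs, 2L, colSums(probs), "/")
    }

    truth <- matrix(0L, nrow = 27L, ncol = config$n_drugs,
                    dimnames = list(codes, ids))
    case_counter <- 10000000L
    sex_codes <- names(config$sex_probs)
    role_codes <- names(config$role_probs)
    N <- config$n_drugs * config$n_reports_per_drug
    rep_cid <- character(N); rep_sex <- character(N)
    rep_names <- vector("list", N); rep_roles <- vector("list", N)
    rep_terms <- vector("list", N)
    w <- 0L

    for (i in seq_len(config$n_drugs)) {
        for (k in seq_len(config$n_reports_per_drug)) {
            case_counter <- case_counter + 1L
            w <- w + 1L
            rep_cid[w] <- as.character(case_counter)
            rep_sex[w] <- sample(sex_codes, 1, prob = config$sex_probs)
            nr <- 1L + stats::rpois(1, config$reactions_lambda)
            socs <- sample(codes, nr, replace = TRUE, prob = probs[, i])
            jdx <- sample.int(n_pts, nr, replace = TRUE)
            lvl <- ifelse(stats::runif(nr) < config$llt_fraction, "llt", "pt")
            terms <- sprintf("%s %s %d", lvl, tolower(socs), jdx)
            role <- sample(role_codes, 1, prob = config$role_probs)
            drug_names <- sample(syns[[i]], 1)
            drug_roles <- role
            if (stats::runif(1) < config$concomitant_rate &&
                config$n_drugs > 1L) {
                other <- sample(setdiff(seq_len(config$n_drugs), i), 1)
                drug_names <- c(drug_names, pref[other])
                drug_roles <- c(drug_roles, "C")
            }
            rep_names[[w]] <- drug_names
            rep_roles[[w]] <- drug_roles
            rep_terms[[w]] <- terms
            # ground truth counts only suspect-role, per-report-unique terms
            if (role %in% c("PS", "SS")) {
                uterms <- unique(terms)
                usocs <- sub("^(llt|pt) (.+) [0-9]+$", "\\2", uterms)
                tt <- table(toupper(usocs))
                truth[names(tt), i] <- truth[names(tt), i] + as.integer(tt)
            }
        }
    }

    ## 4. corruption: duplicates then incompletes, one pass each
    dup_flags <- stats::runif(N) < config$duplicate_rate
    dup <- which(dup_flags)
    dup_ids <- rep_cid[dup]
    n_incomplete <- stats::rbinom(1, N, config$incomplete_rate)
    modes <- if (n_incomplete)
        sample(c("no_caseid", "no_drug", "no_reactions"), n_incomplete,
               replace = TRUE) else character()
    inc_cid <- character(n_incomplete); inc_ver <- integer(n_incomplete)
    inc_sex <- character(n_incomplete); inc_drug <- character(n_incomplete)
    inc_term <- character(n_incomplete)
    blank_ver <- 100L  # unique versions keep blank-id reports distinct keys
    for (m in seq_along(modes)) {
        case_counter <- case_counter + 1L
        cid <- as.character(case_counter)
        ver <- 1L
        inc_sex[m] <- sample(sex_codes, 1, prob = config$sex_probs)
        inc_drug[m] <- pref[sample.int(config$n_drugs, 1)]
        inc_term[m] <- sprintf("pt %s 1", tolower(sample(codes, 1)))
        if (modes[m] == "no_caseid") {
            blank_ver <- blank_ver + 1L
            cid <- ""; ver <- blank_ver
        }
        inc_cid[m] <- cid; inc_ver[m] <- ver
    }
    incomplete <- data.frame(case_id = inc_cid, case_version = inc_ver,
                             mode = modes, stringsAsFactors = FALSE)

    ## assemble the three FAERS tables: clean, duplicate, incomplete blocks
    demo <- rbind(
        data.frame(caseid = rep_cid, caseversion = rep(1L, N),
                   sex = rep_sex, stringsAsFactors = FALSE),
        data.frame(caseid = rep_cid[dup], caseversion = rep(2L, length(dup)),
                   sex = rep_sex[dup], stringsAsFactors = FALSE),
        data.frame(caseid = inc_cid, caseversion = inc_ver, sex = inc_sex,
                   stringsAsFactors = FALSE))
    mk_drug <- function(idx, ver) {
        n <- sum(lengths(rep_names[idx]))
        data.frame(
            caseid = rep(rep_cid[idx], lengths(rep_names[idx])),
            caseversion = rep(ver, n),
            role_cod = unlist(rep_roles[idx], use.names = FALSE),
            drugname = unlist(rep_names[idx], use.names = FALSE),
            stringsAsFactors = FALSE)
    }
    keep_drug <- modes != "no_drug"
    drg <- rbind(
        mk_drug(seq_len(N), 1L), mk_drug(dup, 2L),
        data.frame(caseid = inc_cid[keep_drug],
                   caseversion = inc_ver[keep_drug],
                   role_cod = rep("PS", sum(keep_drug)),
                   drugname = inc_drug[keep_drug], stringsAsFactors = FALSE))
    mk_reac <- function(idx, ver) {
        n <- sum(lengths(rep_terms[idx]))
        data.frame(
            caseid = rep(rep_cid[idx], lengths(rep_terms[idx])),
            caseversion = rep(ver, n),
            pt = unlist(rep_terms[idx], use.names = FALSE),
            stringsAsFactors = FALSE)
    }
    keep_reac <- modes != "no_reactions"
    rea <- rbind(
        mk_reac(seq_len(N), 1L), mk_reac(dup, 2L),
        data.frame(caseid = inc_cid[keep_reac],
                   caseversion = inc_ver[keep_reac], pt = inc_term[keep_reac],
                   stringsAsFactors = FALSE))

    paths <- list(
        trials = file.path(dir, "trials.csv"),
        demo = file.path(dir, "demo.txt"),
        drug = file.path(dir, "drug.txt"),
        reac = file.path(dir, "reac.txt"),
        dictionary = file.path(dir, "meddra.tsv"),
        lexicon = file.path(dir, "lexicon.tsv"),
        vocabulary = file.path(dir, "soc_vocabulary.tsv"),
        manifest = file.path(dir, "manifest.json"))
    utils::write.csv(trials, paths$trials, row.names = FALSE, quote = TRUE)
    .writeFaers(demo, paths$demo)
    .writeFaers(drg, paths$drug)
    .writeFaers(rea, paths$reac)
    .writeDictionary(dict, paths$dictionary)
    .writeLexicon(lexicon, paths$lexicon)
    file.copy(system.file("extdata", "soc_vocabulary.tsv",
                          package = "socsafety", mustWork = TRUE),
              paths$vocabulary, overwrite = TRUE)

    trial_counts <- stats::setNames(n_trials, ids)
    manifest <- list(
        soc_counts = truth,
        planted = config$enrichments,
        duplicate_case_ids = dup_ids,
        incomplete_reports = incomplete,
        trial_counts = trial_counts,
        n_clean_reports = N,
        seed = config$seed)
    mj <- manifest
    mj$soc_counts <- as.data.frame(mj$soc_counts)
    jsonlite::write_json(mj, paths$manifest, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    invisible(list(paths = paths, manifest = manifest, vocab = vocab,
                   dict = dict, lexicon = lexicon))
}
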