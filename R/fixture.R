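#' Write the frozen hand-checkable micro-corpus
#'
#' Emits a small, fully deterministic corpus (12 distinct cases over 3
#' drugs, 5 SOCs in use) that exercises every cleaning rule: a
#' duplicated case resubmitted with an incremented version (twice), an
#' incomplete report missing its case id and one missing its reactions,
#' a concomitant-only report that must yield no records, an unmapped
#' reaction term, an LLT resolving through its parent PT, a trade-name
#' drug mention with dose text, a repeated reaction term that must
#' collapse, and F/M/UNK sex codes. The correct post-pipeline counts
#' were tallied by hand once and are written alongside as
#' \code{expected_counts.tsv}. No randomness: regenerating the fixture
#' yields identical bytes.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of file paths (the corpus files plus
#'   \code{expected_counts}).
#' @export
writeFixtureSmall <- function(dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)

    lexicon <- data.frame(
        drug_id = c("D1", "D2", "D3"),
        preferred_name = c("alphacillin", "betaprofen", "gammazole"),
        synonyms = c("alphacillin|alphacil", "betaprofen|betafen",
                     "gammazole"),
        atc_codes = c("J01CA01", "M01AE01|N02BB02", ""),
        stringsAsFactors = FALSE)

    dict <- data.frame(
        term_text = c("cardiac arrest", "chest pain", "fatigue", "nausea",
                      "headache", "rash", "tired", "feeling sick"),
        level = c(rep("PT", 6), "LLT", "LLT"),
        parent_pt = c(rep(NA, 6), "fatigue", "nausea"),
        primary_soc = c("CARD", "CARD", "GD", "GI", "NERV", "SKIN", NA, NA),
        stringsAsFactors = FALSE)

    trials <- data.frame(
        trial_id = c("NCT0000001", "NCT0000002", "NCT0000003", "NCT0000004"),
        status = c("Completed", "Recruiting", "Withdrawn", "Completed"),
        interventions = c("Drug: Alphacillin 500 mg",
                          "Drug: Betaprofen 200 mg|Drug: Alphacillin 100 mg",
                          "Drug: Gammazole 50 mg",
                          "Behavioral: yoga"),
        stringsAsFactors = FALSE)

    demo <- data.frame(
        caseid = c("1001", "1001", "1002", "1003", "1004", "1005", "1006",
                   "1007", "1008", "1009", "", "1010", "1011", "1011"),
        caseversion = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 99L, 1L,
                        1L, 2L),
        sex = c("F", "F", "M", "UNK", "F", "M", "F", "F", "M", "F", "F",
                "M", "F", "F"),
        stringsAsFactors = FALSE)

    drug <- data.frame(
        caseid = c("1001", "1001", "1002", "1002", "1003", "1004", "1005",
                   "1006", "1007", "1008", "1009", "", "1010", "1011",
                   "1011"),
        caseversion = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 99L,
                        1L, 1L, 2L),
        role_cod = c("PS", "PS", "PS", "SS", "PS", "C", "PS", "PS", "PS",
                     "PS", "PS", "PS", "PS", "PS", "PS"),
        drugname = c("Alphacillin", "Alphacillin", "alphacillin",
                     "betaprofen", "Betaprofen", "gammazole", "gammazole",
                     "betaprofen", "alphacillin", "Alphacil 500 mg",
                     "betaprofen", "alphacillin", "alphacillin",
                     "gammazole", "gammazole"),
        stringsAsFactors = FALSE)

    reac <- data.frame(
        caseid = c("1001", "1001", "1001", "1001", "1002", "1003", "1004",
                   "1005", "1005", "1006", "1006", "1007", "1008", "1009",
                   "1009", "", "1011", "1011"),
        caseversion = c(1L, 1L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
                        1L, 1L, 1L, 99L, 1L, 2L),
        pt = c("Cardiac Arrest", "Fatigue", "Cardiac Arrest", "Fatigue",
               "NAUSEA", "tired", "rash", "headache", "rash",
               "feeling sick", "nausea", "totally made up term",
               "chest pain", "rash", "rash", "nausea", "fatigue",
               "fatigue"),
        stringsAsFactors = FALSE)

    # hand-tallied post-pipeline (drug, SOC) counts:
    #   case 1001 keeps v2 (CARD+GD for D1); 1002 credits D1 and D2 one GI
    #   each; 1003 is an LLT -> GD for D2; 1004 is concomitant-only; 1005
    #   gives D3 NERV+SKIN; 1006 gives D2 GI twice (two distinct terms);
    #   1007 is unmapped; 1008 CARD via trade name; 1009 collapses to one
    #   SKIN; blank-id and reaction-less 1010 are dropped; 1011 keeps v2
    #   (GD for D3).
    expected <- data.frame(
        drug_id = c("D1", "D1", "D1", "D2", "D2", "D2", "D3", "D3", "D3"),
        soc_code = c("CARD", "GD", "GI", "GD", "GI", "SKIN", "GD", "NERV",
                     "SKIN"),
        count = c(2L, 1L, 1L, 1L, 3L, 1L, 1L, 1L, 1L),
        stringsAsFactors = FALSE)

    paths <- list(
        trials = file.path(dir, "trials.csv"),
        demo = file.path(dir, "demo.txt"),
        drug = file.path(dir, "drug.txt"),
        reac = file.path(dir, "reac.txt"),
        dictionary = file.path(dir, "meddra.tsv"),
        lexicon = file.path(dir, "lexicon.tsv"),
        vocabulary = file.path(dir, "soc_vocabulary.tsv"),
        expected_counts = file.path(dir, "expected_counts.tsv"))
    utils::write.csv(trials, paths$trials, row.names = FALSE, quote = TRUE)
    .writeFaers(demo, paths$demo)
    .writeFaers(drug, paths$drug)
    .writeFaers(reac, paths$reac)
    utils::write.table(dict, paths$dictionary, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    utils::write.table(lexicon, paths$lexicon, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.copy(system.file("extdata", "soc_vocabulary.tsv",
                          package = "socsafety", mustWork = TRUE),
              paths$vocabulary, overwrite = TRUE)
    utils::write.table(expected, paths$expected_counts, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(paths)
}
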