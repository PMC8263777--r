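# Shared in-code fixtures for the unit tests.

tinyVocab <- function() defaultSOCVocabulary()

# five-term dictionary exercising both levels and the unmapped path
tinyDict <- function() {
    path <- tempfile(fileext = ".tsv")
    writeLines(c(
        "term_text\tlevel\tparent_pt\tprimary_soc",
        "cardiac arrest\tPT\t\tCARD",
        "nausea\tPT\t\tGI",
        "fatigue\tPT\t\tGD",
        "tired\tLLT\tfatigue\t",
        "feeling sick\tLLT\tnausea\t"), path)
    loadMedDRADictionary(path, tinyVocab())
}

tinyLexicon <- function() {
    drugLexicon(
        drug_id = c("HCQ", "CQ", "LPV", "RTV"),
        preferred_name = c("hydroxychloroquine", "chloroquine",
                           "lopinavir", "ritonavir"),
        synonyms = list(
            c("hydroxychloroquine sulfate", "plaquenil"),
            c("chloroquine phosphate"),
            character(),
            character()),
        atc_codes = list("P01BA02", "P01BA01", "J05AE06", "J05AE03"))
}

# simulate a corpus and push it through the pipeline stages in memory
runCorpus <- function(sim, out_dir = tempfile(), stratify = TRUE) {
    cfg <- pipelineConfig(
        trials = sim$paths$trials, demo = sim$paths$demo,
        drug = sim$paths$drug, reac = sim$paths$reac,
        dictionary = sim$paths$dictionary, lexicon = sim$paths$lexicon,
        vocabulary = sim$paths$vocabulary, out_dir = out_dir,
        stratify = stratify)
    cmdRun(cfg)
}

# clean + map + aggregate without touching the trials stage or disk
corpusProfiles <- function(sim) {
    reports <- readReports(sim$paths$demo, sim$paths$drug, sim$paths$reac)
    kept <- deduplicateReports(dropIncomplete(reports)$kept)$kept
    records <- explodeSuspectEvents(kept, sim$lexicon, sim$dict, sim$vocab)
    computeZscores(aggregateProfiles(records, sim$vocab))
}
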