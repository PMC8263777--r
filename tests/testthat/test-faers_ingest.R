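writeFaersTriple <- function(demo, drug, reac, sep = "$") {
    paths <- list(demo = tempfile(), drug = tempfile(), reac = tempfile())
    w <- function(df, p) utils::write.table(df, p, sep = sep, quote = FALSE,
                                            row.names = FALSE, na = "")
    w(demo, paths$demo); w(drug, paths$drug); w(reac, paths$reac)
    paths
}

test_that("the three report files join on (case id, version)", {
    p <- writeFaersTriple(
        data.frame(caseid = c("1", "2"), caseversion = 1L,
                   sex = c("F", "M")),
        data.frame(caseid = c("1", "2"), caseversion = 1L, role_cod = "PS",
                   drugname = c("a", "b")),
        data.frame(caseid = c("1", "2"), caseversion = 1L,
                   pt = c("x", "y")))
    reports <- readReports(p$demo, p$drug, p$reac)
    expect_identical(nrow(reports), 2L)
    expect_identical(reports$sex_code, c("F", "M"))
    expect_identical(reports$drug_names[[1]], "a")
})

test_that("a drug row without a demo row yields a sexless complete report", {
    p <- writeFaersTriple(
        data.frame(caseid = "1", caseversion = 1L, sex = "F"),
        data.frame(caseid = c("1", "2"), caseversion = 1L, role_cod = "PS",
                   drugname = c("a", "b")),
        data.frame(caseid = c("1", "2"), caseversion = 1L,
                   pt = c("x", "y")))
    reports <- readReports(p$demo, p$drug, p$reac)
    r2 <- reports[reports$case_id == "2", ]
    expect_true(is.na(r2$sex_code))
    expect_identical(dropIncomplete(reports)$n_dropped, 0L)
})

test_that("an empty reaction file makes every report incomplete", {
    p <- writeFaersTriple(
        data.frame(caseid = c("1", "2"), caseversion = 1L,
                   sex = c("F", "M")),
        data.frame(caseid = c("1", "2"), caseversion = 1L, role_cod = "PS",
                   drugname = c("a", "b")),
        data.frame(caseid = character(), caseversion = integer(),
                   pt = character()))
    reports <- readReports(p$demo, p$drug, p$reac)
    inc <- dropIncomplete(reports)
    expect_identical(nrow(inc$kept), 0L)
    expect_identical(inc$n_dropped, 2L)
})

test_that("reports missing id, drug or reactions are dropped", {
    p <- writeFaersTriple(
        data.frame(caseid = c("", "2", "3"), caseversion = c(7L, 1L, 1L),
                   sex = "F"),
        data.frame(caseid = c("", "2", "3"), caseversion = c(7L, 1L, 1L),
                   role_cod = "PS", drugname = c("a", "", "c")),
        data.frame(caseid = c("", "2", "3"), caseversion = c(7L, 1L, 1L),
                   pt = c("x", "y", "z")))
    inc <- dropIncomplete(readReports(p$demo, p$drug, p$reac))
    expect_identical(inc$kept$case_id, "3")
    expect_identical(inc$n_dropped, 2L)
})

test_that("deduplication keeps the latest version of a repeated case", {
    p <- writeFaersTriple(
        data.frame(caseid = "10", caseversion = 1:3, sex = "F"),
        data.frame(caseid = "10", caseversion = 1:3, role_cod = "PS",
                   drugname = "drug a"),
        data.frame(caseid = "10", caseversion = 1:3, pt = "headache"))
    dd <- deduplicateReports(readReports(p$demo, p$drug, p$reac))
    expect_identical(nrow(dd$kept), 1L)
    expect_identical(dd$kept$case_version, 3L)
    expect_identical(dd$n_removed, 2L)
    # idempotence
    dd2 <- deduplicateReports(dd$kept)
    expect_identical(dd2$n_removed, 0L)
    expect_identical(dd2$kept, dd$kept)
})

test_that("same case id with different reaction sets is not a duplicate", {
    p <- writeFaersTriple(
        data.frame(caseid = "10", caseversion = 1:2, sex = "F"),
        data.frame(caseid = "10", caseversion = 1:2, role_cod = "PS",
                   drugname = "drug a"),
        data.frame(caseid = c("10", "10"), caseversion = 1:2,
                   pt = c("headache", "nausea")))
    dd <- deduplicateReports(readReports(p$demo, p$drug, p$reac))
    expect_identical(nrow(dd$kept), 2L)
    expect_identical(dd$n_removed, 0L)
})

test_that("the dedup key is order-insensitive in drugs and reactions", {
    p <- writeFaersTriple(
        data.frame(caseid = "10", caseversion = 1:2, sex = "F"),
        data.frame(caseid = rep("10", 4), caseversion = c(1L, 1L, 2L, 2L),
                   role_cod = "PS",
                   drugname = c("a", "b", "b", "a")),
        data.frame(caseid = rep("10", 4), caseversion = c(1L, 1L, 2L, 2L),
                   pt = c("x", "y", "Y", "x")))
    dd <- deduplicateReports(readReports(p$demo, p$drug, p$reac))
    expect_identical(nrow(dd$kept), 1L)
    expect_identical(dd$kept$case_version, 2L)
})

test_that("a tied highest version keeps the later report and warns", {
    # two distinct reports collapse under the same dedup key and tie on
    # version; build them directly rather than through a file round-trip,
    # which would merge rows sharing the join key
    reports <- data.frame(case_id = c("10", "10"), case_version = c(2L, 2L),
                          sex_code = c("F", "M"), stringsAsFactors = FALSE)
    reports$drug_names <- list("a", "a")
    reports$drug_roles <- list("PS", "PS")
    reports$reactions <- list("x", "x")
    expect_warning(dd <- deduplicateReports(reports), "tied")
    expect_identical(nrow(dd$kept), 1L)
    expect_identical(dd$kept$sex_code, "M")
})

test_that("suspect-role expansion emits one record per drug-event pair", {
    lex <- tinyLexicon(); dict <- tinyDict(); vocab <- tinyVocab()
    p <- writeFaersTriple(
        data.frame(caseid = c("1", "2", "3"), caseversion = 1L,
                   sex = c("F", "M", "UNK")),
        data.frame(caseid = c("1", "2", "3"), caseversion = 1L,
                   role_cod = c("PS", "C", "PS"),
                   drugname = c("hydroxychloroquine", "chloroquine",
                                "ritonavir")),
        data.frame(caseid = c("1", "1", "2", "3"),
                   caseversion = 1L,
                   pt = c("cardiac arrest", "tired", "nausea",
                          "feeling sick")))
    reports <- deduplicateReports(
        dropIncomplete(readReports(p$demo, p$drug, p$reac))$kept)$kept
    rec <- explodeSuspectEvents(reports, lex, dict, vocab)
    # report 1: PS drug, two mapped reactions -> 2 records
    expect_identical(sum(rec$drug_id == "HCQ"), 2L)
    # report 2: concomitant-only -> nothing
    expect_false("CQ" %in% rec$drug_id)
    # report 3: UNK sex kept overall, excluded from sex strata
    expect_identical(rec$sex_stratum[rec$drug_id == "RTV"], "unspecified")
    expect_identical(nrow(rec), 3L)
})

test_that("a drug mentioned as both PS and SS counts once per reaction", {
    lex <- tinyLexicon(); dict <- tinyDict(); vocab <- tinyVocab()
    p <- writeFaersTriple(
        data.frame(caseid = "1", caseversion = 1L, sex = "F"),
        data.frame(caseid = c("1", "1"), caseversion = 1L,
                   role_cod = c("PS", "SS"),
                   drugname = c("chloroquine", "chloroquine phosphate")),
        data.frame(caseid = "1", caseversion = 1L, pt = "nausea"))
    reports <- readReports(p$demo, p$drug, p$reac)
    rec <- explodeSuspectEvents(reports, lex, dict, vocab)
    expect_identical(nrow(rec), 1L)
    expect_identical(rec$drug_id, "CQ")
})

test_that("unmapped terms and unmatched drugs are dropped with counters", {
    lex <- tinyLexicon(); dict <- tinyDict(); vocab <- tinyVocab()
    p <- writeFaersTriple(
        data.frame(caseid = c("1", "2"), caseversion = 1L,
                   sex = c("F", "M")),
        data.frame(caseid = c("1", "2"), caseversion = 1L, role_cod = "PS",
                   drugname = c("chloroquine", "unheard-of elixir")),
        data.frame(caseid = c("1", "1", "2"), caseversion = 1L,
                   pt = c("nausea", "martian fever", "nausea")))
    rec <- explodeSuspectEvents(readReports(p$demo, p$drug, p$reac),
                                lex, dict, vocab)
    counters <- attr(rec, "counters")
    expect_identical(unname(counters["unmapped_reaction_mentions"]), 1L)
    expect_identical(unname(counters["unmatched_drug_mentions"]), 1L)
    expect_identical(nrow(rec), 1L)
})

test_that("stratum counts always sum to the overall record count", {
    cfg <- simulationConfig(n_drugs = 5, n_reports_per_drug = 80, seed = 3)
    sim <- simulateCorpus(cfg, tempfile())
    reports <- readReports(sim$paths$demo, sim$paths$drug, sim$paths$reac)
    kept <- deduplicateReports(dropIncomplete(reports)$kept)$kept
    rec <- explodeSuspectEvents(kept, sim$lexicon, sim$dict, sim$vocab)
    expect_identical(
        nrow(rec),
        sum(rec$sex_stratum == "female") + sum(rec$sex_stratum == "male") +
            sum(rec$sex_stratum == "unspecified"))
})

test_that("pipeline counts equal an independent brute-force recount", {
    cfg <- simulationConfig(n_drugs = 4, n_reports_per_drug = 50, seed = 29)
    sim <- simulateCorpus(cfg, tempfile())
    prof <- corpusProfiles(sim)
    cnt <- SummarizedExperiment::assay(prof, "counts")
    expect_identical(flattenCounts(cnt), oracleRecount(sim$paths))
})

test_that("cleaning removes exactly the manifest-listed corruption", {
    cfg <- simulationConfig(n_drugs = 4, n_reports_per_drug = 50,
                            duplicate_rate = 0.1, incomplete_rate = 0.1,
                            seed = 47)
    sim <- simulateCorpus(cfg, tempfile())
    reports <- readReports(sim$paths$demo, sim$paths$drug, sim$paths$reac)
    inc <- dropIncomplete(reports)
    expect_identical(inc$n_dropped, nrow(sim$manifest$incomplete_reports))
    dd <- deduplicateReports(inc$kept)
    expect_identical(dd$n_removed,
                     length(sim$manifest$duplicate_case_ids))
    # survivors of duplicated cases carry the resubmitted version
    dupes <- dd$kept[dd$kept$case_id %in% sim$manifest$duplicate_case_ids, ]
    expect_true(all(dupes$case_version == 2L))
})
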