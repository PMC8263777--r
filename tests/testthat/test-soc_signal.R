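# direct mean/SD arithmetic, independent of the package implementation
oracleZ <- function(counts) {
    mu <- sum(counts) / 27
    sigma <- sqrt(sum((counts - mu)^2) / 27)
    if (sigma == 0) rep(NA_real_, 27) else (counts - mu) / sigma
}

test_that("profiles tally records per (drug, SOC) in vocabulary order", {
    vocab <- tinyVocab()
    rec <- data.frame(drug_id = "X", soc_code = rep("CARD", 5),
                      sex_stratum = "female", case_id = as.character(1:5))
    prof <- aggregateProfiles(rec, vocab)
    cnt <- SummarizedExperiment::assay(prof, "counts")
    expect_identical(rownames(cnt), socCodes(vocab))
    expect_identical(cnt["CARD", "X"], 5L)
    expect_identical(sum(cnt), 5L)
    # empty input -> no drug columns
    empty <- rec[0, ]
    expect_identical(ncol(aggregateProfiles(empty, vocab)), 0L)
    # stratum selection drops other strata's records
    expect_identical(ncol(aggregateProfiles(rec, vocab, "male")), 0L)
})

test_that("one-hot and shifted profiles give the closed-form Z", {
    onehot <- c(100, rep(0, 26))
    z1 <- computeZscores(onehot)
    expect_equal(z1[1], sqrt(26), tolerance = 1e-12)
    expect_equal(z1[-1], rep(-1 / sqrt(26), 26), tolerance = 1e-12)
    # location-scale invariance: (3, 1 x 26) = 2 * onehot/100 + 1
    z2 <- computeZscores(c(3, rep(1, 26)))
    expect_equal(z2, z1, tolerance = 1e-9)
    expect_equal(z2, oracleZ(c(3, rep(1, 26))), tolerance = 1e-12)
})

test_that("zero dispersion yields undefined Z, zero total an error", {
    z <- computeZscores(rep(7, 27))
    expect_true(all(is.na(z)))
    expect_identical(unique(zBand(z)), "undefined")
    expect_error(computeZscores(rep(0, 27)), "empty-profile")
    expect_error(computeZscores(rep(1, 26)), "27")
})

test_that("Z vectors satisfy the moment invariants on random profiles", {
    set.seed(123)
    for (i in 1:300) {
        counts <- stats::rpois(27, lambda = sample(c(0.5, 2, 20, 200), 1))
        if (sum(counts) == 0) counts[1] <- 1
        z <- computeZscores(counts)
        if (all(is.na(z))) next
        expect_lt(abs(sum(z)), 1e-9)
        expect_lt(abs(sum(z^2) - 27), 1e-9)
        expect_lte(max(abs(z)), sqrt(26) + 1e-12)
        expect_lte(sum(z > 2), 6L)
        expect_equal(z, oracleZ(counts), tolerance = 1e-12)
    }
})

test_that("Z is invariant under positive affine count transforms", {
    set.seed(5)
    for (i in 1:50) {
        counts <- stats::rpois(27, 10)
        if (stats::sd(counts) == 0) next
        a <- stats::runif(1, 0.5, 10); b <- sample(0:50, 1)
        expect_equal(computeZscores(a * counts + b), computeZscores(counts),
                     tolerance = 1e-9)
    }
})

test_that("permuting SOC order permutes Z identically", {
    set.seed(9)
    counts <- stats::rpois(27, 8)
    perm <- sample(27)
    expect_equal(unname(computeZscores(counts[perm])),
                 unname(computeZscores(counts)[perm]), tolerance = 1e-12)
})

test_that("the sample-SD divisor option rescales Z by sqrt(26/27)", {
    # the sample SD is larger by sqrt(27/26), so the Z-scores shrink
    counts <- c(40, rep(2, 26))
    zp <- computeZscores(counts)
    zs <- computeZscores(counts, divisor = "sample")
    expect_equal(zs, zp * sqrt(26 / 27), tolerance = 1e-12)
})

test_that("banding follows the five-band thresholds and boundary rules", {
    expect_identical(zBand(3.7), "significantly_frequent")
    expect_identical(zBand(2.4), "significantly_frequent")
    expect_identical(zBand(-0.03), "likely_infrequent")
    # the significance rule is strictly > 2, so 2.0 is only 'frequent'
    expect_identical(zBand(2.0), "frequent")
    # half-open bands: each boundary belongs to the band below it
    expect_identical(zBand(c(1.0, 0.5, 0, -1, -1.5)),
                     c("slightly_frequent", "slightly_frequent",
                       "likely_infrequent", "infrequent", "infrequent"))
    expect_identical(zBand(NA_real_), "undefined")
})

test_that("significant SOCs are those with Z strictly above 2", {
    z <- stats::setNames(rep(-0.5, 27), sprintf("S%02d", 1:27))
    z["S05"] <- 2.4
    expect_identical(significantSOCs(z), "S05")
    z["S05"] <- 2
    expect_identical(significantSOCs(z), character())
    # never more than 6 on any valid profile
    set.seed(77)
    for (i in 1:100) {
        zz <- computeZscores(stats::rpois(27, 3) + 1)
        if (all(is.na(zz))) next
        expect_lte(length(significantSOCs(stats::setNames(zz,
            sprintf("S%02d", 1:27)))), 6L)
    }
})

test_that("profile sets gain z assay and per-drug moments", {
    vocab <- tinyVocab()
    rec <- data.frame(
        drug_id = rep(c("X", "Y"), c(4, 3)),
        soc_code = c("CARD", "CARD", "GI", "GD", "NERV", "NERV", "SKIN"),
        sex_stratum = "female", case_id = as.character(1:7))
    prof <- computeZscores(aggregateProfiles(rec, vocab))
    z <- SummarizedExperiment::assay(prof, "z")
    cd <- SummarizedExperiment::colData(prof)
    expect_identical(unname(cd$total), c(4, 3))
    expect_equal(z[, "X"], oracleZ(SummarizedExperiment::assay(prof,
        "counts")[, "X"]), tolerance = 1e-12)
    expect_equal(unname(cd$mu), c(4, 3) / 27)
})

test_that("ATC class summaries average events over member drugs", {
    vocab <- tinyVocab()
    lex <- drugLexicon(c("d1", "d2", "d3", "d4"),
                       c("drug one", "drug two", "drug three", "drug four"),
                       list(character(), character(), character(),
                            character()),
                       atc_codes = list("J01FA10", c("J01XX01", "j05AB01"),
                                        c("A02BC01", "N05BA01"),
                                        character()))
    rec <- data.frame(
        drug_id = rep(c("d1", "d2", "d3", "d4"), c(10, 30, 8, 2)),
        soc_code = "CARD", sex_stratum = "female",
        case_id = as.character(1:50))
    prof <- computeZscores(aggregateProfiles(rec, vocab))
    s <- atcClassSummary(prof, lex)
    j <- s[s$atc_class == "J", ]
    # two drugs in J (d2's duplicate first letter collapses), totals 10+30
    expect_identical(j$n_drugs, 2L)
    expect_identical(j$total_events, 40)
    expect_identical(j$mean_events_per_drug, 20)
    # d3 contributes its full total to both A and N
    expect_identical(s$total_events[s$atc_class == "A"], 8)
    expect_identical(s$total_events[s$atc_class == "N"], 8)
    # d4 has no codes and appears nowhere
    expect_identical(sum(s$n_drugs), 4L)
    # a lexicon with no ATC codes at all -> empty summary
    lex0 <- drugLexicon("d1", "drug one", list(character()))
    rec1 <- rec[rec$drug_id == "d1", ]
    expect_identical(nrow(atcClassSummary(
        computeZscores(aggregateProfiles(rec1, vocab)), lex0)), 0L)
})

test_that("planted signals attain the maximum Z and exceed 2", {
    hits <- 0L
    for (seed in 1:5) {
        cfg <- simulationConfig(
            n_drugs = 8, n_reports_per_drug = 200, reactions_lambda = 0,
            enrichments = data.frame(drug_id = "D003", soc_code = "HEPAT",
                                     lambda = 5),
            seed = seed)
        sim <- simulateCorpus(cfg, tempfile())
        prof <- corpusProfiles(sim)
        z <- SummarizedExperiment::assay(prof, "z")
        if (which.max(z[, "D003"]) == which(rownames(z) == "HEPAT") &&
            z["HEPAT", "D003"] > 2) hits <- hits + 1L
    }
    expect_identical(hits, 5L)
})
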