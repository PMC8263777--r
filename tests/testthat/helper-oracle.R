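# Independent brute-force recount of per-(drug, SOC) totals straight from
# the raw corpus files. Deliberately written as plain nested loops with its
# own normalization, matching, mapping and cleaning logic -- it shares no
# code with the package implementation it checks.

oracleNorm <- function(s) {
    s <- tolower(s)
    s <- gsub("[[:space:]]+", " ", s)
    gsub("^[[:punct:] ]+|[[:punct:] ]+$", "", s)
}

oracleRecount <- function(paths, sep = "$") {
    rd <- function(p) utils::read.delim(p, sep = sep, quote = "",
                                        colClasses = "character",
                                        na.strings = character())
    demo <- rd(paths$demo); drug <- rd(paths$drug); reac <- rd(paths$reac)
    lex <- utils::read.delim(paths$lexicon, colClasses = "character")
    dict <- utils::read.delim(paths$dictionary, colClasses = "character",
                              na.strings = c("", "NA"))

    # term -> primary SOC (LLT through its parent PT)
    soc_of <- new.env()
    for (i in seq_len(nrow(dict)))
        if (dict$level[i] == "PT")
            assign(oracleNorm(dict$term_text[i]), dict$primary_soc[i], soc_of)
    for (i in seq_len(nrow(dict)))
        if (dict$level[i] == "LLT")
            assign(oracleNorm(dict$term_text[i]),
                   get(oracleNorm(dict$parent_pt[i]), soc_of), soc_of)

    # synonym token sequences per drug
    syn_tokens <- list(); syn_drug <- character()
    for (i in seq_len(nrow(lex))) {
        for (s in strsplit(lex$synonyms[i], "|", fixed = TRUE)[[1]]) {
            syn_tokens[[length(syn_tokens) + 1L]] <-
                strsplit(gsub("[^a-z0-9]+", " ", oracleNorm(s)), " ")[[1]]
            syn_drug <- c(syn_drug, lex$drug_id[i])
        }
    }
    match_one <- function(name) {
        tok <- strsplit(gsub("[^a-z0-9]+", " ", oracleNorm(name)), " ")[[1]]
        hits <- character()
        for (k in seq_along(syn_tokens)) {
            s <- syn_tokens[[k]]; m <- length(s)
            if (m == 0L || m > length(tok)) next
            for (p in seq_len(length(tok) - m + 1L))
                if (all(tok[p:(p + m - 1L)] == s)) {
                    hits <- c(hits, syn_drug[k]); break
                }
        }
        unique(hits)
    }

    # assemble reports key by key
    keys <- unique(c(paste0(demo$caseid, "#", demo$caseversion),
                     paste0(drug$caseid, "#", drug$caseversion),
                     paste0(reac$caseid, "#", reac$caseversion)))
    kd <- paste0(drug$caseid, "#", drug$caseversion)
    kr <- paste0(reac$caseid, "#", reac$caseversion)
    reports <- list()
    for (key in keys) {
        cid <- sub("#[^#]*$", "", key)
        ver <- as.integer(sub("^.*#", "", key))
        di <- which(kd == key); ri <- which(kr == key)
        reports[[length(reports) + 1L]] <- list(
            cid = cid, ver = ver,
            names = drug$drugname[di], roles = drug$role_cod[di],
            terms = reac$pt[ri])
    }

    # completeness, then keep latest version per duplicate group
    complete <- vapply(reports, function(r)
        nzchar(r$cid) && any(nzchar(r$names)) && any(nzchar(r$terms)),
        logical(1))
    reports <- reports[complete]
    gkey <- vapply(reports, function(r)
        paste(r$cid,
              paste(sort(unique(oracleNorm(r$names[nzchar(r$names)]))),
                    collapse = ";"),
              paste(sort(unique(oracleNorm(r$terms[nzchar(r$terms)]))),
                    collapse = ";"), sep = "@@"), character(1))
    keep <- logical(length(reports))
    for (g in unique(gkey)) {
        i <- which(gkey == g)
        vmax <- max(vapply(reports[i], `[[`, integer(1), "ver"))
        top <- i[vapply(reports[i], `[[`, integer(1), "ver") == vmax]
        keep[top[length(top)]] <- TRUE
    }
    reports <- reports[keep]

    counts <- new.env()
    for (r in reports) {
        suspects <- unique(r$names[r$roles %in% c("PS", "SS") &
                                   nzchar(r$names)])
        ids <- character()
        for (s in suspects) ids <- c(ids, match_one(s))
        ids <- unique(ids)
        terms <- unique(oracleNorm(r$terms[nzchar(r$terms)]))
        for (id in ids) for (tm in terms) {
            if (!exists(tm, soc_of, inherits = FALSE)) next
            k <- paste0(id, "|", get(tm, soc_of))
            assign(k, (if (exists(k, counts, inherits = FALSE))
                get(k, counts) else 0L) + 1L, counts)
        }
    }
    out <- unlist(as.list(counts))
    if (is.null(out)) out <- integer()
    out[order(names(out))]
}

# flatten a counts matrix from the pipeline into the oracle's key form
flattenCounts <- function(cnt) {
    nz <- which(cnt > 0, arr.ind = TRUE)
    v <- cnt[nz]
    names(v) <- paste0(colnames(cnt)[nz[, 2]], "|", rownames(cnt)[nz[, 1]])
    v <- v[order(names(v))]
    storage.mode(v) <- "integer"
    v
}
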