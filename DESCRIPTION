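Package: socsafety
Title: SOC-Level Z-Score Safety Concern Profiles from Spontaneous
    Adverse-Event Reports
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pharmacovigilance pipeline that turns FAERS-style
    spontaneous adverse-event reports into per-drug safety concern
    profiles over the 27 MedDRA system organ classes (SOCs). It covers
    identification of drugs from a clinical-trials registry export,
    cleaning of report files (removal of incomplete reports,
    deduplication by case identity, suspect-role filtering), mapping of
    reported LLT/PT reaction terms to primary SOCs, and a within-drug
    Z-score that standardizes each SOC count against the drug's own
    27-SOC distribution, with a five-band categorization, sex-stratified
    tables and ATC first-level class summaries. A synthetic-corpus
    generator with a ground-truth manifest makes the whole pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, Pharmacogenomics, Epidemiology, QualityControl
RoxygenNote: 7.3.3
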