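Package: dmtpv
Title: Pharmacovigilance Analysis of Multiple Sclerosis Therapies in
    Pregnancy and Lactation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for disproportionality analysis of spontaneous adverse
    event reports on multiple sclerosis disease-modifying therapies used
    during pregnancy and breastfeeding. Reads and writes
    EudraVigilance-style individual case safety report (ICSR) line
    listings, selects pregnancy and lactation cases by keyword and
    route-of-administration rules, partitions every reaction term into ten
    clinically defined event groups, produces the descriptive case and
    event tables, and computes reporting odds ratios (ROR) with Woolf 95
    percent confidence intervals for each newer therapy against glatiramer
    as comparator. Includes a deterministic exact-count case set matching
    the published marginal tables and a stochastic report generator for
    testing every pipeline stage offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
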