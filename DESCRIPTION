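Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("pvsignal", "developers", email = "pvsignal@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance disproportionality analysis of
    individual case safety report (ICSR) line listings, with reference
    tables for the ATC N03A antiseizure medications. Parses
    EudraVigilance-style line-listing exports with packed reaction fields,
    maps MedDRA preferred terms to system organ classes, classifies drugs
    by chemical subgroup and marketing era, builds 2x2 contingency tables,
    and computes reporting odds ratios (ROR), proportional reporting
    ratios (PRR), Woolf confidence intervals, Pearson chi-square tests and
    the EMA signal-of-disproportionate-reporting (SDR) criteria. Includes
    composable scan stages (per-SOC, seriousness, outcome, SUDEP,
    demographics), a seeded synthetic ICSR generator with planted
    drug-event odds ratios, an exact margin replicator for fixture
    construction, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
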