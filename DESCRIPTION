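Package: litquery
Title: Literature-Alert-Driven Re-Query of Clinical Exome Variant Stores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted reanalysis engine for clinical exome databases. Gene
    alerts derived from prospective literature monitoring drive whole-word
    queries over a heterogeneous store of per-sample annotated variant tables
    produced by multiple pipeline versions. Hits are deduplicated to the most
    recent analysis, harmonized onto a master annotation schema, filtered for
    rarity (population allele frequency below 1 percent), matched against the
    variant class and inheritance mode reported for the alert, classified
    under the ACMG-AMP combining rules, and summarized into diagnostic-yield
    reports. Includes a synthetic store generator with planted ground truth
    and curated example data from a diagnostic exome reanalysis programme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
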