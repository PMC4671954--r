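Package: cernadel
Title: Competing Endogenous RNA Analysis of Genomic Deletion Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A deletion-wide competing endogenous RNA (ceRNA) screen for
    interstitial deletion syndromes, modelled on the 5q- myelodysplastic
    syndrome. Calls haploinsufficient genes inside a commonly deleted
    region by two-group Student's t-tests (from raw expression matrices or
    from published per-group summary statistics), ranks microRNAs putatively
    released by the loss of their in-region targets, intersects the
    genome-wide targets of the released microRNAs to nominate out-of-region
    ceRNA candidate genes, and validates candidates by differential
    expression. Ships a seeded synthetic-data generator with planted
    deletion effects, released microRNAs and ceRNA genes so the whole
    pipeline can be exercised and benchmarked without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
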