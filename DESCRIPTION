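Package: strainshare
Title: Strain-Level Gut Microbiome Transmission Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects strain sharing between gut metagenome samples from
    single-nucleotide-variant (SNV) profiles using an allele-incidence
    likelihood score (P_raw = L_obs/L_min, z-standardized to the
    transmission score S_T), and calls transmission events between
    cohoused hosts and between foregut and hindgut of the same animal.
    Also provides the surrounding genome-catalog computations: MAG
    quality scoring and tiering, greedy dereplication and novelty
    classification on average-nucleotide-identity tables, CPM and
    median-CPM abundance, Bray-Curtis/PERMANOVA community statistics,
    and a synthetic-study generator with planted transmission events
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
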