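Package: coarsetraits
Title: Coarse-Grained Proteomic Traits from Metaproteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers coarse-grained proteomic traits of microbial taxa from
    peptide-level metaproteomic intensity tables: ribosomal and photosynthetic
    proteomic mass fractions, filter-size-weighted combination of estimates
    from size-fractionated samples, taxon relative abundance, and an
    environment-independent (regulatory-cost proxy) proteome fraction
    classified by peptide coefficients of variation against a
    replicate-culture-derived cutoff. Includes a synthetic multi-taxon
    metaproteome generator and a data-dependent acquisition (top-N with
    dynamic exclusion) mass-spectrometry sampling simulator for quantifying
    the bias that limited peptide sequence diversity imposes on coarse-grained
    quantification, plus a cofragmentation-risk score based on precursor
    isolation windows and predicted retention times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
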