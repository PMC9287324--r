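Package: hybridtrace
Title: Hybrid Detection from Additive ITS Polymorphisms and Plastid Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects interspecific hybrids of aquatic Ranunculus (sect.
    Batrachium) from additive IUPAC polymorphisms in directly sequenced
    nuclear ITS, infers parental species pairs (including complex
    multi-parent hybrids and heterozygous single-base indel superposition
    in Sanger consensus reads), orients each cross as maternal x paternal
    from maternally inherited plastid haplotypes (rpl32-trnL, petL-psbE),
    and computes regional hybrid-frequency and crossing-direction
    statistics. Includes a seedable synthetic-data generator emulating
    parental ribotype panels, F1 and three-way hybrid consensus sequences,
    ambiguity-dropout noise, and maternal plastid inheritance, so the whole
    pipeline is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
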