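Package: ltrdyn
Title: Comparative Dynamics of LTR Retrotransposon Insertions Between Two Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the evolutionary dynamics of long terminal repeat
    (LTR) retrotransposons between two closely related genome assemblies and
    across resequenced cultivar cohorts. Provides structural filtering and
    Copia/Gypsy classification of candidate LTR elements, insertion dating from
    the Kimura two-parameter divergence of the two LTRs of each element,
    cross-species family clustering under the 80/80 rule, flank-anchored
    detection of orthologous insertion loci with conserved / lineage-specific /
    partially-deleted calls, fixed-versus-polymorphic classification of
    reference insertions from cohort deletion calls, structural-variant to TE
    association, and a fully reproducible two-genome evolution simulator with
    ground-truth ledgers that underpins the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
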