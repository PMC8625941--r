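Package: srnaends
Title: Differential RNA End Mapping and Maturation Analysis of UTR-Derived Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the maturation of bacterial small regulatory RNAs
    (sRNAs) that are released from mRNA untranslated regions. The package calls
    differential RNA 5'/3' ends between wild-type and ribonuclease-mutant
    sequencing libraries from strand-specific per-position end-count tracks,
    classifies sRNAs by genomic origin (5' UTR, 3' UTR, orphan) against
    predicted UTRs, assigns end-generation mechanisms (transcription start
    sites, Rho-independent terminators, RNase E / RNase III / PNPase cleavage
    or pausing sites) by strand-aware window queries, and quantifies
    condition-dependent processing from densitometry and reporter-fluorescence
    tables (loading-control normalization, mature/precursor ratios, log2 fold
    changes, trend classes, Student's t tests). A fully seeded synthetic-data
    generator produces annotations, end-count tracks and signal tables with
    known ground truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
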