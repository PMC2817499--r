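Package: rlgsim
Title: Virtual Restriction Landmark Genome Scanning and Methylation Inheritance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Methylation-aware in silico restriction landmark genome scanning
    (RLGS). Scans genomes for NotI landmarks and simulates the sequential
    NotI-MspI/HpaII-BamHI digestions that underlie two-dimensional RLGS gels,
    honouring the differential methylation sensitivity of the MspI/HpaII
    isoschizomer pair. Synthesizes diploid two-dimensional spot patterns with
    copy-number intensities, matches and compares patterns to call CpG
    methylation from [MspI] versus [HpaII] differences, and tests per-locus
    segregation of spot classes across F1 and selfed progeny panels to flag
    non-Mendelian inheritance of DNA methylation. Includes a synthetic-data
    generator that plants restriction-site cassettes and epialleles in random
    genomes and simulates crosses under Mendelian and
    methylation-maintenance transmission models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    BiocGenerics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
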