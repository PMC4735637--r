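Package: introscan
Title: Introgression Mapping and Balancing-Selection Scans for Pool-Seq and
    Haplotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map a Mendelian locus by introgression pool-sequencing
    and to characterise ancient balanced polymorphism at the mapped region.
    Implements diagnostic-SNP ancestry-proportion mapping with windowed
    averaging and identity-by-descent filtering, per-SNP Dxy with SNP-indexed
    sliding windows, HKA-like polymorphism/divergence scans and locus-level
    contingency tests, haplogroup clustering with Hudson FST, fixed-difference
    and incomplete-lineage-sorting statistics, and calibrated distance-based
    divergence dating with site bootstraps. A seeded simulator generates
    backcross introgression designs, pooled sequencing counts and balanced
    two-haplogroup locus alignments so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
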