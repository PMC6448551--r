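Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and Selection Scans from
    SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in diploid SNP genotypes with
    a sliding-window caller, derives pedigree (FPED), ROH-based (FROH by
    length class) and SNP-by-SNP (FSNP1-3) inbreeding coefficients, locates
    ROH islands and cold-spots from per-SNP ROH incidence, computes extended
    haplotype homozygosity (EHH) and standardized iHS selection scores from
    phased haplotypes, and estimates historical effective population size
    from distance-binned linkage disequilibrium. Ships a gene-dropping
    pedigree simulator with tracked identity-by-descent tracts so every stage
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
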