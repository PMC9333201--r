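Package: pgxstar
Title: Copy-Number-Aware Star-Allele Genotyping for Targeted
    Pharmacogenomic Sequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Star-allele diplotype calling for pharmacogenes from targeted or
    whole-genome sequencing data. Reads multi-sample variant tables and
    per-base depth-of-coverage profiles, converts depth to copy number by
    control-gene (intra-sample) and cohort (inter-sample) normalization,
    classifies structural variants (whole-gene deletions, duplications,
    multiplications, and gene-pseudogene hybrids) with a one-vs-rest linear
    support vector machine over binned copy-number profiles, matches phased
    haplotypes to star-allele translation tables, disambiguates copy
    configurations with allelic-depth fractions, and translates diplotypes to
    CPIC phenotypes via activity scores or diplotype-to-phenotype maps.
    Includes genotype- and diplotype-level concordance reports for panel
    validation and a synthetic-data generator for capture depth, allelic
    depths, and labeled structural-variant training cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
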