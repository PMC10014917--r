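Package: phasestar
Title: Phasing-Aware Star-Allele Assignment and Tool Concordance for CYP2C19
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns CYP2C19 star-allele diplotypes from phased VCF genotypes
    against a PharmVar-like allele-definition table, resolving suballeles via
    read-backed phase sets, flagging candidate novel suballeles carried in cis
    with known haplotypes, and translating diplotypes to CPIC/DPWG metabolizer
    phenotypes. Includes per-sample phasing statistics, cohort variant
    characterization (known/novel flagging, singletons, CADD impact classes),
    multi-caller diplotype concordance at minor/major/any-listed/phenotype
    levels, and a reproducible synthetic phased-VCF cohort generator for
    testing every stage without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
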