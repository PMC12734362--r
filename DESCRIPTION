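Package: cpgpgx
Title: Screening Variants that Disrupt or Form CpG Dinucleotides with
    Pharmacogenomic Significance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies CpG-PGx SNPs: genetic variants that destroy or
    create a CpG dinucleotide in their local sequence context and at the
    same time carry a significant pharmacogenomic (variant-drug) or
    genome-wide-significant GWAS association.  Provides a local-haplotype
    CpG delta classifier for SNVs and indels, two screening pathways
    (PharmGKB-style annotation tables and GWAS-catalog-style association
    tables), per-gene and per-function tallies, minor-allele-frequency
    prioritisation, a multi-factor hub-gene comparison, packaged
    reference tables from the originating screen, and seeded synthetic
    data generators with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
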