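Package: zwgwas
Title: Mixed-Model Genome Scans and Transmission Genetics for Sex
    Reversal in ZW Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to dissect the genetic architecture of female-to-male
    sex reversal in ZW-chromosome fish such as the Chinese tongue sole.
    Provides a forward simulator of ZW family populations with hemizygous
    Z/W genotype coding and pseudomale sires that transmit only Z gametes;
    genotype QC (minor-allele-frequency and call-rate filters) and
    linkage-disequilibrium imputation of missing calls; a realized genomic
    relationship matrix; an EMMAX-style binary-trait linear mixed-model
    genome scan with REML variance components, Cholesky whitening,
    upcrossing-based genome-wide significance thresholds and peak support
    intervals; two-locus epistatic penetrance classification with
    offspring sex-ratio tests under a no-W-sperm transmission model; and a
    Dmrt1 polymorphism panel for haplotype matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
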