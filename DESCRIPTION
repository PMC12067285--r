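Package: hgtscreen
Title: Detection, Validation and Dating of Horizontal Nuclear DNA Transfer
    in Transmissible Cancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a screen for host-to-tumor horizontal transfer of
    nuclear DNA in clonally transmissible cancers such as the canine
    transmissible venereal tumor (CTVT). Provides purity-corrected variant
    allele fraction genotyping against local copy number, a flipping-SNP
    screen with robust outlier detection over genomic windows, hallmark
    validation of candidate regions (integer copy-number step, somatic VAF
    dosage pattern, per-copy mutation-density deficit), breakpoint-junction
    chain assembly of the transferred element, CpG C>T molecular-clock
    dating by parental-count subtraction, donor-haplotype inference from
    allele-count subtraction, and allelic deconvolution of expression into
    transferred, cancer-parental and host sources. A synthetic cohort
    generator with full ground truth makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
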