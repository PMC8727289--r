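Package: epiMRD
Title: Measurable Residual Disease Estimation from DNA Methylation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to estimate measurable residual disease (MRD) in acute
    myeloid leukemia from DNA methylation. Selects AML-associated CpGs from
    Illumina 450k-style beta-value matrices, combines four anchor CpGs into
    an AML-score with a control-percentile cutoff, and detects anomalous
    per-read methylation patterns in bisulfite amplicon sequencing data with
    a depth-limited random forest and with per-cluster autoencoders using
    reconstruction-error thresholds. Includes allele-symmetry analysis at
    heterozygous SNPs, an in-silico limiting-dilution sensitivity harness,
    and synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ranger,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
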