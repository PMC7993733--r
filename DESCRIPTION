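Package: ampage
Title: Targeted Bisulfite Amplicon Methylation Quantification and Epigenetic Age Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies per-CpG DNA methylation (percent beta values) from
    targeted bisulfite amplicon sequencing reads for an eight-marker, 44-CpG
    forensic age panel, with the associated quality-control metrics (bisulfite
    conversion efficiency, misincorporation rate, normalized read depth, read
    depth thresholds). Trains and evaluates tissue-specific epigenetic
    age-prediction models (blood, buccal cells, bones) by univariate screening,
    power transformation of non-linear markers, and stepwise multivariable
    linear regression, and tests equivalence between assays via joint
    slope/intercept regression tests. A synthetic cohort and read generator
    emulating age-dependent methylation, duplicate measurement noise,
    marker-specific PCR bias, amplicon depth imbalance and input-DNA dilution
    makes every stage testable without external data.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Encoding: UTF-8
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
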