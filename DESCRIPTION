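Package: methylSERS
Title: Gene Methylation Quantification from PCR-SERS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for quantifying gene promoter methylation
    from surface-enhanced Raman spectra (SERS) of bisulfite-PCR products.
    Models bisulfite conversion and PCR to derive the per-amplicon linear map
    between methylation level and CG base-pair fraction, preprocesses Raman
    spectra (Savitzky-Golay smoothing, asymmetric least squares baseline
    correction, normalization), unmixes sample spectra into dsCG/dsAT
    reference components by multiple linear regression, converts fitted
    coefficients into methylation-level estimates, and evaluates verification
    sets and simulated clinical cohorts with Bland-Altman agreement, ROC with
    Youden-optimal cutoffs, CART decision trees, and Fisher's exact tests.
    Includes a synthetic spectrum and cohort generator that stands in for the
    Raman instrument so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rpart
Config/testthat/edition: 3
RoxygenNote: 7.3.3
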