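Package: breathdisc
Title: Discrimination Analysis of Untargeted Breathomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end chemometric workflow for two-group discrimination of
    untargeted LC-MS exhaled-breath-condensate feature tables: quality-control
    based feature filtering, stochastic missing-value imputation, probabilistic
    quotient normalization, log transformation and centering; per-feature
    nonparametric screening with Benjamini-Hochberg false-discovery-rate
    control; PCA-based outlier screening (Hotelling T2 and Q statistics);
    PLS-DA with VIP-ranked bootstrap stability selection, out-of-bag and
    cross-validated Matthews correlation, permutation testing and model
    post-transformation; a multilevel (paired) PLS-DA variant for
    before/after designs; and putative metabolite annotation by
    adduct-corrected neutral-mass lookup. Includes a synthetic study
    generator with planted group effects for validation of the whole
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
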