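Package: codasig
Title: Sparse Log-Ratio Signatures for Cross-Sectional and Longitudinal
    Microbiome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of sparse, predictive microbial signatures from
    compositional microbiome data. Variable selection is performed by
    cross-validated elastic-net penalized regression on the all-pairs
    log-ratio model, and the selected pairs are collapsed to a zero-sum
    log-contrast (a weighted balance between two groups of taxa). For
    longitudinal studies the same machinery is applied to integrals of
    pairwise log-ratio trajectories over a time window. Includes a
    template-based case-control read-count simulator, a stratified
    cross-validation benchmarking harness with a differential-abundance
    baseline, delimited-text readers, and plots of the penalization path,
    the signature, the predictions and the signature trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    glmnet,
    ggplot2,
    patchwork,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
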