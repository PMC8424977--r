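Package: marrqc
Title: Maximum Rank Reproducibility Assessment for Mass Spectrometry
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rank-based assessment of replicate concordance in mass
    spectrometry metabolomics experiments. Implements the maximum rank
    reproducibility (MaRR) procedure: a nonparametric estimator of the
    proportion of reproducible metabolites between replicate experiments,
    with classification of individual metabolites under marginal false
    discovery rate control. Supports hierarchical (multi-layer) replicate
    designs through pairwise comparison and abundance pooling, provides
    the standard metabolomics preprocessing steps (missing-value
    filtering, k-nearest-neighbour imputation, quantile/median/run-day
    normalization, log transformation, outlier-sample removal),
    data-driven filtering of reproducible metabolites and sample pairs,
    a relative standard deviation (RSD) baseline for comparison, and
    simulation generators with known ground truth for operating
    characteristic studies (FDR, discriminative power, bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    limma,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
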