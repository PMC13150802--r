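Package: sensortrim
Title: Minimal Sensor-Array Selection for Analyte Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Supervised backward-elimination wrapper that reduces a
    cross-reactive chemical sensor array to a minimal subset while
    preserving analyte-class separability under few replicates per class.
    Fits per-class Gaussians in a principal-component plane with
    finite-sample predictive variance inflation, Ledoit-Wolf-style
    shrinkage toward the pooled covariance and eigenvalue conditioning;
    builds quadratic discriminant (QDA) or nearest-centroid (Voronoi)
    decision regions; estimates per-class misclassification by Monte
    Carlo integration of each class Gaussian over its own decision
    region; ranks sensors by Pearson chi-squared between decision-aware
    discretized readings and class labels (uniform or pairwise-weighted);
    and selects a working sensor count by minimizing an explicit
    error-versus-array-size cost. Includes a synthetic screening-data
    generator and variance-inflation stress protocol so the whole
    pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
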