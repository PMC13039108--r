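Package: locusmotion
Title: Single-Locus Chromatin Motion Analysis from Tracking or Synthetic Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying the mobility of fluorescently labelled
    genomic loci from 2D time-lapse microscopy. Provides exact simulation of
    fractional Brownian motion trajectories with localization noise and drift,
    rendering of synthetic image stacks with Gaussian point-spread functions,
    spot detection (Laplacian-of-Gaussian and Hessian detectors), subpixel
    refinement by bounded 2D Gaussian fitting, linear-assignment-problem track
    linking with gap closing, time-averaged and ensemble mean-squared-
    displacement analysis yielding the anomalous exponent and generalized
    diffusion coefficient, fractional-Brownian-motion diagnostics (velocity
    autocorrelation, displacement Gaussianity), a PCA minor-axis control for
    substrate drift, and population statistics (Kruskal-Wallis with Dunn's
    post hoc comparisons, Hartigan's dip test for multimodality).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    tiff,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
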