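Package: suturemetrics
Title: Quantifying Cranial Suture Complexity from Open-Curve Semi-Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for comparative analysis of cranial suture morphology from
    two-dimensional open-curve semi-landmarks. Reads TPS and CSV landmark files,
    resamples outlines to equidistant semi-landmarks, performs generalized
    Procrustes superimposition, extracts signed chord-deviation signals, and
    computes five complexity metrics per suture: sinuosity index, suture
    complexity index, fractal dimension by box counting and by madogram, and a
    windowed short-time Fourier transform power spectral density score. Includes
    principal component analysis of shapes and of complexity scores, Pearson
    correlation reports, heatmap binning, a parametrized synthetic suture
    generator spanning straight to looping morphologies, and an end-to-end
    pipeline with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
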