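Package: thzamino
Title: Terahertz Time-Domain Spectral Simulation and Amino-Acid
    Classification with an Efficient-Channel-Attention CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Physics-based simulation of terahertz time-domain
    spectroscopy (THz-TDS) measurements of pressed amino-acid tablets
    (Lorentz-oscillator material models, etalon echoes,
    averaging-dependent noise); extraction of the refractive index and
    absorption rate from sample/reference trace pairs via the slab
    transfer function; sym4 wavelet-shrinkage denoising; hybrid Nx2
    absorption/refractive-index feature maps with PCA diagnostics; and a
    compact convolutional classifier with efficient channel attention
    (ECA), trained by SGD with Nesterov momentum, together with
    confusion-matrix metrics and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
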