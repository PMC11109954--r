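Package: mcdda
Title: Monte Carlo Diffusion Distribution Analysis of CRISPR-Cas Target
    Search Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intracellular target search of CRISPR-Cas
    nucleases from single-particle tracking (sptPALM) data. Simulates short
    single-molecule tracks of particles switching among 3D-diffusing,
    1D-sliding, PAM-investigating and target-bound states inside a
    spherocylindrical bacterial cell; estimates apparent diffusion
    coefficients and their logarithmically binned histograms; fits kinetic
    rates to such histograms with a Levenberg-Marquardt procedure driven by
    the stochastic forward model (MC-DDA) with bootstrap confidence
    intervals; computes non-target interaction times in closed form with
    uncertainty propagation; and predicts target-finding times and
    target-bound fractions under varying PAM densities and genome GC
    content.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    minpack.lm,
    Biostrings,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
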