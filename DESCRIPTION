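Package: mrnpmotility
Title: Simulation and Quantitative Analysis of Single-Molecule mRNP Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of single-molecule motility
    recordings of dynein-driven messenger ribonucleoprotein (mRNP) transport
    along microtubules. Provides a stochastic simulator of labeled motor
    complexes landing on microtubules and moving processively (Gaussian
    class-conditional speeds, exponential run lengths, Poisson landing,
    frame-sampled positions with localization noise), per-run trajectory
    statistics (speed by least-squares slope, net run length, color
    classification, normalized run frequency), Gaussian-mixture speed fitting
    with BIC model selection, truncated-exponential run-length fitting,
    two-sample comparisons, a two-color copy-number (stoichiometry)
    correction with bootstrap uncertainty, and coiled-coil contour-length
    arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
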