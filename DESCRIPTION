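Package: carnichron
Title: Chronometric Analysis of Carnivore Death Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the temporal structure of sparse,
    time-averaged vertebrate death assemblages from radiocarbon dates.
    Implements intercept-free probabilistic calibration against tabulated
    calibration curves with highest-posterior-density intervals and
    modern/beyond-range screening; summed probability distributions (SPDs)
    with site-wise binning against pseudo-replication; Monte Carlo
    mark-permutation tests of SPD shape with simulation envelopes, local
    deviation intervals and a global significance statistic; minimum number
    of individuals (MNI) clustering from overlapping calibrated intervals;
    first/last appearance summaries; and convex-hull quantification of
    settlement occupation area with ordinal intensity classes. A synthetic
    assemblage generator with piecewise-constant deposition intensities
    supports power and calibration experiments for the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
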