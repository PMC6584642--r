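Package: cellcaliber
Title: Maximum-Caliber Behavioral Signatures for Migrating Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies the migratory behavior of single cells from time
    series of binary masks or shape trajectories. Cell outlines are encoded
    as rotation- and flip-invariant Fourier power spectra, reduced to
    principal shape components, and discretized into unit-step event
    streams. A maximum-caliber (dynamical maximum-entropy) model over
    two-time-step microtrajectories is fitted to the observed simple and
    time-correlated event rates, yielding a 14-value Lagrange-multiplier
    signature per condition. Includes correlated and uncorrelated
    trajectory simulators, Markovian and nine-memory-state Gillespie
    simulations, long-horizon pattern statistics with Jensen-Shannon
    divergence, bootstrap signature distributions, and k-nearest-neighbor
    classification of conditions from shapes versus behavioral signatures.
    A synthetic-data generator provides shape movies and trajectories with
    known ground truth at every pipeline level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    tiff,
    png,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
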