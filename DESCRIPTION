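Package: circanet
Title: Circadian Cycling Detection and Network Phase Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Replicated harmonic-regression detection of 24-hour cycling genes
    in bulk RNA-seq time courses, circular phase statistics (circular means,
    circular correlation, von Mises kernel density peaks, paired phase shifts),
    and a permutation test for phase organization of cycling genes on a gene
    interaction network (median phase difference as a function of geodesic
    distance against a random-placement null). Includes a synthetic-data
    generator producing networks, planted phase configurations and noisy
    two-experiment TPM time courses with known ground truth, so the full
    pipeline can be exercised and calibrated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
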