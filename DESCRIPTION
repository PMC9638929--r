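Package: polyprof
Title: Modelled Polysome Profiles from Ribosome Footprinting Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs theoretical polysome profiles from ribosome
    footprinting (Ribo-Seq) and RNA-Seq count data, fits experimental
    sucrose-gradient absorbance traces as location-constrained Gaussian
    mixtures with debris and baseline components, and scores dataset
    integrity by comparing modelled and reference profiles using
    root-mean-square deviations, normal-null P-values, and hierarchical
    clustering with Davies-Bouldin cluster-number selection.  Includes a
    synthetic-data generator for traces and count tables with known
    ground truth, and a command-line interface over the main workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
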