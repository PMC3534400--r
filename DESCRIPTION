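Package: hurdlecall
Title: Probabilistic Base-Calling for Flow-Cycle Pyrosequencing with a
    Weighted Hurdle Poisson Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Base-calling for flow-cycle (454-style) pyrosequencing data.
    Per-flow homopolymer lengths are modelled with a two-part hurdle model:
    a logistic additive model separates empty from productive flows, and a
    zero-truncated exponentially weighted Poisson additive model captures
    the underdispersed positive homopolymer counts. Both parts are fitted
    by penalized iteratively reweighted least squares on cubic B-spline
    bases, with the global dispersion weight estimated by profile
    likelihood. The fitted model yields a discrete probability distribution
    over homopolymer lengths in every flow; reads are called by maximum
    probability and accompanied by Phred-like overcall scores plus signed
    quality scores that indicate whether an undercall or an overcall is the
    likelier error. Includes a flow-data simulator, readers and writers for
    flow tables, FASTA/FASTQ and probability sidecars, accuracy and
    quality-score calibration metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    Biostrings
Suggests:
    mgcv,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
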