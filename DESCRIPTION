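Package: cequant
Title: Quantification of High-Throughput Capillary Electrophoresis Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable pipeline for chemical-probing capillary
    electrophoresis (CE) data: reads multi-channel ABIF (.ab1/.fsa)
    sequencer traces organised in batches, detects the informative region,
    removes constant and smooth baselines, aligns lanes by correlation-
    maximising linear fits plus dynamic-programming piecewise-linear
    refinement, maps bands to residues of the probed nucleic-acid sequence
    using reagent-specific reactivity priors, quantifies band areas by
    non-negative least-squares Gaussian deconvolution, and exports
    residue-by-lane reactivity tables as TSV and RDAT. Includes a
    synthetic-electropherogram generator with full ground truth and a
    gel-style renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    pracma,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
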