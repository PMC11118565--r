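Package: limrepair
Title: Quantification of LIM-Protein Assemblies and Actin Repair from
    Fluorescence Time-Lapse Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis toolkit for in vitro reconstitution studies of
    mechanosensitive LIM-domain proteins (zyxin and relatives) on F-actin.
    Detects and tracks LIM-protein assemblies in multi-channel TIRF
    time-lapse movies, classifies them by actin-overlap topology
    (actin-bound patch, bridge, tail), quantifies lifetimes, lengths and
    local-background enrichment, measures partner-protein (VASP,
    alpha-actinin) binding events and colocalization, segments
    biomolecular condensates and extracts FRAP recovery traces, and
    quantifies contractile-bundle thickness and strain-site repair from
    kymographs. Ships a synthetic-movie generator that plants known
    ground truth (object classes, blink gaps, enrichment ratios,
    photobleaching, recovery paths) so every pipeline stage can be
    validated without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    igraph,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
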