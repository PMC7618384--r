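Package: perivquant
Title: Perivascular Cell Quantification and Signalling Analysis for
    Cleared-Nerve Fluorescence Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cleared peripheral-nerve fluorescence volumes
    (FITC-filled vessel lumens, tdTomato-labelled Pdgfrb-lineage cells,
    DAPI nuclei) with exact ground truth, and quantifies them with the
    vessel-proximity classification used in cleared-tissue confocal
    studies: automatic (IsoData) and cross-channel thresholding, vessel
    mask broadening, per-plane nucleus segmentation, area filtering and
    mask-overlap counting of mural versus other Pdgfrb+ stromal cells.
    Includes the accompanying nonparametric statistics (exact and
    asymptotic Mann-Whitney, tie-corrected Kruskal-Wallis, Dunn post hoc,
    Monte-Carlo minimum-detectable-effect sensitivity analysis) and a
    ligand-receptor communication-score analysis matching injury-regulated
    sender genes against multi-subunit receptor expression in sensory
    neuron populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
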