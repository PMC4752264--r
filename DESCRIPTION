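Package: penumbra
Title: Spike-Train Analysis of Cultured Cortical Networks Under Hypoxia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-electrode-array (MEA) recordings of
    cultured cortical networks exposed to controlled hypoxia, an in vitro
    model of the ischemic penumbra. Implements spike detection by a
    noise-scaled amplitude threshold with waveform cutouts, array-wide
    firing rate on the experiment timeline, functional connectivity by
    conditional firing probability (strengths, latencies, connection counts
    and similarity indices between data blocks), action-potential shape
    integrity tracking on single-neuron electrodes, excitatory/inhibitory
    classification by the Fano factor of 6-second spike counts, and
    quantification of synaptically mediated stimulus responses (area under
    the post-stimulus response curve, 15-150 ms). A ground-truth-annotated
    synthetic recording generator (conditionally Poisson coupled units with
    a parameterized hypoxia protocol) makes every stage verifiable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
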