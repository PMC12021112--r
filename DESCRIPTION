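Package: hippomap
Title: Electroanatomical Mapping from Dense Multi-Shank Extracellular Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-dimensional multi-shank dense
    extracellular recordings of the hippocampal circuit: sharp-wave-ripple
    and dentate-spike detection, event-triggered LFP averages and
    one-dimensional current source density maps, waveform- and
    spike-train-based cell-type classification, quantification of
    extracellular action-potential backpropagation, and spike-LFP gamma
    phase-locking and coherence maps across the probe lattice. Includes a
    ground-truthed synthetic-recording generator emulating an 8-shank
    1024-channel probe so that every stage can be validated without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
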