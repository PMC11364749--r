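Package: pulsesort
Title: Label-Free Cell Sorting on Multi-Angle Scattered-Light Pulse Shapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis pipeline for pulse-shape flow cytometry
    with cluster-based, label-free sorting. Generates multi-channel
    scattered-light transit pulses with known population structure, extracts
    Haar wavelet coefficient features (5 per channel from 80-sample windows)
    alongside conventional area/height/width parameters, fits per-channel
    k-means models in coefficient space, enumerates cross-channel conjunction
    sort clusters ranked by an enrichment statistic, and runs a discrete-event
    virtual catcher-tube sorter with coincidence co-sorting, refractory rate
    limiting, and purity re-analysis. Includes readers and writers for pulse
    and wavelet binaries, FCS 3.0/3.1 list-mode files, centroid tables, and
    event-index files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
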