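Package: segclock
Title: Delay-Differential Lattice Model of the Zebrafish Somite Segmentation Clock
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of the zebrafish presomitic-mesoderm gene
    regulatory network linking the her/deltaC segmentation clock to the
    rostrocaudal patterning genes mespa, mespb, ripply and tbx6. The tissue is
    a 4 x 50 hexagonal cell lattice; per-cell gene expression follows
    time-delayed differential equations with juxtacrine Delta/Notch coupling
    and static cell-to-cell rate variability. Includes declarative
    time-windowed perturbation protocols (Notch mutant, DAPT, heat-shock
    overexpression), oscillation and stripe-pattern metrics (period,
    amplitude, synchronization index, stripe geometry, her/mesp
    complementarity), synthetic ground-truth fixtures for metric validation,
    and a harness of in-silico experiments with qualitative verdicts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
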