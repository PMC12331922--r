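Package: stagdia
Title: Staggered-Window DIA Acquisition Design, Demultiplexing and
    Chromatogram-Library Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for data-independent acquisition (DIA) proteomics
    built around staggered isolation windows. Designs staggered-window
    cycles with forbidden-zone boundary snapping, gas-phase fractionation
    (GPF) plans and offline high-pH fraction concatenation schemes;
    demultiplexes overlapped staggered windows onto half-width bins by
    non-negative least squares with cross-cycle interpolation; simulates
    ground-truthed DIA runs and two-group study designs; assembles and
    calibrates ion-chromatogram libraries (fraction-based and hybrid)
    with target-decoy FDR control; performs MS2-level normalization,
    top-3 roll-up quantification and the differential-expression filter
    cascade; and computes library-comparison metrics (completeness,
    library recovery, explained TIC, CV distributions, peptide
    physicochemical properties, overlap sets and rank/correlation
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
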