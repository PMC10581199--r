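Package: cstransfer
Title: Chemical Shift Transfer for Automated Protein NMR Resonance Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers assigned chemical shifts from a source protein onto a
    homologous target via local sequence alignment, builds per-atom assignment
    search spaces with database-statistics fallback, runs a simplified
    replicate-consensus combinatorial assignment engine on HSQC/NOESY peak
    lists, and evaluates assignment accuracy. Includes the random and
    structure-based chemical-shift perturbation generators used to benchmark
    shift transfer under controlled source/target divergence, and a peak-list
    simulator for desk-scale synthetic experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
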