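Package: trnaip
Title: Kinetic Modeling and Interference Analysis for Time-Resolved
    Nucleotide Analog Probing of Ring-Translocase Helicases
Version: 0.1.0
Authors@R:
    person("trnaip", "developers", email = "trnaip-dev@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the translocation cycle of ring-shaped
    RNA helicases (such as the bacterial transcription terminator Rho) from
    nucleotide analog interference experiments. Provides a deterministic
    sequential-step kinetic model of single-run duplex unwinding with
    competing dissociation, a synthetic sequencing-gel data generator
    emulating time-resolved nucleotide analog interference probing (trNAIP)
    and endpoint interference mapping (NAIM) experiments, per-position
    single-exponential amplitude/rate profiling with control-based
    significance calls, normalized lambda interference factors with cluster
    and autocorrelation periodicity analysis, and a small command-line
    workflow tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
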