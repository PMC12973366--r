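Package: ultraplex
Title: Orthogonal-Protease Isobaric Hyperplexing: Design, Simulation and
    Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and benchmarking hyperplexed isobaric
    (TMT/TMTpro) proteomics experiments that multiply sample capacity by
    combining parallel orthogonal protease digests (LysC and lysine-blocked
    "TrypR" trypsin). Provides in silico digestion with cleavage-specificity
    classification and labeled-peptide mass/charge computation, precursor
    orthogonality assessment, plex-design construction and validation with
    bridge channels and two-proteome spike-ins, a reporter-ion quantification
    simulator with an explicit coisolation-interference model separating
    MS2-like and MS3-like acquisition, the bridge-anchored normalization and
    integration chain (median normalization, log2, bridge scaling, global
    centering, MAD harmonization), and QC metrics (missed-cleavage rates,
    specificity profiles, labeling efficiency, protein CVs, subplex overlap,
    spike-in accuracy and ratio-compression summaries).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
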