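Package: pilusmech
Title: Structural and Mechanical Analysis of Type IV Pilus Filaments
Version: 0.1.0
Authors@R: person("Pilusmech", "Developers", email = "pilusmech@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of type IVa pilus (T4aP)
    filaments and their major pilin subunits: construction of helical filament
    models from (twist, rise) symmetry parameters and an asymmetric unit;
    Shrake-Rupley solvent-accessible surface areas, buried subunit-interface
    areas per neighbour-offset class and cross-subunit salt bridges;
    worm-like-chain persistence-length estimation from digitized 2D filament
    traces; classification of AFM retraction force-distance curves into
    nanospring and constant-force-plateau signatures with spring-constant and
    rupture-force extraction; and a major-pilin sequence survey (class III
    signal-peptide detection, mature-length classification, identity
    clustering, taxon summaries and N-terminal consensus). Every analysis
    stage is paired with a deterministic synthetic-data generator so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
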