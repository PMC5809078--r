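Package: dnakink
Title: Detection and Analysis of Protein-Induced DNA Kinks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coordinate-level analysis of protein-induced DNA kinks in
    crystal structures and snapshot ensembles. Detects Watson-Crick base
    pairs, assembles and curates B-DNA duplexes (dangling-end trimming,
    base flip-out flagging, multi-duplex handling), fits standard base
    reference frames, computes the six rigid-body base-pair-step
    parameters, calls kinks from roll profiles (roll > 35 degrees by
    default), identifies fully and partially intercalating protein
    sidechains at kinked steps, truncates sidechains to build alanine or
    glycine mutants, and summarises snapshot ensembles as roll time
    courses, average profiles, Gaussian histogram fits and a three-way
    conformational-stability classification. Includes an exact B-DNA
    coordinate generator (the inverse of the step-parameter measurement)
    so that every stage is verifiable by round-trip recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
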