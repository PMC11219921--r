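Package: y1hscan
Title: Fitness Scoring and Clinical Evidence Calibration for Barcoded
    Yeast One-Hybrid Deep Mutational Scans
Version: 0.1.0
Authors@R:
    person("HGU", "Computational Biology", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for deep mutational scanning of a
    transcription-factor DNA-binding domain read out by a barcoded yeast
    one-hybrid growth selection. Extracts fixed-position barcodes from
    FASTQ reads, builds filtered per-timepoint count tables, computes
    per-variant fitness scores by weighted log-ratio regression against a
    wild-type reference, assigns functional categories from dual
    (wild-type and nonsense) null hypotheses, relates scores to
    protein-DNA structural context (region, solvent accessibility, DNA
    distance), benchmarks scores against clinical labels (ROC), and
    calibrates scores into ACMG/AMP-style evidence strengths via dynamic
    oddsPath windows. Includes a synthetic-data generator that emulates
    the library structure, exponential competitive growth and multinomial
    sequencing noise of such experiments so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
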