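Package: adarkit
Title: Dissecting ADAR Substrate Specificity with Barcoded Hairpin Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing the positional rules of A-to-I RNA editing by
    ADAR enzymes. Designs barcoded hairpin reporter libraries carrying
    systematic structural perturbations (sliding mismatches, pyrimidine-rich
    bulges, opposite-base substitutions, random duplex disruptions), simulates
    amplicon sequencing reads under parameterized enzyme models with
    distance-dependent induction and suppression of editing, quantifies
    per-adenosine editing levels from paired reads, detects the fixed offsets
    at which structural disruptions induce editing (e.g. -26 nt for ADAR2,
    -35 nt for ADAR1) via delta-editing aggregation and LOESS smoothing,
    computes open-versus-closed structure metaplots for endogenous editing
    sites from dot-bracket secondary structures, and designs offset-aware
    ADAR-recruiting guide RNAs (arRNAs) with predicted off-target calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
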