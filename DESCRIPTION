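Package: naltorf
Title: Nested Alternative Open Reading Frames in Mitochondrial Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens mitochondrial coding sequences such as cytb for nested
    alternative open reading frames (nAltORFs) that would be read by the
    cytosolic machinery under the standard genetic code while the host gene is
    translated under the vertebrate mitochondrial code. Classifies the Kozak
    context of each nested start codon into four initiation-strength tiers,
    locates host-frame premature termination codons, and quantifies codon-usage
    adaptation of nested ORFs with the codon adaptation index (CAI) and its
    Monte-Carlo expected value (eCAI), the relative codon deoptimization index
    (RCDI/eRCDI), and RSCU-based cosine similarity against nuclear and
    mitochondrial reference codon-usage tables, with the paired nonparametric
    tests used to compare gene classes. A synthetic-data generator emits
    cytb-like hosts with planted nested ORFs and a ground-truth manifest so the
    whole pipeline is testable without any sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
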