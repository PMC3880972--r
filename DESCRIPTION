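Package: asmqc
Title: Reference-Guided Quality Evaluation of De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating de novo transcriptome assemblies against a
    reference protein set in the absence of a reference genome. Provides
    redundancy removal by 100%-identity (exact substring) clustering,
    assembly summary statistics (N50, length distributions), per-reference
    coverage with contiguity, completeness and percent-hits across
    coverage-threshold sweeps, alignment-anchored translate-and-extend ORF
    calling, seeded paired-read subsampling for sequencing-depth saturation
    analysis, library quality-control fractions (rRNA content,
    unique-start-site complexity), and a pentatricopeptide-repeat (PPR)
    gene census with reciprocal-best-hit ortholog detection. A synthetic
    fixture generator with exact ground truth makes the whole evaluation
    stack testable and runnable without external data or an aligner. A
    command-line entry point ('asmqc') wires the pieces into reproducible
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
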