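Package: bhlhscan
Title: Discovery and Classification of Basic Helix-Loop-Helix Transcription Factors
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide annotation of the basic helix-loop-helix (bHLH)
    transcription-factor family. Builds profile hidden Markov models from
    motif alignments and scans predicted proteomes for HLH domains with a
    local Viterbi search and empirical Gumbel E-value calibration; maps hits
    onto a canonical bHLH coordinate scheme (13-residue basic region, two
    helices, variable loop); predicts DNA-binding class (G-box, E-box,
    non-E-box binder, non-binding HLH) from basic-region residue rules;
    classifies intron patterns within the domain from GFF3 gene models;
    assigns subfamilies by distance to reference exemplars with
    neighbor-joining trees and diagnostic-motif corroboration; groups
    homeologous copies arising from whole-genome duplication; and
    categorizes tissue expression profiles. Includes a fully deterministic
    synthetic gene-family generator with ground-truth manifests so the
    entire pipeline is testable end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ape,
    Biostrings,
    rtracklayer,
    withr,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
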