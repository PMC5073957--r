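Package: chargescan
Title: Screening Protein Sequences for Statistically Significant Charge Clusters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proteome-wide detection of charge clusters: runs of positively
    (Lys/Arg) or negatively (Asp/Glu) charged residues whose local density is
    significantly higher than the background composition, found by an exact
    binomial upper-tail test on sliding windows, merged and trimmed to charged
    boundaries. Detected clusters are mapped relative to annotated functional
    domains (N-terminal, in-domain, interdomain, C-terminal), grouped when
    conserved across proteins, flagged as cell-penetrating-peptide candidates,
    and summarised with contingency, t, and ANOVA statistics. Includes a
    synthetic-proteome generator with planted ground truth for recovery
    benchmarking, and a command-line pipeline front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
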