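Package: ailqtl
Title: QTL Mapping and Candidate-Gene Prioritization for Advanced
    Intercross Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-marker quantitative trait locus (QTL) mapping for
    advanced intercross lines (AILs) descended from two inbred founder
    lines, with multiple-testing correction via the simpleM effective
    number of independent tests, 1.5-LOD-drop support intervals, genotype
    class effect estimation under selective genotyping (two-stage scan),
    pairwise causal modeling of pleiotropic QTL (independent vs
    causal/reactive trait architectures), microarray-style differential
    expression (quantile normalization, per-probe t-tests,
    Benjamini-Hochberg correction), and a decision-tree prioritization of
    positional candidate genes from variant-annotation categories,
    expression differences and pathway membership. Includes a forward
    simulator of AIL genotypes and phenotypes with planted direct and
    mediated QTL effects so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
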