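Package: hepnuc
Title: Ploidy-Resolved Single-Nucleus RNA-Seq Analysis of the Liver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of deep plate-based single-nucleus RNA-seq
    (Smart-seq style) of FACS ploidy-gated liver nuclei. Implements the ordered
    quality-control filter cascade, ERCC spike-in size factors and
    gene-length/coverage normalization, log transformation and optional
    empirical-Bayes batch correction, graph-based clustering with marker-panel
    cell-type annotation, ploidy contrasts (detected-gene fold, Welch
    differential expression with fold-change/Bonferroni call rules,
    Kolmogorov-Smirnov distribution-shift calls), per-gene coefficient-of-
    variation and highly-variable-gene analysis, binary Jaccard co-expression
    module detection for stem/progenitor markers, and diffusion-pseudotime
    zonation analysis (pericentral/periportal annotation, ploidy enrichment,
    binned profiles, zonation-by-ploidy intersections). Ships a synthetic-data
    generator that plants all of these effects with ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    Matrix,
    igraph,
    irlba,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
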