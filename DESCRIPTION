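Package: phylage
Title: Phylostratigraphic Gene-Age Dating with Homology Cutoffs,
    Microsynteny and Expression Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for dating the evolutionary origin of the
    genes in a signaling pathway. Homologs are called from tabular
    protein-BLAST output using a length-normalized bit score with
    species-specific cutoffs, orthology in vertebrates is confirmed by
    conservation of a ten-gene microsynteny window, and each gene is
    assigned to its earliest phylostratum on a twenty-stratum scale from
    cellular organisms to modern humans. Downstream helpers post-process
    branch-site selection tests (Benjamini-Hochberg correction and dN/dS
    classification), test gene-set tissue enrichment with the
    hypergeometric distribution, compare regional brain expression of a
    gene set against the whole-brain mean with one-sample t tests and
    Cohen's d, and score cross-donor expression reproducibility as
    differential stability. Synthetic-data generators with planted
    ground truth make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
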