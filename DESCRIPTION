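Package: chemoscreen
Title: Secretome Screening and Immune-Cell Migration Analysis for
    Tumor-Conditioned Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies immune-cell migration toward conditioned media from
    counting-bead flow-cytometry event tables, applies donor quality control
    and a mean-plus-2SD induction rule, screens Olink-style NPX secretome
    panels for proteins associated with dendritic-cell migration using
    Pearson correlation with Benjamini-Hochberg correction, selects candidate
    chemokines via a limit-of-detection presence contrast between cell-line
    and tumor-microenvironment secretomes, and scores gene-set signatures
    against immunotherapy response. Includes from-scratch exact nonparametric
    tests (Fisher, Mann-Whitney, Wilcoxon signed-rank, Kruskal-Wallis,
    Friedman, Dunn post hoc) and a synthetic-data generator emulating the
    study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
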