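Package: repevol
Title: Reproductive Protein Evolution from Codon Models and Expression Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for contrasting rates of protein evolution
    between reproductive and non-reproductive genes in a four-taxon Solanum
    phylogeny with mixed mating systems. Classifies genes from tissue-level
    TPM expression (reproductive, vegetative, general, tissue-specific and
    gametophytic/sporophytic classes), estimates dN/dS under Goldman-Yang
    codon substitution models (one-ratio and multi-ratio branch models fitted
    by maximum likelihood with Felsenstein pruning), and implements the
    comparison layer: gamma GLMs with identity link and single-step adjusted
    pairwise contrasts, chi-square and one-sided Fisher tests on the
    proportion of genes with dN/dS > 1, a bootstrap null distribution for the
    self-compatible minus self-incompatible rate difference, and
    expression-level regressions. Includes a ground-truthed simulator of
    codon alignments and RNA-seq count tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    multcomp,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
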