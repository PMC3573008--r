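Package: sexinvert
Title: Inverted Expression Profiles of Sex-Biased Genes Under
    Toxico-Pathological Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects inverted expression profiles of sex-biased genes in
    treated-versus-control transcriptome studies. Sex-biased genes are
    called from control males versus control females by two-sample
    Student's t-test; toxicant- or disease-responsive genes are called per
    sex from affected-versus-control contrasts; the fractions of each
    sex-biased gene class that respond up or down are summarised into an
    inversion index that is positive when a sex up-regulates genes biased
    toward the opposite sex and down-regulates genes biased toward its
    own. Also provides cross-tissue consensus sex-biased gene
    identification with chromosomal summaries, hypergeometric
    over-representation analysis of gene sets with Bonferroni adjustment,
    readers for tab-separated expression matrices, sample metadata, GMT
    gene sets and gene-to-chromosome annotations, and a synthetic-data
    generator that plants sex effects and inversion responses with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
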