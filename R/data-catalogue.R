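#' Load the bundled human common sex-biased gene catalogue
#'
#' A published survey of nine human tissues reported 17 genes with
#' sexually dimorphic expression in the same direction in at least four
#' tissues: 7 male-biased and 10 female-biased, the latter dominated by
#' X-linked genes (XIST, ZFX, RPS4X, ...). The catalogue ships with the
#' package as a plain TSV and is useful as a reference query list and for
#' exercising [chromosome_summary()].
#'
#' @return A `"CommonGeneTable"` (see [common_gene_table()]) with the
#'   `chromosome` column filled; selection rule recorded as
#'   `k = 4` of `n_tissues = 9`.
#' @examples
#' cat17 <- human_common_sexbiased_genes()
#' chromosome_summary(cat17)
#' @export
human_common_sexbiased_genes <- function() {
  path <- system.file("extdata", "human_common_sexbiased_genes.tsv",
                      package = "sexinvert", mustWork = TRUE)
  df <- utils::read.delim(path, colClasses = "character")
  common_gene_table(df[, c("gene_id", "associated_sex", "chromosome")],
                    k = 4L, n_tissues = 9L)
}
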