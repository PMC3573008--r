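#' Identify common sex-biased genes across tissues
#'
#' A gene is a common sex-biased gene when it is called biased toward the
#' same sex in at least `k` of the supplied per-tissue tables (the
#' direction-consistent rule; set `consistent_direction = FALSE` to count
#' dimorphic calls of either direction toward `k`, with the majority
#' direction as the associated sex). A gene reaching `k` for both sexes
#' (or tied under the loose rule) is excluded and reported in the
#' `conflicts` attribute. Genes absent from a tissue's table simply cannot
#' contribute a call in that tissue.
#'
#' @param tables Named list of `"SexBiasTable"` objects, one per tissue;
#'   names are the tissue labels.
#' @param k Minimum number of tissues with a same-direction biased call
#'   (default 4).
#' @param annotation Optional named character vector
#'   (`symbol -> chromosome`, see [read_annotation()]) used to fill the
#'   `chromosome` column; genes without an entry get `NA`.
#' @param consistent_direction Count only same-direction calls toward `k`
#'   (default `TRUE`).
#' @return A `"CommonGeneTable"`: data.frame with columns `gene_id`,
#'   `associated_sex`, `n_tissues_biased`, `tissues` (comma-joined),
#'   `chromosome`; attributes `k`, `n_tissues`, `conflicts`,
#'   `tissue_coverage` (genes measured per tissue).
#' @export
find_common_genes <- function(tables, k = 4, annotation = NULL,
                              consistent_direction = TRUE) {
  if (!is.list(tables) || !length(tables) ||
      !all(vapply(tables, inherits, logical(1), "SexBiasTable")))
    stop("`tables` must be a non-empty list of SexBiasTable objects",
         call. = FALSE)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- paste0("tissue", seq_along(tables))
  n_tis <- length(tables)
  if (k < 1 || k > n_tis)
    stop("k must be between 1 and the number of tables (", n_tis, ")",
         call. = FALSE)

  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene_id"),
                              use.names = FALSE)))
  male_mat <- vapply(tables, function(tb) {
    cls <- tb$class[match(genes, tb$gene_id)]
    !is.na(cls) & cls == "male_biased"
  }, logical(length(genes)))
  female_mat <- vapply(tables, function(tb) {
    cls <- tb$class[match(genes, tb$gene_id)]
    !is.na(cls) & cls == "female_biased"
  }, logical(length(genes)))
  if (length(genes) == 1L) {
    male_mat <- matrix(male_mat, nrow = 1)
    female_mat <- matrix(female_mat, nrow = 1)
  }
  n_male <- rowSums(male_mat)
  n_female <- rowSums(female_mat)

  if (consistent_direction) {
    is_male <- n_male >= k
    is_female <- n_female >= k
    conflict <- is_male & is_female
  } else {
    reach <- (n_male + n_female) >= k
    is_male <- reach & n_male > n_female
    is_female <- reach & n_female > n_male
    conflict <- reach & n_male == n_female
  }
  keep_male <- is_male & !conflict
  keep_female <- is_female & !conflict

  sel <- which(keep_male | keep_female)
  assoc <- ifelse(keep_male[sel], "male_biased", "female_biased")
  n_bias <- ifelse(keep_male[sel], n_male[sel], n_female[sel])
  if (!consistent_direction)
    n_bias <- n_male[sel] + n_female[sel]
  tissues <- vapply(seq_along(sel), function(j) {
    i <- sel[j]
    hit <- if (consistent_direction) {
      if (assoc[j] == "male_biased") male_mat[i, ] else female_mat[i, ]
    } else male_mat[i, ] | female_mat[i, ]
    paste(names(tables)[hit], collapse = ",")
  }, character(1))

  out <- data.frame(gene_id = genes[sel], associated_sex = assoc,
                    n_tissues_biased = as.integer(n_bias),
                    tissues = tissues,
                    chromosome = if (is.null(annotation))
                      rep(NA_character_, length(sel))
                    else unname(annotation[genes[sel]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$associated_sex, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("CommonGeneTable", "data.frame"),
            k = k, n_tissues = n_tis, conflicts = genes[conflict],
            tissue_coverage = vapply(tables, nrow, integer(1)))
}

#' Build a CommonGeneTable from an external catalogue
#'
#' Wraps a pre-computed table of common sex-biased genes (for instance a
#' published multi-tissue survey) so it can feed [chromosome_summary()].
#'
#' @param df data.frame with columns `gene_id`, `associated_sex`
#'   (`male_biased`/`female_biased`) and optionally `chromosome`,
#'   `n_tissues_biased`, `tissues`.
#' @param k,n_tissues The selection rule the catalogue was built under,
#'   recorded as attributes.
#' @return A `"CommonGeneTable"`.
#' @export
common_gene_table <- function(df, k = NA_integer_, n_tissues = NA_integer_) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "associated_sex") %in% names(df)))
    stop("need columns gene_id and associated_sex", call. = FALSE)
  bad <- setdiff(unique(df$associated_sex),
                 c("male_biased", "female_biased"))
  if (length(bad))
    stop("invalid associated_sex value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids", call. = FALSE)
  if (!"chromosome" %in% names(df))
    df$chromosome <- rep(NA_character_, nrow(df))
  if (!"n_tissues_biased" %in% names(df))
    df$n_tissues_biased <- rep(NA_integer_, nrow(df))
  if (!"tissues" %in% names(df))
    df$tissues <- rep(NA_character_, nrow(df))
  df <- df[, c("gene_id", "associated_sex", "n_tissues_biased",
               "tissues", "chromosome")]
  structure(df, class = c("CommonGeneTable", "data.frame"),
            k = k, n_tissues = n_tissues, conflicts = character(),
            tissue_coverage = integer())
}

#' Chromosomal distribution of common sex-biased genes
#'
#' Tabulates how many common genes of each associated sex lie on each
#' chromosome — e.g. revealing an excess of female-biased genes on X.
#' Every gene must carry an annotation (from the table itself or the
#' `annotation` argument); an unannotated gene is an error naming it.
#'
#' @param common A [find_common_genes()] / [common_gene_table()] result.
#' @param annotation Optional named character vector
#'   (`symbol -> chromosome`) overriding/filling the table's own
#'   `chromosome` column.
#' @return data.frame with columns `associated_sex`, `chromosome`,
#'   `n_genes`, sorted by sex then descending count. Empty input yields an
#'   empty data.frame. Counts within each sex sum to the number of common
#'   genes of that sex.
#' @export
chromosome_summary <- function(common, annotation = NULL) {
  if (!inherits(common, "CommonGeneTable"))
    stop("`common` must be a CommonGeneTable", call. = FALSE)
  chrom <- common$chromosome
  if (!is.null(annotation)) {
    hit <- common$gene_id %in% names(annotation)
    chrom[hit] <- unname(annotation[common$gene_id[hit]])
  }
  if (nrow(common) == 0L)
    return(data.frame(associated_sex = character(),
                      chromosome = character(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  un <- is.na(chrom) | chrom == ""
  if (any(un))
    stop("no chromosome annotation for gene(s): ",
         paste(common$gene_id[un], collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(list(n_genes = common$gene_id),
                          by = list(associated_sex = common$associated_sex,
                                    chromosome = chrom),
                          FUN = length)
  agg <- agg[order(agg$associated_sex, -agg$n_genes, agg$chromosome), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("associated_sex", "chromosome", "n_genes")]
}
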