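#' Run the inversion-profile pipeline on one study
#'
#' Chains the full per-study analysis: sex-bias calling from controls,
#' per-sex perturbation calling for every (condition, time point) present
#' among the affected samples, responsive-gene ratios, inversion indices
#' and condition labels. Optionally writes two self-describing TSVs
#' (`ratios.tsv` long format; `labels.tsv` one row per contrast, both
#' carrying the thresholds used) into `out_dir`.
#'
#' @param study An [expression_study()] (or a length-2 character vector of
#'   matrix and metadata paths, read via [read_expression_study()]).
#' @param alpha Raw p-value threshold for both gene-calling stages.
#' @param tau Inversion-label threshold, see [label_condition()].
#' @param out_dir Optional output directory for the TSVs.
#' @param collapse Optional `probe_map` data.frame triggering
#'   [collapse_probes()] before analysis (default `NULL`, off).
#' @param verbose Log gene-universe and class counts per stage.
#' @return Invisibly, a list with `bias` (the `"SexBiasTable"`), `ratios`
#'   (long data.frame: condition, time_point, sex, ratio_type, ratio,
#'   numerator, denominator, alpha), `labels` (data.frame: condition,
#'   time_point, index_male, index_female, label, tau, alpha) and
#'   `profiles` (list of `"InversionProfile"`).
#' @export
run_profile <- function(study, alpha = 0.01, tau = 0.05, out_dir = NULL,
                        collapse = NULL, verbose = TRUE) {
  if (is.character(study)) {
    if (length(study) != 2L)
      stop("`study` as paths must be c(matrix_path, metadata_path)",
           call. = FALSE)
    study <- read_expression_study(study[1], study[2])
  }
  stopifnot(inherits(study, "ExpressionStudy"))
  if (!is.null(collapse)) study <- collapse_probes(study, collapse)
  say <- function(...) if (verbose) message(...)
  say("universe: ", nrow(study$matrix), " genes, ",
      ncol(study$matrix), " samples")

  bias <- call_sex_bias(study, alpha = alpha)
  cnt <- table(bias$class)
  say("sex-biased genes at alpha=", alpha, ": ",
      sum(bias$class == "male_biased"), " male-biased, ",
      sum(bias$class == "female_biased"), " female-biased, ",
      sum(bias$class == "unbiased"), " unbiased")

  s <- study$samples
  aff <- s[s$group == "affected", , drop = FALSE]
  if (!nrow(aff))
    stop("study contains no affected samples", call. = FALSE)
  contrasts <- unique(aff[, c("condition", "time_point"), drop = FALSE])

  ratio_rows <- list()
  label_rows <- list()
  profiles <- list()
  for (i in seq_len(nrow(contrasts))) {
    cond <- contrasts$condition[i]
    tp <- contrasts$time_point[i]
    tp_arg <- if (is.na(tp)) NULL else tp
    rr <- lapply(c(male = "male", female = "female"), function(sx) {
      pert <- call_perturbation(study, cond, sx, alpha = alpha,
                                time_point = tp_arg)
      say(cond, if (!is.na(tp)) paste0("@", tp), " ", sx, ": ",
          sum(pert$regulation == "up"), " up, ",
          sum(pert$regulation == "down"), " down")
      responsive_ratios(bias, pert)
    })
    for (sx in names(rr)) {
      r <- rr[[sx]]
      ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
        condition = cond, time_point = tp, sex = sx,
        ratio_type = names(r$ratios), ratio = unname(r$ratios),
        numerator = unname(r$counts[1:4]),
        denominator = unname(r$counts[c(5, 5, 6, 6)]),
        alpha = alpha, stringsAsFactors = FALSE)
    }
    prof <- label_condition(rr$male, rr$female, tau = tau)
    profiles[[length(profiles) + 1L]] <- prof
    label_rows[[length(label_rows) + 1L]] <- data.frame(
      condition = cond, time_point = tp,
      index_male = prof$index_male, index_female = prof$index_female,
      label = prof$label, tau = tau, alpha = alpha,
      stringsAsFactors = FALSE)
  }
  ratios <- do.call(rbind, ratio_rows)
  labels <- do.call(rbind, label_rows)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(ratios, file.path(out_dir, "ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(labels, file.path(out_dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("wrote ", file.path(out_dir, "ratios.tsv"), " and labels.tsv")
  }
  invisible(list(bias = bias, ratios = ratios, labels = labels,
                 profiles = profiles))
}

#' Cross-tissue common sex-biased genes with chromosome summary
#'
#' Calls sex-biased genes in every supplied study (or accepts
#' ready-made `"SexBiasTable"`s), finds genes biased toward the same sex
#' in at least `k` tissues, attaches chromosomes and writes the consensus
#' table plus its chromosome contingency table.
#'
#' @param studies Named list of [expression_study()] or `"SexBiasTable"`
#'   objects; names are tissue labels.
#' @param annotation Named character vector `symbol -> chromosome`
#'   ([read_annotation()]); required for the chromosome summary.
#' @param k Minimum number of same-direction tissues (default 4).
#' @param alpha Threshold passed to [call_sex_bias()] where needed.
#' @param out_dir Optional output directory (`common_genes.tsv`,
#'   `chromosome_summary.tsv`).
#' @return Invisibly, list with `common` (a `"CommonGeneTable"`) and
#'   `chromosomes` (the [chromosome_summary()] data.frame).
#' @export
run_common <- function(studies, annotation, k = 4, alpha = 0.01,
                       out_dir = NULL) {
  tables <- lapply(studies, function(x) {
    if (inherits(x, "SexBiasTable")) x
    else if (inherits(x, "ExpressionStudy")) call_sex_bias(x, alpha = alpha)
    else stop("each study must be an ExpressionStudy or SexBiasTable",
              call. = FALSE)
  })
  common <- find_common_genes(tables, k = k, annotation = annotation)
  chrom <- chromosome_summary(common, annotation = annotation)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    out <- as.data.frame(common)
    out$k <- attr(common, "k")
    out$n_tissues_surveyed <- attr(common, "n_tissues")
    utils::write.table(out, file.path(out_dir, "common_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(chrom,
                       file.path(out_dir, "chromosome_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(common = common, chromosomes = chrom))
}

#' Gene-set enrichment of a query list against a GMT database
#'
#' Thin driver over [enrich()]: accepts file paths or in-memory objects
#' and writes a result TSV carrying the thresholds used.
#'
#' @param query Character vector of gene symbols, or path to a one-symbol-
#'   per-line text file.
#' @param gmt A `"GeneSetDB"` or path to a GMT file.
#' @param background Optional character vector or path (one symbol per
#'   line); default the GMT gene union.
#' @param alpha,min_genes Significance rule, see [enrich()].
#' @param out_dir Optional output directory (`enrichment.tsv`).
#' @return Invisibly, the `"EnrichmentResult"` data.frame.
#' @export
run_enrich <- function(query, gmt, background = NULL, alpha = 0.01,
                       min_genes = 2, out_dir = NULL) {
  read_list <- function(x) {
    lines <- trimws(readLines(x, warn = FALSE))
    lines[nzchar(lines)]
  }
  if (is.character(query) && length(query) == 1L && file.exists(query))
    query <- read_list(query)
  if (is.character(gmt)) gmt <- read_gmt(gmt)
  if (is.character(background) && length(background) == 1L &&
      file.exists(background))
    background <- read_list(background)
  res <- enrich(query, gmt, background = background, alpha = alpha,
                min_genes = min_genes)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    out <- as.data.frame(res)
    out$alpha <- alpha
    out$min_genes <- min_genes
    utils::write.table(out, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}
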