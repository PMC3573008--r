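#' Read an expression study from a matrix file and a metadata file
#'
#' The matrix file is tab-separated with a header row of sample ids and a
#' first column of gene/probe ids; cells are log2 expression values with
#' missing encoded as an empty cell or `NA`. The metadata file is
#' tab-separated with header columns `sample_id`, `sex`, `group`,
#' `condition`, `time_point`.
#'
#' Nothing is silently dropped: every row and column of the input appears
#' in the returned study or an error is raised (mismatched sample ids,
#' duplicate gene ids, unparseable numeric cells with their coordinates).
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return An [expression_study()].
#' @seealso [write_expression_study()] for the inverse operation.
#' @export
read_expression_study <- function(matrix_path, metadata_path) {
  for (p in c(matrix_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)

  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(raw) < 2)
    stop("matrix file needs a gene id column plus >=1 sample column",
         call. = FALSE)
  gene_id <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  missing_tok <- vals == "" | vals == "NA" | toupper(vals) == "NA"
  bad <- is.na(num) & !missing_tok
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "unparseable numeric cell '%s' at matrix row %d (gene %s), column %d (sample %s)",
      vals[idx[1L], idx[2L]], idx[1L], gene_id[idx[1L]], idx[2L],
      colnames(vals)[idx[2L]]), call. = FALSE)
  }
  dimnames(num) <- list(gene_id, colnames(vals))

  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE,
                            colClasses = "character")
  if ("time_point" %in% names(meta)) {
    tp <- suppressWarnings(as.numeric(meta$time_point))
    # keep textual time points as text, numeric ones as numbers
    if (!any(is.na(tp) & !is.na(meta$time_point) & meta$time_point != "" &
             meta$time_point != "NA"))
      meta$time_point <- tp
    else
      meta$time_point[meta$time_point %in% c("", "NA")] <- NA
  }
  expression_study(num, meta)
}

#' Write an expression study to a matrix file and a metadata file
#'
#' Inverse of [read_expression_study()]; numeric cells are written with 17
#' significant digits so a write-then-read round trip reproduces values
#' bit-exactly.
#'
#' @param study An [expression_study()].
#' @param matrix_path,metadata_path Output paths (TSV).
#' @return Invisibly, the two paths.
#' @export
write_expression_study <- function(study, matrix_path, metadata_path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  m <- study$matrix
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  if (nrow(m) == 0L) {
    writeLines(header, matrix_path)
  } else {
    fmt <- matrix(sprintf("%.17g", m), nrow = nrow(m), ncol = ncol(m))
    fmt[is.na(m)] <- "NA"
    body <- apply(cbind(rownames(m), fmt), 1, paste, collapse = "\t")
    writeLines(c(header, body), matrix_path)
  }
  utils::write.table(study$samples, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(c(matrix_path, metadata_path))
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member gene symbols. Duplicate genes within
#' a line are collapsed with a warning; a line with fewer than three fields
#' is an error reporting its line number.
#'
#' @param path Path to the GMT file.
#' @return A `"GeneSetDB"`: list with `sets` (named list of character
#'   vectors) and `descriptions` (named character vector). An empty file
#'   yields an empty database.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    name <- f[[1L]]
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", name, "': duplicate gene(s) collapsed: ",
              paste(unique(genes[duplicated(genes)]), collapse = ", "),
              call. = FALSE)
      genes <- unique(genes)
    }
    if (name %in% names(sets))
      stop("duplicate set name '", name, "' at GMT line ", i, call. = FALSE)
    sets[[name]] <- genes
    descs[[name]] <- f[[2L]]
  }
  structure(list(sets = sets, descriptions = descs), class = "GeneSetDB")
}

#' @export
print.GeneSetDB <- function(x, ...) {
  cat("GeneSetDB:", length(x$sets), "set(s),",
      length(unique(unlist(x$sets, use.names = FALSE))), "distinct genes\n")
  invisible(x)
}

#' Read a gene-to-chromosome annotation table
#'
#' Two-column tab-separated file (no header): gene symbol, chromosome
#' label (e.g. `"X"`, `"Y"`, `"17"`). Duplicate rows repeating the same
#' chromosome are de-duplicated; a symbol listed with two different
#' chromosomes is an error naming the symbol.
#'
#' @param path Path to the annotation TSV.
#' @return Named character vector: `symbol -> chromosome`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2)
    stop("annotation file must have two tab-separated columns", call. = FALSE)
  df <- unique(df[, 1:2])
  names(df) <- c("symbol", "chromosome")
  if (any(df$chromosome == "" | is.na(df$chromosome)))
    stop("empty chromosome label for symbol(s): ",
         paste(df$symbol[df$chromosome == "" | is.na(df$chromosome)],
               collapse = ", "), call. = FALSE)
  dup <- unique(df$symbol[duplicated(df$symbol)])
  if (length(dup))
    stop("conflicting chromosome annotations for symbol(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  stats::setNames(df$chromosome, df$symbol)
}
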