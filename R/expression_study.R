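#' Construct an ExpressionStudy
#'
#' An `ExpressionStudy` bundles a log2-scale expression matrix (genes in
#' rows, samples in columns) with a sample-metadata table. It is the unit
#' every analysis stage consumes. Values are assumed already normalised and
#' on log2 scale; no transformation is applied.
#'
#' @param matrix Numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene/probe ids) and colnames (sample ids). Cells must be
#'   finite or `NA` (explicit missing).
#' @param samples `data.frame` with columns `sample_id`, `sex`
#'   (`"male"`/`"female"`), `group` (`"control"`/`"affected"`), `condition`
#'   (free-text label, e.g. `"As"`, `"Cd"`) and optionally `time_point`.
#'   Must contain exactly one row per matrix column.
#'
#' @return An object of class `"ExpressionStudy"`: a list with elements
#'   `matrix` and `samples` (samples reordered to match matrix columns).
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' md <- data.frame(sample_id = paste0("s", 1:4),
#'                  sex = rep(c("male", "female"), 2),
#'                  group = rep(c("control", "affected"), each = 2),
#'                  condition = "As", time_point = NA)
#' study <- expression_study(m, md)
#' @export
expression_study <- function(matrix, samples) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  if (nrow(matrix) == 0L && is.null(rownames(matrix)))
    rownames(matrix) <- character()
  gid <- rownames(matrix)
  sid <- colnames(matrix)
  if (nrow(matrix) > 0L && (is.null(gid) || anyNA(gid) || any(gid == "")))
    stop("matrix must have non-empty gene rownames", call. = FALSE)
  if (is.null(sid) || anyNA(sid) || any(sid == ""))
    stop("matrix must have non-empty sample colnames", call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  bad <- !is.finite(matrix) & !is.na(matrix)
  if (any(bad))
    stop("non-finite expression values (Inf/NaN) at ",
         sum(bad), " cell(s); encode missing values as NA", call. = FALSE)

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "sex", "group", "condition")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"time_point" %in% names(samples)) samples$time_point <- NA
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)

  only_meta <- setdiff(samples$sample_id, sid)
  only_mat  <- setdiff(sid, samples$sample_id)
  if (length(only_meta) || length(only_mat))
    stop("sample ids differ between matrix and metadata; ",
         if (length(only_mat))
           paste0("matrix-only: ", paste(only_mat, collapse = ", "), "; "),
         if (length(only_meta))
           paste0("metadata-only: ", paste(only_meta, collapse = ", ")),
         call. = FALSE)

  bad_sex <- setdiff(unique(samples$sex), c("male", "female"))
  if (length(bad_sex))
    stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "),
         "; allowed values are \"male\", \"female\"", call. = FALSE)
  bad_grp <- setdiff(unique(samples$group), c("control", "affected"))
  if (length(bad_grp))
    stop("invalid group value(s): ", paste(bad_grp, collapse = ", "),
         "; allowed values are \"control\", \"affected\"", call. = FALSE)

  # preserve the matrix sample order
  samples <- samples[match(sid, samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(matrix = matrix, samples = samples),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy:", nrow(x$matrix), "genes x",
      ncol(x$matrix), "samples\n")
  tab <- table(sex = x$samples$sex, group = x$samples$group)
  print(tab)
  conds <- unique(x$samples$condition)
  cat("condition(s):", paste(conds, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionStudy <- function(x) dim(x$matrix)

#' Collapse probe-level rows to gene symbols
#'
#' Optional step for probe-level matrices: rows mapping to the same symbol
#' are collapsed to their per-sample median. Probes with no mapping are
#' dropped. Off by default in the pipeline drivers because platforms differ
#' in whether their row identifiers are already gene-level.
#'
#' @param study An [expression_study()].
#' @param probe_map `data.frame` with columns `probe_id` and `symbol`.
#' @return A new `ExpressionStudy` whose rownames are symbols.
#' @export
collapse_probes <- function(study, probe_map) {
  stopifnot(inherits(study, "ExpressionStudy"))
  probe_map <- as.data.frame(probe_map, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "symbol") %in% names(probe_map)))
    stop("probe_map needs columns probe_id and symbol", call. = FALSE)
  sym <- probe_map$symbol[match(rownames(study$matrix), probe_map$probe_id)]
  keep <- !is.na(sym) & sym != ""
  if (!any(keep)) stop("no probes map to a symbol", call. = FALSE)
  m <- study$matrix[keep, , drop = FALSE]
  sym <- sym[keep]
  collapsed <- t(vapply(split(seq_along(sym), sym), function(idx) {
    apply(m[idx, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  }, numeric(ncol(m))))
  collapsed[is.nan(collapsed)] <- NA_real_
  expression_study(collapsed, study$samples)
}
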