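#' Hypergeometric upper-tail probability
#'
#' Over-representation p-value `P(X >= k)` for an observed overlap of `k`
#' genes between a query of size `n` and a gene set with `K` members,
#' drawn from a background of `N` genes. Evaluated through the
#' hypergeometric distribution function, which is numerically stable for
#' large arguments.
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Set size within the background.
#' @param n Query size within the background.
#' @param N Background size; `K <= N`, `n <= N`.
#' @return `P(X >= k)`; equals 1 when `k = 0`.
#' @examples
#' hypergeom_upper_tail(4, K = 5, n = 4, N = 10)  # 5/210
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N))
    if (length(v) != 1L || !is.finite(v) || v != round(v) || v < 0)
      stop("k, K, n, N must be single non-negative integers", call. = FALSE)
  if (K > N || n > N)
    stop("K and n must not exceed the background size N", call. = FALSE)
  if (k > min(K, n))
    stop("k must not exceed min(K, n)", call. = FALSE)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Tests each set of a [read_gmt()] database for over-representation in a
#' query gene list with [hypergeom_upper_tail()], then applies Bonferroni
#' adjustment `adj_p = min(1, m * raw_p)` where `m` is the number of sets
#' actually testable (at least one member inside the background; sets
#' lying entirely outside it are skipped rather than inflating `m`).
#' A set is significant when `adj_p < alpha` and its overlap has at least
#' `min_genes` genes.
#'
#' @param query Character vector of gene symbols. Symbols outside the
#'   background are dropped with a warning. An empty query gives
#'   `raw_p = 1` everywhere.
#' @param db A `"GeneSetDB"` from [read_gmt()].
#' @param background Character vector of gene symbols defining the
#'   universe. Default: the union of all genes in `db`. Typically this
#'   should be intersected with the measured gene universe by passing it
#'   explicitly.
#' @param alpha Adjusted p-value threshold (default 0.01).
#' @param min_genes Minimum overlap size for significance (default 2).
#' @return An `"EnrichmentResult"` data.frame sorted by `adj_p` then set
#'   name, with columns `set_name`, `k`, `K`, `n`, `N`, `raw_p`, `adj_p`,
#'   `significant`, `overlap_genes` (comma-joined); attributes `alpha`,
#'   `min_genes`, `m_tested`.
#' @export
enrich <- function(query, db, background = NULL, alpha = 0.01,
                   min_genes = 2) {
  if (!inherits(db, "GeneSetDB"))
    stop("`db` must be a GeneSetDB (see read_gmt)", call. = FALSE)
  if (!length(db$sets))
    stop("gene-set database is empty", call. = FALSE)
  if (is.null(background))
    background <- unique(unlist(db$sets, use.names = FALSE))
  background <- unique(as.character(background))
  if (!length(background))
    stop("background gene universe is empty", call. = FALSE)
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background ",
            "dropped: ", paste(utils::head(outside, 5), collapse = ", "),
            if (length(outside) > 5) ", ...", call. = FALSE)
    query <- intersect(query, background)
  }
  N <- length(background)
  n <- length(query)

  Ks <- vapply(db$sets, function(s) length(intersect(s, background)),
               integer(1))
  testable <- Ks >= 1L
  m <- sum(testable)
  if (m == 0L)
    stop("no gene set overlaps the background", call. = FALSE)

  rows <- lapply(names(db$sets)[testable], function(nm) {
    hits <- intersect(intersect(db$sets[[nm]], background), query)
    k <- length(hits)
    K <- Ks[[nm]]
    raw <- stats::phyper(k - 1, m = K, n = N - K, k = n,
                         lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, raw_p = raw,
               overlap_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- pmin(1, m * res$raw_p)
  res$significant <- res$adj_p < alpha & res$k >= min_genes
  res <- res[order(res$adj_p, res$set_name), c(
    "set_name", "k", "K", "n", "N", "raw_p", "adj_p", "significant",
    "overlap_genes")]
  rownames(res) <- NULL
  structure(res, class = c("EnrichmentResult", "data.frame"),
            alpha = alpha, min_genes = min_genes, m_tested = m)
}
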