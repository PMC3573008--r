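#' Two-sample Student's t-test (pooled variance)
#'
#' Two-sided two-sample t-test with the equal-variance (pooled) statistic:
#' the sign of `t_stat` follows `mean(a) - mean(b)` and the p-value comes
#' from the t distribution with `n_a + n_b - 2` degrees of freedom. A Welch
#' (unequal-variance) variant is available via `var_equal = FALSE`.
#'
#' Degenerate inputs get a deterministic contract: both groups constant
#' with equal means gives `t = 0, p = 1`; both groups constant with unequal
#' means gives `p = 0` with `t = +/-Inf`; either case is flagged
#' `degenerate`. Fewer than two finite values in a group is an error.
#'
#' @param a,b Numeric vectors of log2 expression values; `NA`s are dropped.
#' @param var_equal Pooled variance if `TRUE` (default), Welch otherwise.
#' @return List with `t_stat`, `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `df` and logical `degenerate`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(3, 4, 5))
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("insufficient replicates: each group needs >= 2 finite values ",
         "(got ", length(a), " and ", length(b), ")", call. = FALSE)
  n_a <- length(a); n_b <- length(b)
  m_a <- mean(a);   m_b <- mean(b)
  v_a <- stats::var(a); v_b <- stats::var(b)
  const_a <- diff(range(a)) == 0
  const_b <- diff(range(b)) == 0

  if (const_a && const_b) {
    if (m_a == m_b)
      return(list(t_stat = 0, p_value = 1, mean_a = m_a, mean_b = m_b,
                  n_a = n_a, n_b = n_b, df = n_a + n_b - 2,
                  degenerate = TRUE))
    return(list(t_stat = sign(m_a - m_b) * Inf, p_value = 0,
                mean_a = m_a, mean_b = m_b, n_a = n_a, n_b = n_b,
                df = n_a + n_b - 2, degenerate = TRUE))
  }

  if (var_equal) {
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  } else {
    se2_a <- v_a / n_a
    se2_b <- v_b / n_b
    se <- sqrt(se2_a + se2_b)
    df <- (se2_a + se2_b)^2 /
      (se2_a^2 / (n_a - 1) + se2_b^2 / (n_b - 1))
  }
  t_stat <- (m_a - m_b) / se
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  list(t_stat = t_stat, p_value = p, mean_a = m_a, mean_b = m_b,
       n_a = n_a, n_b = n_b, df = df, degenerate = FALSE)
}

# Vectorised pooled t over matrix rows with pairwise NA deletion.
# Returns a data.frame with one row per gene. Rows with < 2 finite values
# in either group are flagged insufficient (t/p = NA); constant-constant
# rows follow the degenerate contract of two_sample_t().
row_pooled_t <- function(x_a, x_b) {
  stats_for <- function(x) {
    ok <- is.finite(x)
    x0 <- x
    x0[!ok] <- 0
    n <- rowSums(ok)
    s <- rowSums(x0)
    m <- ifelse(n > 0, s / n, NA_real_)
    # two-pass centred sum of squares for accuracy
    cs <- (x0 - m)^2
    cs[!ok] <- 0
    v <- ifelse(n > 1, rowSums(cs) / (n - 1), NA_real_)
    rng0 <- x
    rng0[!ok] <- NA
    cmin <- do.call(pmin, c(as.data.frame(rng0), na.rm = TRUE))
    cmax <- do.call(pmax, c(as.data.frame(rng0), na.rm = TRUE))
    list(n = n, mean = m, var = v, const = !is.na(cmin) & cmin == cmax)
  }
  sa <- stats_for(x_a)
  sb <- stats_for(x_b)
  n_a <- sa$n; n_b <- sb$n
  insufficient <- n_a < 2L | n_b < 2L
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sa$var + (n_b - 1) * sb$var) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t_stat <- (sa$mean - sb$mean) / se
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)

  both_const <- sa$const & sb$const & !insufficient
  eq <- both_const & sa$mean == sb$mean
  ne <- both_const & sa$mean != sb$mean
  t_stat[eq] <- 0;   p[eq] <- 1
  t_stat[ne] <- sign(sa$mean[ne] - sb$mean[ne]) * Inf
  p[ne] <- 0
  t_stat[insufficient] <- NA_real_
  p[insufficient] <- NA_real_

  data.frame(gene_id = rownames(x_a), t_stat = t_stat, p_value = p,
             mean_a = sa$mean, mean_b = sb$mean, n_a = n_a, n_b = n_b,
             degenerate = both_const, insufficient = insufficient,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify sex-biased genes from control samples
#'
#' Compares control males against control females gene by gene with the
#' pooled two-sample t-test. Genes with raw `p < alpha` and higher male
#' mean are `male_biased`; with higher female mean, `female_biased`;
#' everything else (including genes with too few usable samples, which are
#' flagged) is `unbiased`. Only `group == "control"` samples are used, so
#' the classification reflects unperturbed physiology.
#'
#' @param study An [expression_study()] with at least two male and two
#'   female control samples.
#' @param alpha Raw p-value threshold (default 0.01). No multiple-testing
#'   correction is applied to these per-gene calls.
#' @return A `"SexBiasTable"`: data.frame with columns `gene_id`, `t_stat`,
#'   `p_value`, `mean_male`, `mean_female`, `n_male`, `n_female`,
#'   `degenerate`, `insufficient`, `class`; attribute `alpha`. Classes
#'   partition the gene universe.
#' @export
call_sex_bias <- function(study, alpha = 0.01) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  s <- study$samples
  male_ctl   <- s$sample_id[s$sex == "male"   & s$group == "control"]
  female_ctl <- s$sample_id[s$sex == "female" & s$group == "control"]
  if (length(male_ctl) < 2L || length(female_ctl) < 2L)
    stop("need >= 2 male and >= 2 female control samples (have ",
         length(male_ctl), " male, ", length(female_ctl), " female)",
         call. = FALSE)
  res <- row_pooled_t(study$matrix[, male_ctl, drop = FALSE],
                      study$matrix[, female_ctl, drop = FALSE])
  names(res)[names(res) == "mean_a"] <- "mean_male"
  names(res)[names(res) == "mean_b"] <- "mean_female"
  names(res)[names(res) == "n_a"] <- "n_male"
  names(res)[names(res) == "n_b"] <- "n_female"
  cls <- rep("unbiased", nrow(res))
  sig <- !is.na(res$p_value) & res$p_value < alpha
  cls[sig & res$mean_male > res$mean_female] <- "male_biased"
  cls[sig & res$mean_male < res$mean_female] <- "female_biased"
  res$class <- cls
  structure(res, class = c("SexBiasTable", "data.frame"), alpha = alpha)
}

#' Classify perturbation-responsive genes within one sex
#'
#' Compares affected samples of one sex and condition against the control
#' samples of the same sex, gene by gene, with the pooled two-sample
#' t-test. Genes with raw `p < alpha` and higher affected mean are `up`;
#' with lower affected mean, `down`; everything else is `unchanged`.
#'
#' If `time_point` is given, affected samples are restricted to it (each
#' (condition, time point) is an independent contrast); controls matching
#' that time point are used when present, otherwise all controls of the
#' sex serve as the reference.
#'
#' @param study An [expression_study()].
#' @param condition Condition label of the affected samples to test.
#' @param sex `"male"` or `"female"`.
#' @param alpha Raw p-value threshold (default 0.01).
#' @param time_point Optional time point restricting the affected samples.
#' @return A `"PerturbationTable"`: data.frame with columns `gene_id`,
#'   `t_stat`, `p_value`, `mean_affected`, `mean_control`, `n_affected`,
#'   `n_control`, `degenerate`, `insufficient`, `regulation`; attributes
#'   `condition`, `sex`, `time_point`, `alpha`.
#' @export
call_perturbation <- function(study, condition, sex, alpha = 0.01,
                              time_point = NULL) {
  stopifnot(inherits(study, "ExpressionStudy"))
  sex <- match.arg(sex, c("male", "female"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  s <- study$samples
  aff <- s$sex == sex & s$group == "affected" & s$condition == condition
  ctl <- s$sex == sex & s$group == "control"
  if (!is.null(time_point)) {
    aff <- aff & !is.na(s$time_point) & s$time_point == time_point
    ctl_tp <- ctl & !is.na(s$time_point) & s$time_point == time_point
    if (any(ctl_tp)) ctl <- ctl_tp
  }
  if (sum(aff) < 2L || sum(ctl) < 2L)
    stop("need >= 2 affected and >= 2 control ", sex, " samples for ",
         "condition '", condition, "'",
         if (!is.null(time_point)) paste0(" at time point ", time_point),
         " (have ", sum(aff), " affected, ", sum(ctl), " control)",
         call. = FALSE)
  res <- row_pooled_t(study$matrix[, s$sample_id[aff], drop = FALSE],
                      study$matrix[, s$sample_id[ctl], drop = FALSE])
  names(res)[names(res) == "mean_a"] <- "mean_affected"
  names(res)[names(res) == "mean_b"] <- "mean_control"
  names(res)[names(res) == "n_a"] <- "n_affected"
  names(res)[names(res) == "n_b"] <- "n_control"
  reg <- rep("unchanged", nrow(res))
  sig <- !is.na(res$p_value) & res$p_value < alpha
  reg[sig & res$mean_affected > res$mean_control] <- "up"
  reg[sig & res$mean_affected < res$mean_control] <- "down"
  res$regulation <- reg
  structure(res, class = c("PerturbationTable", "data.frame"),
            condition = condition, sex = sex,
            time_point = if (is.null(time_point)) NA else time_point,
            alpha = alpha)
}

#' Build a SexBiasTable from pre-computed class labels
#'
#' Constructor for importing externally derived sex-bias calls (for
#' example a published gene list) into the pipeline; statistics columns
#' are `NA`.
#'
#' @param gene_id Character vector of gene ids.
#' @param class Character vector in `{male_biased, female_biased,
#'   unbiased}`, recycled if length 1.
#' @param alpha The threshold under which the calls were made (recorded
#'   as an attribute).
#' @return A `"SexBiasTable"`.
#' @export
sex_bias_table <- function(gene_id, class, alpha = 0.01) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids", call. = FALSE)
  if (length(class) == 1L) class <- rep(class, length(gene_id))
  bad <- setdiff(unique(class), c("male_biased", "female_biased", "unbiased"))
  if (length(bad))
    stop("invalid class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(
    data.frame(gene_id = gene_id, t_stat = NA_real_, p_value = NA_real_,
               mean_male = NA_real_, mean_female = NA_real_,
               n_male = NA_integer_, n_female = NA_integer_,
               degenerate = FALSE, insufficient = FALSE, class = class,
               stringsAsFactors = FALSE),
    class = c("SexBiasTable", "data.frame"), alpha = alpha)
}

#' Build a PerturbationTable from pre-computed regulation labels
#'
#' Constructor mirroring [sex_bias_table()] for externally derived
#' up/down/unchanged calls.
#'
#' @param gene_id Character vector of gene ids.
#' @param regulation Character vector in `{up, down, unchanged}`, recycled
#'   if length 1.
#' @param condition,sex Labels of the contrast the calls came from.
#' @param alpha Threshold attribute.
#' @return A `"PerturbationTable"`.
#' @export
perturbation_table <- function(gene_id, regulation, condition, sex,
                               alpha = 0.01) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids", call. = FALSE)
  if (length(regulation) == 1L)
    regulation <- rep(regulation, length(gene_id))
  bad <- setdiff(unique(regulation), c("up", "down", "unchanged"))
  if (length(bad))
    stop("invalid regulation value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sex <- match.arg(sex, c("male", "female"))
  structure(
    data.frame(gene_id = gene_id, t_stat = NA_real_, p_value = NA_real_,
               mean_affected = NA_real_, mean_control = NA_real_,
               n_affected = NA_integer_, n_control = NA_integer_,
               degenerate = FALSE, insufficient = FALSE,
               regulation = regulation, stringsAsFactors = FALSE),
    class = c("PerturbationTable", "data.frame"),
    condition = condition, sex = sex, time_point = NA, alpha = alpha)
}
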