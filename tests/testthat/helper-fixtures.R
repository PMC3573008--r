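# Shared builders for small in-code fixtures.

make_meta <- function(ids, sex, group, condition = "cond", time_point = NA) {
  data.frame(sample_id = ids, sex = sex, group = group,
             condition = condition, time_point = time_point,
             stringsAsFactors = FALSE)
}

# A deterministic 4-cell study: `planted` rows get +delta in male samples
# (negative delta for female-biased plants); noise-free unless sigma > 0.
tiny_study <- function(n_genes = 6, n = 3, delta = 0, sigma = 0,
                       planted = integer(), seed = 42) {
  set.seed(seed)
  ids <- c(paste0("mc", 1:n), paste0("fc", 1:n),
           paste0("ma", 1:n), paste0("fa", 1:n))
  meta <- make_meta(ids,
                    sex = rep(rep(c("male", "female"), each = n), 2),
                    group = rep(c("control", "affected"), each = 2 * n))
  m <- matrix(8, n_genes, length(ids),
              dimnames = list(paste0("g", seq_len(n_genes)), ids))
  male_cols <- meta$sex == "male"
  for (g in planted) m[g, male_cols] <- m[g, male_cols] + delta
  if (sigma > 0) m <- m + matrix(rnorm(length(m), 0, sigma), nrow(m))
  expression_study(m, meta)
}

# Closed-form pooled two-sided t, written independently of the package
# internals: textbook formula, evaluated step by step.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  ssa <- sum((a - ma)^2); ssb <- sum((b - mb)^2)
  df <- na + nb - 2
  sp <- sqrt((ssa + ssb) / df)
  t <- (ma - mb) / (sp * sqrt(1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = df))
}
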