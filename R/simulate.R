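#' Configuration for the synthetic-study generator
#'
#' Defines the generative model of [simulate_study()]: a four-cell design
#' (male/female x control/affected) with planted male- and female-biased
#' genes and a tunable inversion response. All effects are on the log2
#' scale, matching preprocessed microarray intensities.
#'
#' Defaults emulate a liver-scale toxicogenomic experiment: 2000 genes, 5%
#' planted biased genes per sex with a 1 log2-unit sex effect, five
#' replicate arrays per cell, 0.5 log2-units of Gaussian noise, and 60% of
#' each bias class responding to treatment with a 1 log2-unit shift.
#'
#' @param n_genes Number of genes.
#' @param frac_male_biased,frac_female_biased Planted fractions of male-
#'   and female-biased genes (their sum must be <= 1).
#' @param delta Sex-effect size (log2 units) added to the biased sex.
#' @param beta_male,beta_female Treatment inversion magnitude (log2 units)
#'   in affected males / females: responsive genes biased toward the
#'   affected sex shift down by `beta`, genes biased toward the opposite
#'   sex shift up by `beta`.
#' @param rho Responsive fraction of each bias class, in `[0, 1]`.
#' @param sigma Noise standard deviation (log2 units), > 0.
#' @param n_per_group Replicates per (sex, group) cell, >= 2.
#' @param baseline_mean,baseline_sd Gene baseline expression distribution.
#' @param condition Condition label written into the metadata.
#' @param seed Integer seed; the full study is reproducible from it.
#' @return A validated `"SimulationConfig"` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              frac_male_biased = 0.05,
                              frac_female_biased = 0.05,
                              delta = 1,
                              beta_male = 1,
                              beta_female = 1,
                              rho = 0.6,
                              sigma = 0.5,
                              n_per_group = 5,
                              baseline_mean = 8,
                              baseline_sd = 2,
                              condition = "toxicant",
                              seed = 0) {
  cfg <- list(n_genes = as.integer(n_genes),
              frac_male_biased = frac_male_biased,
              frac_female_biased = frac_female_biased,
              delta = delta, beta_male = beta_male,
              beta_female = beta_female, rho = rho, sigma = sigma,
              n_per_group = as.integer(n_per_group),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              condition = condition, seed = as.integer(seed))
  if (cfg$n_genes < 0) stop("n_genes must be >= 0", call. = FALSE)
  if (cfg$frac_male_biased < 0 || cfg$frac_female_biased < 0 ||
      cfg$frac_male_biased + cfg$frac_female_biased > 1)
    stop("biased fractions must be >= 0 and sum to <= 1", call. = FALSE)
  if (cfg$rho < 0 || cfg$rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  if (cfg$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (cfg$n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  structure(cfg, class = "SimulationConfig")
}

#' Simulate an expression study with planted inversion responses
#'
#' Generative model per gene g and sample i:
#' `x_gi = mu_g + bias + treatment + noise` with
#' `mu_g ~ N(baseline_mean, baseline_sd^2)`;
#' `bias = +delta` when the gene's planted bias class matches the sample's
#' sex, else 0; for affected samples of sex s the treatment term (applied
#' only to responsive biased genes) is `-beta_s` when the gene is biased
#' toward s and `+beta_s` when biased toward the opposite sex; and
#' `noise ~ N(0, sigma^2)` independently. Four sample cells are generated
#' (male/female x control/affected), each with `n_per_group` replicates.
#'
#' The planted treatment term is the inverted pattern itself, so the
#' generator provides ground truth for [call_sex_bias()],
#' [call_perturbation()], [responsive_ratios()] and [label_condition()].
#'
#' @param config A [simulation_config()].
#' @return List with `study` (an [expression_study()]) and `truth`, a
#'   data.frame with columns `gene_id`, `bias_class`, `responsive`,
#'   `shift_male`, `shift_female` (the signed treatment shifts applied in
#'   affected males / females).
#' @examples
#' sim <- simulate_study(simulation_config(n_genes = 200, seed = 1))
#' table(sim$truth$bias_class)
#' @export
simulate_study <- function(config = simulation_config()) {
  if (!inherits(config, "SimulationConfig"))
    stop("`config` must come from simulation_config()", call. = FALSE)
  set.seed(config$seed)
  G <- config$n_genes
  n <- config$n_per_group
  gene_id <- if (G > 0) sprintf("g%04d", seq_len(G)) else character()

  n_mb <- round(G * config$frac_male_biased)
  n_fb <- round(G * config$frac_female_biased)
  bias <- rep("unbiased", G)
  planted <- if (G > 0) sample.int(G, n_mb + n_fb) else integer()
  bias[planted[seq_len(n_mb)]] <- "male_biased"
  bias[planted[n_mb + seq_len(n_fb)]] <- "female_biased"

  responsive <- rep(FALSE, G)
  for (cl in c("male_biased", "female_biased")) {
    idx <- which(bias == cl)
    n_resp <- round(length(idx) * config$rho)
    if (n_resp > 0)
      responsive[sample(idx, n_resp)] <- TRUE
  }

  # signed treatment shift per (gene, affected sex)
  shift_for <- function(sex) {
    sh <- numeric(G)
    own <- if (sex == "male") "male_biased" else "female_biased"
    opp <- if (sex == "male") "female_biased" else "male_biased"
    beta <- if (sex == "male") config$beta_male else config$beta_female
    sh[responsive & bias == own] <- -beta
    sh[responsive & bias == opp] <- +beta
    sh
  }
  shift_male <- shift_for("male")
  shift_female <- shift_for("female")

  cells <- expand.grid(sex = c("male", "female"),
                       group = c("control", "affected"),
                       stringsAsFactors = FALSE)
  mu <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
  cols <- list()
  meta <- list()
  for (ci in seq_len(nrow(cells))) {
    sex <- cells$sex[ci]; group <- cells$group[ci]
    base <- mu +
      config$delta * (bias == paste0(sex, "_biased")) +
      if (group == "affected") {
        if (sex == "male") shift_male else shift_female
      } else 0
    block <- base + matrix(stats::rnorm(G * n, 0, config$sigma), G, n)
    ids <- sprintf("%s_%s_%d", substr(sex, 1, 1), substr(group, 1, 4),
                   seq_len(n))
    colnames(block) <- ids
    cols[[ci]] <- block
    meta[[ci]] <- data.frame(sample_id = ids, sex = sex, group = group,
                             condition = config$condition,
                             time_point = NA, stringsAsFactors = FALSE)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- gene_id
  samples <- do.call(rbind, meta)
  if (G == 0) m <- matrix(numeric(), 0, nrow(samples),
                          dimnames = list(NULL, samples$sample_id))

  truth <- data.frame(gene_id = gene_id, bias_class = bias,
                      responsive = responsive, shift_male = shift_male,
                      shift_female = shift_female,
                      stringsAsFactors = FALSE)
  list(study = expression_study(m, samples), truth = truth)
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Emits the TSV dialects of [read_expression_study()] plus a ground-truth
#' TSV (`matrix.tsv`, `metadata.tsv`, `truth.tsv`) into `dir_path`.
#'
#' @param study The `study` element of a [simulate_study()] result.
#' @param truth The `truth` element.
#' @param dir_path Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_fixture <- function(study, truth, dir_path) {
  if (!dir.exists(dir_path))
    dir.create(dir_path, recursive = TRUE)
  paths <- file.path(dir_path, c("matrix.tsv", "metadata.tsv", "truth.tsv"))
  write_expression_study(study, paths[1], paths[2])
  utils::write.table(truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
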