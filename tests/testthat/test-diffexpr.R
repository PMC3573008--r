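test_that("pooled t matches the frozen closed-form example and t.test", {
  tt <- two_sample_t(c(1, 2, 3), c(3, 4, 5))
  # hand-derived: pooled sd 1, se = sqrt(2/3), t = -2/se = -sqrt(6), 4 df
  expect_equal(tt$t_stat, -2.4494897427831779, tolerance = 1e-12)
  expect_equal(tt$p_value, 0.070483996910219934, tolerance = 1e-12)
  expect_identical(tt$df, 4)

  ref <- t.test(c(1, 2, 3), c(3, 4, 5), var.equal = TRUE)
  expect_equal(tt$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("identical groups give t = 0, p = 1 and swapping negates t", {
  tt <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(tt$t_stat, 0)
  expect_identical(tt$p_value, 1)

  a <- rnorm(5); b <- rnorm(4) + 1
  fwd <- two_sample_t(a, b); rev <- two_sample_t(b, a)
  expect_equal(rev$t_stat, -fwd$t_stat)
  expect_equal(rev$p_value, fwd$p_value)
})

test_that("pooled t agrees with independent oracles on random inputs", {
  set.seed(11)
  for (i in 1:200) {
    a <- rnorm(sample(2:8, 1), sd = runif(1, 0.1, 3))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2))
    got <- two_sample_t(a, b)
    orc <- oracle_pooled_t(a, b)
    expect_equal(got$t_stat, orc$t, tolerance = 1e-10)
    expect_equal(got$p_value, orc$p, tolerance = 1e-10)
    # and against stats::t.test as an independent implementation
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    refw <- t.test(a, b, var.equal = FALSE)
    gotw <- two_sample_t(a, b, var_equal = FALSE)
    expect_equal(gotw$p_value, refw$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate and insufficient inputs follow the stated contract", {
  # both groups constant, equal means
  eq <- two_sample_t(c(2, 2, 2), c(2, 2))
  expect_identical(eq$t_stat, 0)
  expect_identical(eq$p_value, 1)
  expect_true(eq$degenerate)
  # both constant, unequal means
  ne <- two_sample_t(c(3, 3), c(1, 1, 1))
  expect_identical(ne$p_value, 0)
  expect_identical(ne$t_stat, Inf)
  expect_true(ne$degenerate)
  # fewer than 2 values
  expect_error(two_sample_t(1, c(1, 2)), "insufficient replicates")
  expect_error(two_sample_t(c(1, NA), c(1, 2)), "insufficient replicates")
})

test_that("call_sex_bias recovers a planted male-biased gene and partitions", {
  study <- tiny_study(n_genes = 20, n = 4, delta = 4, sigma = 0.1,
                      planted = 1, seed = 5)
  sb <- call_sex_bias(study)
  expect_identical(sb$class[sb$gene_id == "g1"], "male_biased")
  expect_identical(sort(unique(sb$class)),
                   sort(unique(c(sb$class, "unbiased"))))
  counts <- table(factor(sb$class, c("male_biased", "female_biased",
                                     "unbiased")))
  expect_identical(sum(counts), nrow(sb))  # partition conservation
})

test_that("alpha = 0 yields no biased genes and calls are monotone in alpha", {
  sim <- simulate_study(simulation_config(n_genes = 300, delta = 1.2,
                                          sigma = 0.5, seed = 8))
  expect_true(all(call_sex_bias(sim$study, alpha = 0)$class == "unbiased"))
  b1 <- call_sex_bias(sim$study, alpha = 0.005)
  b2 <- call_sex_bias(sim$study, alpha = 0.05)
  biased1 <- b1$gene_id[b1$class != "unbiased"]
  biased2 <- b2$gene_id[b2$class != "unbiased"]
  expect_true(all(biased1 %in% biased2))
})

test_that("swapping control sex labels exchanges the biased classes exactly", {
  sim <- simulate_study(simulation_config(n_genes = 400, delta = 1.5,
                                          sigma = 0.5, seed = 13))
  sb <- call_sex_bias(sim$study)
  flipped <- sim$study
  is_ctl <- flipped$samples$group == "control"
  flipped$samples$sex[is_ctl] <-
    ifelse(flipped$samples$sex[is_ctl] == "male", "female", "male")
  sbf <- call_sex_bias(flipped)
  expect_identical(sb$gene_id[sb$class == "male_biased"],
                   sbf$gene_id[sbf$class == "female_biased"])
  expect_identical(sb$gene_id[sb$class == "female_biased"],
                   sbf$gene_id[sbf$class == "male_biased"])
})

test_that("call_sex_bias demands both sexes among controls", {
  study <- tiny_study(n_genes = 5, n = 3)
  males_only <- study$samples$sex == "male" | study$samples$group == "affected"
  sub <- expression_study(study$matrix[, males_only],
                          study$samples[males_only, ])
  expect_error(call_sex_bias(sub), "control samples")
})

test_that("perturbation calls find planted responses and respect nulls", {
  set.seed(21)
  study <- tiny_study(n_genes = 10, n = 4, sigma = 0.2, seed = 21)
  # plant an up-response in affected males for gene 1
  aff_m <- study$samples$sample_id[study$samples$sex == "male" &
                                   study$samples$group == "affected"]
  study$matrix["g1", aff_m] <- study$matrix["g1", aff_m] + 3
  pt_m <- call_perturbation(study, "cond", "male")
  expect_identical(pt_m$regulation[pt_m$gene_id == "g1"], "up")
  expect_identical(sum(table(pt_m$regulation)), nrow(pt_m))

  # affected identical to control: copy control values over
  study2 <- tiny_study(n_genes = 8, n = 3, sigma = 0.3, seed = 22)
  s <- study2$samples
  ctl_f <- s$sample_id[s$sex == "female" & s$group == "control"]
  aff_f <- s$sample_id[s$sex == "female" & s$group == "affected"]
  study2$matrix[, aff_f] <- study2$matrix[, ctl_f]
  pt_f <- call_perturbation(study2, "cond", "female")
  expect_true(all(pt_f$regulation == "unchanged"))
})

test_that("null data produce ~alpha false-positive calls", {
  sim <- simulate_study(simulation_config(n_genes = 1000, delta = 0,
                                          beta_male = 0, beta_female = 0,
                                          seed = 99))
  for (alpha in c(0.01, 0.05)) {
    sb <- call_sex_bias(sim$study, alpha = alpha)
    frac <- mean(sb$class != "unbiased")
    ci <- qnorm(0.995) * sqrt(alpha * (1 - alpha) / 1000)
    expect_lt(abs(frac - alpha), ci + 1e-12)
  }
  pt <- call_perturbation(sim$study, "toxicant", "male")
  expect_lt(abs(mean(pt$regulation != "unchanged") - 0.01),
            qnorm(0.995) * sqrt(0.01 * 0.99 / 1000))
})

test_that("genes with too few usable samples are flagged, not dropped", {
  study <- tiny_study(n_genes = 4, n = 3, seed = 3)
  study$matrix[2, study$samples$sex == "male" &
                  study$samples$group == "control"] <- c(8, NA, NA)
  sb <- call_sex_bias(study)
  expect_identical(nrow(sb), 4L)
  expect_true(sb$insufficient[sb$gene_id == "g2"])
  expect_identical(sb$class[sb$gene_id == "g2"], "unbiased")
})
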