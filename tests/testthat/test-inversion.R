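test_that("ratios are overlap counts over class totals", {
  genes <- paste0("g", 1:30)
  cls <- c(rep("male_biased", 10), rep("female_biased", 5),
           rep("unbiased", 15))
  bias <- sex_bias_table(genes, cls)
  reg <- rep("unchanged", 30)
  reg[1:3] <- "up"          # 3 of the 10 male-biased genes up
  reg[11:12] <- "down"      # 2 of the 5 female-biased genes down
  pert <- perturbation_table(genes, reg, "As", "male")
  rr <- responsive_ratios(bias, pert)
  expect_equal(rr$ratios[["r_up_male_biased"]], 0.3)
  expect_equal(rr$ratios[["r_down_female_biased"]], 0.4)
  expect_equal(rr$ratios[["r_down_male_biased"]], 0)
  expect_identical(rr$counts[["n_male_biased"]], 10L)

  # empty up and down sets: all four ratios zero
  rr0 <- responsive_ratios(bias,
                           perturbation_table(genes, "unchanged", "As", "male"))
  expect_true(all(rr0$ratios == 0))
})

test_that("empty bias classes and mismatched universes are errors", {
  genes <- paste0("g", 1:4)
  no_fb <- sex_bias_table(genes, c("male_biased", "male_biased",
                                   "unbiased", "unbiased"))
  pert <- perturbation_table(genes, "up", "As", "male")
  expect_error(responsive_ratios(no_fb, pert), "no female-biased genes")

  both <- sex_bias_table(genes, c("male_biased", "female_biased",
                                  "unbiased", "unbiased"))
  pert2 <- perturbation_table(paste0("h", 1:4), "up", "As", "male")
  expect_error(responsive_ratios(both, pert2), "different gene universes")
})

test_that("ratios are invariant to gene order and never exceed 1", {
  set.seed(31)
  genes <- paste0("g", 1:40)
  cls <- sample(c("male_biased", "female_biased", "unbiased"), 40, TRUE,
                prob = c(0.3, 0.3, 0.4))
  cls[1:2] <- c("male_biased", "female_biased")  # guarantee both classes
  reg <- sample(c("up", "down", "unchanged"), 40, TRUE)
  rr1 <- responsive_ratios(sex_bias_table(genes, cls),
                           perturbation_table(genes, reg, "x", "male"))
  perm <- sample(40)
  rr2 <- responsive_ratios(sex_bias_table(genes[perm], cls[perm]),
                           perturbation_table(genes, reg, "x", "male"))
  expect_equal(rr1$ratios, rr2$ratios)
  expect_true(all(rr1$ratios >= 0 & rr1$ratios <= 1))
  expect_lte(rr1$ratios[["r_up_male_biased"]] +
               rr1$ratios[["r_down_male_biased"]], 1)
  expect_lte(rr1$ratios[["r_up_female_biased"]] +
               rr1$ratios[["r_down_female_biased"]], 1)
})

test_that("inversion index follows its defining arithmetic", {
  genes <- paste0("g", 1:20)
  cls <- c(rep("male_biased", 10), rep("female_biased", 10))
  bias <- sex_bias_table(genes, cls)
  # male contrast: 4/10 female-biased up, 3/10 male-biased down
  reg <- rep("unchanged", 20)
  reg[11:14] <- "up"
  reg[1:3] <- "down"
  rr <- responsive_ratios(bias, perturbation_table(genes, reg, "x", "male"))
  expect_equal(inversion_index(rr), 0.7)

  # all four ratios equal -> index 0
  reg2 <- rep("unchanged", 20)
  reg2[c(1, 11)] <- "up"; reg2[c(2, 12)] <- "down"
  rr2 <- responsive_ratios(bias, perturbation_table(genes, reg2, "x", "male"))
  expect_equal(inversion_index(rr2), 0)
})

test_that("swapping the bias classes negates the index (antisymmetry)", {
  set.seed(37)
  genes <- paste0("g", 1:30)
  for (sx in c("male", "female")) {
    for (i in 1:20) {
      cls <- sample(c("male_biased", "female_biased"), 30, TRUE)
      cls[1:2] <- c("male_biased", "female_biased")
      reg <- sample(c("up", "down", "unchanged"), 30, TRUE)
      swapped <- ifelse(cls == "male_biased", "female_biased", "male_biased")
      i1 <- inversion_index(responsive_ratios(
        sex_bias_table(genes, cls),
        perturbation_table(genes, reg, "x", sx)))
      i2 <- inversion_index(responsive_ratios(
        sex_bias_table(genes, swapped),
        perturbation_table(genes, reg, "x", sx)))
      expect_equal(i1, -i2)
      # relabelling up<->down equally negates it
      flip <- c(up = "down", down = "up", unchanged = "unchanged")[reg]
      i3 <- inversion_index(responsive_ratios(
        sex_bias_table(genes, cls),
        perturbation_table(genes, unname(flip), "x", sx)))
      expect_equal(i1, -i3)
    }
  }
})

test_that("the female index mirrors the male index roles", {
  genes <- paste0("g", 1:10)
  cls <- c(rep("male_biased", 5), rep("female_biased", 5))
  bias <- sex_bias_table(genes, cls)
  reg <- c(rep("up", 5), rep("down", 5))  # mb up, fb down
  rr_m <- responsive_ratios(bias, perturbation_table(genes, reg, "x", "male"))
  rr_f <- responsive_ratios(bias, perturbation_table(genes, reg, "x", "female"))
  expect_equal(inversion_index(rr_m), -2)  # males: own-bias up = anti-inverted
  expect_equal(inversion_index(rr_f), 2)   # females: opposite-bias up = inverted
})

test_that("condition labelling applies the threshold rule", {
  genes <- paste0("g", 1:20)
  bias <- sex_bias_table(genes, c(rep("male_biased", 10),
                                  rep("female_biased", 10)))
  mk <- function(reg, sx) responsive_ratios(
    bias, perturbation_table(genes, reg, "As", sx))

  # strong male inversion (fb up 8/10, mb down 8/10), quiet female
  reg_m <- rep("unchanged", 20); reg_m[11:18] <- "up"; reg_m[1:8] <- "down"
  quiet <- rep("unchanged", 20)
  prof <- label_condition(mk(reg_m, "male"), mk(quiet, "female"))
  expect_identical(prof$label, "male_inverted")
  expect_equal(prof$index_male, 1.6)
  expect_equal(prof$index_female, 0)

  # both zero -> none
  prof0 <- label_condition(mk(quiet, "male"), mk(quiet, "female"))
  expect_identical(prof0$label, "none")

  # sub-threshold male index stays none
  reg_w <- rep("unchanged", 20); reg_w[11] <- "up"  # index 0.1 < tau 0.15
  prof_w <- label_condition(mk(reg_w, "male"), mk(quiet, "female"),
                            tau = 0.15)
  expect_identical(prof_w$label, "none")

  # exact tie above tau -> none with tie flag
  reg_tm <- rep("unchanged", 20); reg_tm[11:14] <- "up"
  reg_tf <- rep("unchanged", 20); reg_tf[1:4] <- "up"
  prof_t <- label_condition(mk(reg_tm, "male"), mk(reg_tf, "female"))
  expect_identical(prof_t$label, "none")
  expect_true(prof_t$tie)

  # condition mismatch
  rr_other <- responsive_ratios(
    bias, perturbation_table(genes, quiet, "Cd", "female"))
  expect_error(label_condition(mk(reg_m, "male"), rr_other), "mismatch")
})

test_that("a planted male-only inversion is labelled male_inverted", {
  hits <- 0L
  for (seed in 0:24) {
    sim <- simulate_study(simulation_config(
      n_genes = 800, delta = 1.5, beta_male = 1.5, beta_female = 0,
      rho = 1, sigma = 0.5, seed = seed))
    res <- run_profile(sim$study, verbose = FALSE)
    hits <- hits + (res$labels$label == "male_inverted")
  }
  expect_gte(hits, 24L)  # >= 95% of 25 replicates
})
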