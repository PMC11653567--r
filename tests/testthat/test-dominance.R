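test_that("orientation picks the higher parental line and is idempotent", {
  s <- toy_samples(reps = 2)
  norm <- toy_norm(s, list(AA_female = c(10, 30), AA_male = c(10, 30),
                           BB_female = c(30, 10), BB_male = c(30, 10),
                           AB_female = c(20, 20), AB_male = c(20, 20),
                           BA_female = c(20, 20), BA_male = c(20, 20)))
  hl <- orient_alleles(norm, s, c("A", "B"))
  expect_identical(unname(hl), c("B", "A"))
  # re-orienting is a no-op
  expect_identical(orient_alleles(norm, s, c("A", "B")), hl)
  # exact tie goes to the lexicographically larger label, with a message
  tied <- toy_norm(s, list(AA_female = 5, AA_male = 5, BB_female = 5,
                           BB_male = 5, AB_female = 5, AB_male = 5,
                           BA_female = 5, BA_male = 5))
  expect_message(hl2 <- orient_alleles(tied, s, c("A", "B")), "tie")
  expect_identical(unname(hl2), "B")
})

test_that("delta from group means matches hand calculations", {
  s <- toy_samples(reps = 2)
  norm <- toy_norm(s, list(
    AA_female = c(10, 10, 10), AA_male = c(10, 20, 10),
    BB_female = c(30, 30, 30), BB_male = c(30, 40, 30),
    AB_female = c(30, 20, 10), AB_male = c(30, 30, 15),
    BA_female = c(30, 20, 10), BA_male = c(30, 30, 15)))
  hl <- orient_alleles(norm, s, c("A", "B"))
  d <- estimate_delta(norm, s, hl, c("A", "B"))
  # gene 1: AA=10, BB=30, het=30 -> ln(30/20) = ln 1.5
  expect_equal(d$delta_f[1], log(1.5), tolerance = 1e-12)
  # gene 2 female: het = midparent -> 0
  expect_equal(d$delta_f[2], 0, tolerance = 1e-12)
  # gene 3: het below midparent -> negative
  expect_lt(d$delta_f[3], 0)
  # delta is invariant to swapping which line is called A or B
  swap <- s
  swap$dam <- chartr("AB", "BA", s$dam)
  swap$sire <- chartr("AB", "BA", s$sire)
  swap$genotype <- paste0(swap$dam, swap$sire)
  colnames(norm) <- swap$sample_id
  hl2 <- orient_alleles(norm, swap, c("A", "B"))
  d2 <- estimate_delta(norm, swap, hl2, c("A", "B"))
  expect_equal(d2$delta_f, d$delta_f, tolerance = 1e-12)
  expect_equal(d2$delta_m, d$delta_m, tolerance = 1e-12)
})

test_that("sex-by-dominance LRT is invariant to line relabeling", {
  s <- toy_samples(reps = 3)
  set.seed(31)
  X <- cross_design(s, c("A", "B"))
  mu <- exp(log(60) + 0.5 * X[, "sex"] + 0.5 * X[, "a"] +
              0.4 * X[, "sex_h"])
  y <- rnbinom(nrow(s), mu = mu, size = 1 / 0.03)
  p1 <- nb_lrt_fit(y, cross_design(s, c("A", "B")), "sex_h",
                   phi = 0.03)$p
  p2 <- nb_lrt_fit(y, cross_design(s, c("B", "A")), "sex_h",
                   phi = 0.03)$p
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("classification follows the delta signs and q thresholds", {
  c1 <- classify_dominance(0.4, -0.3, 0.01, 0.02, 0.001)
  expect_identical(c1[c("class_f", "class_m")],
                   list(class_f = "dominant", class_m = "recessive"))
  expect_true(c1$ssd); expect_true(c1$reversal)

  c2 <- classify_dominance(0.4, 0.1, 0.01, 0.4, 0.01)
  expect_identical(c2$class_m, "additive")
  expect_true(c2$ssd); expect_false(c2$reversal)

  c3 <- classify_dominance(0.4, -0.3, 0.01, 0.02, 0.2)
  expect_false(c3$ssd); expect_false(c3$reversal)
})

test_that("sex-bias change in heterozygotes: hand cases and symmetry", {
  expect_identical(sb_change_in_hets(20, 40, 20, 40)$label, "equal")
  lesser <- sb_change_in_hets(30, 40, 20, 40)
  expect_identical(lesser$label, "lesser")
  expect_equal(lesser$d_het, abs(log2(30 / 40)), tolerance = 1e-12)
  expect_equal(lesser$d_mid, 1, tolerance = 1e-12)
  # swapping the sexes leaves the label unchanged
  expect_identical(sb_change_in_hets(40, 30, 40, 20)$label, "lesser")
  expect_identical(sb_change_in_hets(80, 20, 40, 20)$label, "greater")
  expect_identical(sb_change_in_hets(0, 20, 40, 20)$label, NA_character_)
})

test_that("focal filter separates line effects from sex-discordant ones", {
  # plant three regimes: no line effect, concordant, strongly discordant
  cfg <- quick_config(n_genes = 120, seed = 32, prop_line_diff = 0.5,
                      prop_sex_line_inter = 0.4,
                      additive_range = c(1, 2),
                      baseline_log2_range = c(6, 10),
                      dispersion_meanlog = log(0.02), dispersion_sdlog = 0.3)
  sim <- simulate_cross(cfg)
  sf <- size_factors(sim$counts)
  foc <- focal_filter(sim$counts, sim$samples, sf, c("A", "B"))
  tr <- sim$truth
  # strong concordant line effects are recovered as focal
  strong <- tr$line_diff & !tr$sex_line_inter & abs(tr$beta_a_f) >= 1
  expect_gte(mean(foc$focal[strong]), 0.9)
  # genes with no parental difference fail step 1
  expect_lt(mean(foc$parental_DE_pass[!tr$line_diff]), 0.1)
  # strongly discordant genes do not survive both steps
  disc <- tr$sex_line_inter &
    abs(tr$beta_a_f - tr$beta_a_m) >= 1.5
  expect_lt(mean(foc$focal[disc]), 0.3)
})

test_that("X-linked analysis yields female-only dominance calls", {
  cfg <- sim_config(n_genes = 60, crosses = list(c("A", "B")), seed = 33,
                    prop_x_linked = 1, prop_y_linked = 0,
                    baseline_log2_range = c(6, 10))
  sim <- simulate_cross(cfg)
  sf <- size_factors(sim$counts)
  res <- suppressMessages(run_dominance(sim$counts, sim$samples, sf,
                                        c("A", "B"), chrom_class = "X"))
  expect_true(all(is.na(res$delta_m)))
  expect_true(all(is.na(res$p_sexdom)))
  expect_true(all(is.na(res$ssd)))
  expect_true(all(is.na(res$class_m)))
  # female nonadditivity p-values exist for focal converged genes
  ok <- res$focal & !is.na(res$converged) & res$converged
  expect_true(all(!is.na(res$p_nonadd_f[ok])))
})

test_that("parent-of-origin calls require both sexes", {
  # strong POE in every line-different gene: flagged consistently
  cfg <- quick_config(n_genes = 80, seed = 34, prop_line_diff = 1,
                      prop_poe = 1, poe_range = c(0.8, 1.2),
                      prop_sex_line_inter = 0, prop_ssd = 0,
                      baseline_log2_range = c(7, 10),
                      dispersion_meanlog = log(0.02), dispersion_sdlog = 0.2)
  sim <- simulate_cross(cfg)
  sf <- size_factors(sim$counts)
  res <- suppressMessages(run_dominance(sim$counts, sim$samples, sf,
                                        c("A", "B")))
  ok <- res$focal & !is.na(res$converged) & res$converged
  expect_gte(mean(res$poe_sex_consistent[ok]), 0.8)

  # no POE simulated: consistent fraction near zero
  cfg0 <- quick_config(n_genes = 80, seed = 35, prop_line_diff = 1,
                       prop_poe = 0, prop_sex_line_inter = 0, prop_ssd = 0,
                       baseline_log2_range = c(7, 10))
  sim0 <- simulate_cross(cfg0)
  res0 <- suppressMessages(run_dominance(sim0$counts, sim0$samples,
                                         size_factors(sim0$counts),
                                         c("A", "B")))
  ok0 <- res0$focal & !is.na(res0$converged) & res0$converged
  expect_lte(mean(res0$poe_sex_consistent[ok0]), 0.05)
})
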