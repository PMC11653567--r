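test_that("seeding contract: same seed bit-identical, new seed differs", {
  a <- simulate_cross(quick_config(seed = 3))
  b <- simulate_cross(quick_config(seed = 3))
  c <- simulate_cross(quick_config(seed = 4))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$counts, c$counts))
})

test_that("config proportions and scales are validated", {
  expect_error(sim_config(prop_ssd = 1.4), "proportion")
  expect_error(sim_config(prop_x_linked = 0.7, prop_y_linked = 0.5),
               "exceeds 1")
  expect_error(sim_config(additive_range = c(2, 1)), "increasing")
  expect_error(sim_config(ssd_delta_range = c(0.5, 4), delta_max = 1.2),
               "incompatible")
})

test_that("additivity limit: heterozygote means converge to midparent", {
  # delta = 0 everywhere, near-zero dispersion, deep counts
  cfg <- quick_config(n_genes = 60, seed = 5, prop_ssd = 0, delta_sd = 0,
                      prop_poe = 0, prop_sex_line_inter = 0,
                      prop_sex_biased = 0,
                      dispersion_meanlog = log(1e-7),
                      dispersion_sdlog = 1e-3,
                      baseline_log2_range = c(16, 18), libsize_sdlog = 0)
  sim <- simulate_cross(cfg)
  s <- sim$samples
  gm <- function(geno, sex)
    rowMeans(sim$counts[, s$sample_id[s$genotype == geno & s$sex == sex],
                        drop = FALSE])
  for (sex in c("female", "male")) {
    het <- (gm("AB", sex) + gm("BA", sex)) / 2
    mid <- (gm("AA", sex) + gm("BB", sex)) / 2
    expect_lt(max(abs(log(het / mid))), 0.02)
  }
})

test_that("X-linked male heterozygotes express the dam line's level", {
  cfg <- sim_config(n_genes = 80, crosses = list(c("A", "B")), seed = 6,
                    prop_x_linked = 1, prop_y_linked = 0,
                    prop_sex_biased = 0,
                    dispersion_meanlog = log(1e-7), dispersion_sdlog = 1e-3,
                    baseline_log2_range = c(16, 18), libsize_sdlog = 0)
  sim <- simulate_cross(cfg)
  s <- sim$samples
  gm <- function(geno)
    rowMeans(sim$counts[, s$sample_id[s$genotype == geno &
                                        s$sex == "male"], drop = FALSE])
  expect_lt(max(abs(log(gm("AB") / gm("AA")))), 0.02)  # dam = A
  expect_lt(max(abs(log(gm("BA") / gm("BB")))), 0.02)  # dam = B
})

test_that("counts match negative-binomial moments", {
  cfg <- sim_config(n_genes = 40, n_reps = 150,
                    crosses = list(c("A", "B")), seed = 7,
                    prop_sex_biased = 0, prop_line_diff = 0, prop_ssd = 0,
                    prop_x_linked = 0, prop_y_linked = 0,
                    dispersion_meanlog = log(0.1), dispersion_sdlog = 0,
                    baseline_log2_range = c(8, 8), libsize_sdlog = 0)
  sim <- simulate_cross(cfg)
  mu_hat <- rowMeans(sim$counts)
  v_hat <- apply(sim$counts, 1, var)
  expect_lt(max(abs(mu_hat / 256 - 1)), 0.15)
  # var ~ mu + phi mu^2 = 256 + 0.1 * 256^2 ~ 6810
  expected_var <- 256 + 0.1 * 256^2
  expect_lt(median(abs(v_hat / expected_var - 1)), 0.25)
})

test_that("reciprocal heterozygotes differ only through parent of origin", {
  cfg <- quick_config(n_genes = 50, seed = 8, prop_line_diff = 1,
                      prop_poe = 1, poe_range = c(0.6, 0.6),
                      prop_sex_line_inter = 0, prop_sex_biased = 0,
                      dispersion_meanlog = log(1e-7), dispersion_sdlog = 1e-3,
                      baseline_log2_range = c(16, 18), libsize_sdlog = 0)
  sim <- simulate_cross(cfg)
  s <- sim$samples
  for (sex in c("female", "male")) {
    ab <- rowMeans(sim$counts[, s$sample_id[s$genotype == "AB" &
                                              s$sex == sex]])
    ba <- rowMeans(sim$counts[, s$sample_id[s$genotype == "BA" &
                                              s$sex == sex]])
    # dam B direction is e^{+poe/2}, dam A is e^{-poe/2}: ratio e^{poe}
    expect_lt(max(abs(log(ba / ab) - sign(sim$truth$poe) * 0.6)), 0.05)
  }
})

test_that("mis-sexed samples are generated with the swapped sex", {
  cfg <- quick_config(n_genes = 300, seed = 9, n_mis_sexed = 2)
  sim <- simulate_cross(cfg)
  expect_length(sim$mis_sexed, 2L)
  sf <- size_factors(sim$counts)
  p <- pca_samples(vst(sim$counts, sf))
  sx <- sim$samples$sex[match(rownames(p$scores), sim$samples$sample_id)]
  ctr_f <- mean(p$scores[sx == "female", 1])
  ctr_m <- mean(p$scores[sx == "male", 1])
  for (id in sim$mis_sexed) {
    sc <- p$scores[id, 1]
    annotated <- sx[rownames(p$scores) == id]
    wrong_ctr <- if (annotated == "female") ctr_m else ctr_f
    right_ctr <- if (annotated == "female") ctr_f else ctr_m
    expect_lt(abs(sc - wrong_ctr), abs(sc - right_ctr))
  }
})

test_that("truth recovery report: near-noiseless data gives near-zero bias", {
  cfg <- quick_config(n_genes = 80, seed = 10, prop_line_diff = 1,
                      prop_ssd = 0.3, prop_poe = 0, prop_sex_line_inter = 0,
                      prop_sex_biased = 0,
                      dispersion_meanlog = log(1e-7), dispersion_sdlog = 1e-3,
                      baseline_log2_range = c(12, 14), libsize_sdlog = 0)
  sim <- simulate_cross(cfg)
  # unit library sizes in the config: raw counts are already normalized
  norm <- sim$counts
  hl <- orient_alleles(norm, sim$samples, c("A", "B"))
  d <- estimate_delta(norm, sim$samples, hl, c("A", "B"))
  results <- data.frame(gene_id = d$gene_id, cross_id = "I",
                        delta_f = d$delta_f, delta_m = d$delta_m,
                        q_sexdom = NA_real_)
  rep <- truth_recovery_report(sim$truth, results)
  expect_lt(abs(rep$bias[["delta_f"]]), 0.02)
  expect_lt(abs(rep$bias[["delta_m"]]), 0.02)

  results$gene_id[1] <- "nope"
  expect_error(truth_recovery_report(sim$truth, results), "not present")
})
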