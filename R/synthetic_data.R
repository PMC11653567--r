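#' Configuration for the synthetic reciprocal-cross generator
#'
#' Defaults emulate the study design the analysis assumes: per cross, 4
#' genotypes (two homozygous parental lines plus the two reciprocal
#' heterozygotes) x 2 sexes x `n_reps` replicates of pooled-abdomen RNA-seq
#' counts; genome-wide strong sex-biased expression (about half of all
#' transcripts, with large fold changes so that PC1 of the transformed
#' counts separates the sexes); parental-line expression differences in
#' about half of all genes, a minority of which carry sex-specific additive
#' effects; sex-specific dominance in a small fraction of line-different
#' genes; rare parent-of-origin effects; X hemizygosity in males; male-only
#' Y expression; and optionally whole-sample sex mislabels.
#'
#' All effect magnitudes are in log2 units except the dominance
#' coefficients `delta`, which are injected on the natural scale relative
#' to the arithmetic midparent (0 = additive), and the parent-of-origin
#' effect, a natural-log shift of +/- poe/2 between the two reciprocal
#' heterozygote directions.
#'
#' @param n_genes Number of transcripts per cross.
#' @param n_reps Replicates per (genotype, sex) cell.
#' @param crosses List of length-2 character vectors of parental line
#'   labels, one per cross; the default mirrors the three-cross study
#'   design (per-gene effects are drawn independently per cross, so the
#'   crosses expose distinct regulatory variants).
#' @param prop_sex_biased Fraction of genes with sex-biased expression.
#' @param sex_effect_range Range of |log2 female/male| for biased genes.
#' @param prop_line_diff Fraction of genes with a parental-line difference.
#' @param additive_range Range of the absolute between-line log2 fold
#'   change for line-different genes; the two homozygotes sit at baseline
#'   times 2^(+/- effect / 2).
#' @param prop_sex_line_inter Fraction of line-different genes whose
#'   additive effect differs between the sexes (drawn independently per
#'   sex; these should fail the sex-concordance filter).
#' @param prop_ssd Fraction of line-different genes with sex-specific
#'   dominance (`delta_f != delta_m`).
#' @param delta_sd Standard deviation of the shared dominance coefficient
#'   for sexually concordant genes, Normal truncated to `|delta| <=
#'   delta_max`.
#' @param delta_max Truncation bound for dominance coefficients.
#' @param ssd_delta_range Range of |delta_f - delta_m| for SSD genes.
#' @param prop_poe Fraction of line-different genes with a parent-of-origin
#'   effect.
#' @param poe_range Range of the natural-log reciprocal shift `poe`.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   per-gene NB dispersion; the default median 0.02 reflects pools of six
#'   isogenic individuals per sample.
#' @param baseline_log2_range Range of baseline log2 mean counts.
#' @param libsize_sdlog Log-normal sd of per-sample library size factors.
#' @param prop_x_linked,prop_y_linked Fractions of X- and Y-linked genes.
#' @param n_mis_sexed Number of whole samples generated with the opposite
#'   sex to their annotation.
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_reps = 3L,
                       crosses = list(c("A", "B"), c("C", "D"),
                                      c("E", "F")),
                       prop_sex_biased = 0.5,
                       sex_effect_range = c(0.5, 10),
                       prop_line_diff = 0.5,
                       additive_range = c(0.25, 2),
                       prop_sex_line_inter = 0.3,
                       prop_ssd = 0.08,
                       delta_sd = 0.3,
                       delta_max = 1.2,
                       ssd_delta_range = c(0.5, 1.5),
                       prop_poe = 0.02,
                       poe_range = c(0.2, 0.8),
                       dispersion_meanlog = log(0.02),
                       dispersion_sdlog = 0.6,
                       baseline_log2_range = c(2, 10),
                       libsize_sdlog = 0.3,
                       prop_x_linked = 0.13,
                       prop_y_linked = 0.02,
                       n_mis_sexed = 0L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
              crosses = crosses,
              prop_sex_biased = prop_sex_biased,
              sex_effect_range = sex_effect_range,
              prop_line_diff = prop_line_diff,
              additive_range = additive_range,
              prop_sex_line_inter = prop_sex_line_inter,
              prop_ssd = prop_ssd,
              delta_sd = delta_sd, delta_max = delta_max,
              ssd_delta_range = ssd_delta_range,
              prop_poe = prop_poe, poe_range = poe_range,
              dispersion_meanlog = dispersion_meanlog,
              dispersion_sdlog = dispersion_sdlog,
              baseline_log2_range = baseline_log2_range,
              libsize_sdlog = libsize_sdlog,
              prop_x_linked = prop_x_linked,
              prop_y_linked = prop_y_linked,
              n_mis_sexed = as.integer(n_mis_sexed),
              seed = as.integer(seed))
  props <- c("prop_sex_biased", "prop_line_diff", "prop_sex_line_inter",
             "prop_ssd", "prop_poe", "prop_x_linked", "prop_y_linked")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("config error: ", p, " must be a proportion in [0, 1]")
  }
  if (cfg$prop_x_linked + cfg$prop_y_linked > 1)
    stop("config error: prop_x_linked + prop_y_linked exceeds 1")
  for (p in c("sex_effect_range", "additive_range", "ssd_delta_range",
              "poe_range", "baseline_log2_range")) {
    v <- cfg[[p]]
    if (length(v) != 2L || any(v < 0) || v[2] < v[1])
      stop("config error: ", p, " must be an increasing pair of ",
           "non-negative scales")
  }
  if (cfg$delta_sd < 0 || cfg$delta_max < 0 || cfg$libsize_sdlog < 0)
    stop("config error: scales must be >= 0")
  if (cfg$ssd_delta_range[2] > 2 * cfg$delta_max)
    stop("config error: ssd_delta_range incompatible with delta_max")
  if (cfg$n_genes < 1L || cfg$n_reps < 1L)
    stop("config error: n_genes and n_reps must be positive")
  structure(cfg, class = "sim_config")
}

#' @noRd
runif_signed <- function(n, range) {
  sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, range[1], range[2])
}

#' Simulate reciprocal-cross RNA-seq counts with known truth
#'
#' Draws negative-binomial counts whose log-scale means are a library-size
#' offset plus baseline, sex, and genotype contributions. For heterozygotes
#' of sex s the expected normalized expression is the arithmetic midparent
#' of that sex times `exp(delta_s)`, multiplied by `exp(+/- poe/2)` for the
#' two reciprocal directions (the + sign when the dam is the line written
#' second in the cross's line pair). Autosomal homozygotes sit at baseline
#' times `2^(+/- additive effect)`. X-linked genes in males take the dam
#' line's expression level (hemizygosity); Y-linked genes are expressed in
#' males only. Mis-sexed samples are generated with the swapped sex while
#' keeping the annotated sex.
#'
#' @param config A [sim_config()].
#' @return List with elements `counts` (integer matrix), `samples` (sample
#'   table), `genes` (annotation table), `truth` (per gene x cross true
#'   parameters) and `mis_sexed` (character vector of mislabeled sample
#'   ids).
#' @export
simulate_cross <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ng <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(ng))

  # gene-level properties: shared across crosses (it is the same genome)
  classes <- sample(c("X", "Y", "autosome"), ng, replace = TRUE,
                    prob = c(config$prop_x_linked, config$prop_y_linked,
                             1 - config$prop_x_linked - config$prop_y_linked))
  genes <- data.frame(gene_id = gene_ids, chrom_class = classes,
                      stringsAsFactors = FALSE)
  baseline_log2 <- stats::runif(ng, config$baseline_log2_range[1],
                                config$baseline_log2_range[2])
  sex_biased <- stats::runif(ng) < config$prop_sex_biased
  sex_effect <- ifelse(sex_biased,
                       runif_signed(ng, config$sex_effect_range), 0)
  dispersion <- stats::rlnorm(ng, config$dispersion_meanlog,
                              config$dispersion_sdlog)

  all_counts <- NULL
  all_samples <- NULL
  truth_list <- list()

  for (ci in seq_along(config$crosses)) {
    lines <- config$crosses[[ci]]
    cross_id <- as.roman(ci)
    # line-level properties: each cross segregates its own variants
    tr <- data.frame(gene_id = gene_ids, cross = as.character(cross_id),
                     chrom_class = classes, stringsAsFactors = FALSE)
    tr$baseline_log2 <- baseline_log2
    tr$sex_biased <- sex_biased
    tr$sex_effect <- sex_effect
    tr$line_diff <- stats::runif(ng) < config$prop_line_diff
    beta <- ifelse(tr$line_diff, runif_signed(ng, config$additive_range), 0)
    tr$sex_line_inter <- tr$line_diff &
      stats::runif(ng) < config$prop_sex_line_inter
    tr$beta_a_f <- beta
    tr$beta_a_m <- beta
    inter <- which(tr$sex_line_inter)
    tr$beta_a_f[inter] <- runif_signed(length(inter), config$additive_range)
    tr$beta_a_m[inter] <- runif_signed(length(inter), config$additive_range)

    tr$ssd <- tr$line_diff & stats::runif(ng) < config$prop_ssd
    d0 <- stats::rnorm(ng, 0, config$delta_sd)
    d0 <- pmax(pmin(d0, config$delta_max), -config$delta_max)
    tr$delta_f <- ifelse(tr$line_diff, d0, 0)
    tr$delta_m <- tr$delta_f
    sg <- which(tr$ssd)
    if (length(sg) > 0L) {
      gap <- runif_signed(length(sg), config$ssd_delta_range)
      ctr <- stats::rnorm(length(sg), 0, config$delta_sd / 2)
      lim <- config$delta_max - abs(gap) / 2
      ctr <- pmax(pmin(ctr, lim), -lim)
      tr$delta_f[sg] <- ctr + gap / 2
      tr$delta_m[sg] <- ctr - gap / 2
    }
    tr$poe_flag <- tr$line_diff & stats::runif(ng) < config$prop_poe
    tr$poe <- ifelse(tr$poe_flag, runif_signed(ng, config$poe_range), 0)
    tr$dispersion <- dispersion
    # X-linked males are hemizygous: no male heterozygote, no male delta
    tr$delta_m[tr$chrom_class == "X"] <- NA_real_

    genotypes <- c(paste0(lines[1], lines[1]), paste0(lines[2], lines[2]),
                   paste0(lines[1], lines[2]), paste0(lines[2], lines[1]))
    cells <- expand.grid(replicate = seq_len(config$n_reps),
                         sex = c("female", "male"), genotype = genotypes,
                         stringsAsFactors = FALSE)
    cells$dam <- substr(cells$genotype, 1L, 1L)
    cells$sire <- substr(cells$genotype, 2L, 2L)
    cells$cross <- as.character(cross_id)
    cells$sample_id <- sprintf("%s_%s_%s_r%d", cells$cross, cells$genotype,
                               ifelse(cells$sex == "female", "F", "M"),
                               cells$replicate)
    samples <- make_sample_table(cells[, c("sample_id", "sex", "dam",
                                           "sire", "cross", "replicate")])
    lib <- stats::rlnorm(nrow(samples), 0, config$libsize_sdlog)
    lib <- lib / exp(mean(log(lib)))

    mu <- matrix(0, nrow = ng, ncol = nrow(samples),
                 dimnames = list(gene_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      gen_sex <- samples$sex[j]
      mu[, j] <- lib[j] * expected_expression(tr, lines, gen_sex,
                                              samples$dam[j],
                                              samples$sire[j])
    }
    # swap the generating sex of mislabeled samples, keep annotation
    mis <- character(0)
    if (config$n_mis_sexed > 0L) {
      mis_idx <- sample(nrow(samples), min(config$n_mis_sexed,
                                           nrow(samples)))
      mis <- samples$sample_id[mis_idx]
      for (j in mis_idx) {
        swapped <- if (samples$sex[j] == "female") "male" else "female"
        mu[, j] <- lib[j] * expected_expression(tr, lines, swapped,
                                                samples$dam[j],
                                                samples$sire[j])
      }
    }
    size <- 1 / pmax(tr$dispersion, 1e-12)
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = rep(size, times = ncol(mu))),
                     nrow = ng, dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"
    tr$lib_size <- NA_real_
    truth_list[[ci]] <- tr
    all_counts <- if (is.null(all_counts)) counts else
      cbind(all_counts, counts)
    samples$mis_sexed_truth <- samples$sample_id %in% mis
    all_samples <- if (is.null(all_samples)) samples else
      rbind(all_samples, samples)
  }
  truth <- do.call(rbind, lapply(truth_list, function(x)
    x[, setdiff(colnames(x), "lib_size")]))
  rownames(truth) <- NULL
  mis_all <- all_samples$sample_id[all_samples$mis_sexed_truth]
  list(counts = validate_counts(all_counts),
       samples = all_samples[, setdiff(colnames(all_samples),
                                       "mis_sexed_truth")],
       genes = genes, truth = truth, mis_sexed = mis_all)
}

#' Expected normalized expression for every gene in one design cell
#'
#' @param tr Truth table for one cross.
#' @param lines Character pair; `lines[2]` carries the `+` additive sign
#'   and the `+poe/2` reciprocal direction when it is the dam.
#' @param sex Generating sex.
#' @param dam,sire Parental line labels of the cell.
#' @return Numeric vector of expected normalized means.
#' @noRd
expected_expression <- function(tr, lines, sex, dam, sire) {
  half_sex <- ifelse(sex == "female", 0.5, -0.5)
  mu0 <- 2^(tr$baseline_log2 + half_sex * tr$sex_effect)
  beta <- if (sex == "female") tr$beta_a_f else tr$beta_a_m
  mu_lo <- mu0 * 2^(-beta / 2)   # homozygote for lines[1]
  mu_hi <- mu0 * 2^(+beta / 2)   # homozygote for lines[2]
  if (dam == sire) {
    mu <- if (dam == lines[1]) mu_lo else mu_hi
  } else {
    delta <- if (sex == "female") tr$delta_f else tr$delta_m
    mid <- (mu_lo + mu_hi) / 2
    poe_sign <- if (dam == lines[2]) +0.5 else -0.5
    mu <- mid * exp(ifelse(is.na(delta), 0, delta)) * exp(poe_sign * tr$poe)
    if (sex == "male") {
      x <- tr$chrom_class == "X"   # hemizygous: expression follows the dam
      mu[x] <- if (dam == lines[1]) mu_lo[x] else mu_hi[x]
    }
  }
  y <- tr$chrom_class == "Y"
  if (sex == "female") mu[y] <- 0
  mu
}

#' Summarize parameter recovery against the generator's truth
#'
#' @param truth Truth table from [simulate_cross()].
#' @param results Per-transcript results with columns `gene_id`, `cross_id`,
#'   `delta_f`, `delta_m` and `q_sexdom`.
#' @param q_cutoff q-value threshold for calling sex-specific dominance.
#' @return List with per-parameter `bias` and `rmse` (over genes where both
#'   truth and estimate are finite) and the SSD `confusion` matrix.
#' @export
truth_recovery_report <- function(truth, results, q_cutoff = 0.05) {
  key_t <- paste(truth$gene_id, truth$cross)
  key_r <- paste(results$gene_id, results$cross_id)
  if (!all(key_r %in% key_t))
    stop("gene/cross ids in results not present in truth")
  m <- match(key_r, key_t)
  tru <- truth[m, , drop = FALSE]
  stats_for <- function(est, true) {
    ok <- is.finite(est) & is.finite(true)
    if (!any(ok)) return(c(bias = NA_real_, rmse = NA_real_, n = 0))
    e <- est[ok] - true[ok]
    c(bias = mean(e), rmse = sqrt(mean(e^2)), n = sum(ok))
  }
  bias_rmse <- rbind(delta_f = stats_for(results$delta_f, tru$delta_f),
                     delta_m = stats_for(results$delta_m, tru$delta_m))
  called <- !is.na(results$q_sexdom) & results$q_sexdom <= q_cutoff
  confusion <- table(truth_ssd = factor(tru$ssd, c(FALSE, TRUE)),
                     called_ssd = factor(called, c(FALSE, TRUE)))
  list(bias = bias_rmse[, "bias"], rmse = bias_rmse[, "rmse"],
       n = bias_rmse[, "n"], confusion = confusion)
}
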