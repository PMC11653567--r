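#' Orient each gene so that "BB" is the higher-expressed parental line
#'
#' The dominance coefficient always refers to the allele conferring the
#' higher homozygous expression, so per gene the parental line with the
#' higher pooled-sex normalized mean is designated the high ("BB") line.
#' Exact ties are broken deterministically towards the lexicographically
#' larger line label.
#'
#' @param norm Normalized count matrix (counts / size factors).
#' @param samples Sample table for one cross (excluded samples dropped).
#' @param lines Character pair of parental line labels.
#' @return Character vector (per gene) naming the high line.
#' @export
orient_alleles <- function(norm, samples, lines) {
  lines <- sort(lines)
  hom1 <- samples$sample_id[samples$genotype == paste0(lines[1], lines[1])]
  hom2 <- samples$sample_id[samples$genotype == paste0(lines[2], lines[2])]
  m1 <- rowMeans(norm[, hom1, drop = FALSE])
  m2 <- rowMeans(norm[, hom2, drop = FALSE])
  high <- ifelse(m2 >= m1, lines[2], lines[1])
  ties <- sum(m1 == m2)
  if (ties > 0L)
    message(sprintf(
      "%d exact parental-mean tie(s) oriented to line '%s'", ties,
      lines[2]))
  stats::setNames(high, rownames(norm))
}

#' Two-step focal-transcript filter on parental samples
#'
#' Step 1 keeps transcripts with a significant expression difference
#' between the two parental homozygous lines (1-df LRT of the line main
#' effect; only such transcripts are informative about dominance). Step 2
#' removes transcripts whose parental line difference is not sexually
#' concordant (1-df LRT of the sex-by-line interaction, tested among step-1
#' survivors). Both steps use homozygous samples only and q-values at
#' `q_cutoff` over the respective tested set.
#'
#' @param counts Count matrix (one cross, one chromosome class).
#' @param samples Sample table; only homozygous, non-excluded samples are
#'   used.
#' @param sf Size factors for all samples in `counts`.
#' @param lines Parental line pair.
#' @param q_cutoff q-value threshold.
#' @param phi Optional per-gene dispersions (estimated once under the
#'   saturated full-cross design and shared by all tests on a gene, as in
#'   standard count-model practice); estimated from the parental samples
#'   when missing.
#' @return Data frame with per-gene `p_line`, `q_line`, `p_sex_line`,
#'   `q_sex_line`, `parental_DE_pass`, `sex_concordance_pass`, `focal`.
#' @export
focal_filter <- function(counts, samples, sf = size_factors(counts),
                         lines, q_cutoff = 0.05, phi = NULL) {
  lines <- sort(lines)
  par <- samples[samples$homozygous & !samples$excluded, , drop = FALSE]
  idx <- match(par$sample_id, colnames(counts))
  offset <- log(sf[idx])
  sex <- ifelse(par$sex == "female", 1, -1)
  line <- ifelse(par$dam == lines[2], 1, -1)
  X <- cbind(intercept = 1, sex = sex, line = line, sex_line = sex * line)
  ng <- nrow(counts)
  p_line <- p_sex_line <- rep(NA_real_, ng)
  for (g in seq_len(ng)) {
    y <- counts[g, idx]
    phi_g <- if (!is.null(phi)) phi[g] else
      tryCatch(as.numeric(estimate_dispersion(y, X, offset)),
               error = function(e) NA_real_)
    if (is.na(phi_g)) next
    step2 <- tryCatch(nb_lrt_fit(y, X, "sex_line", offset, phi_g),
                      error = function(e) NULL)
    if (is.null(step2)) next
    red_main <- fit_nb(y, X[, c("intercept", "sex", "line")], offset,
                       phi_g)
    red_noline <- fit_nb(y, X[, c("intercept", "sex")], offset, phi_g)
    p_line[g] <- nb_lrt(red_main, red_noline, df = 1)$p
    p_sex_line[g] <- step2$p
  }
  q_line <- storey_qvalue(p_line)
  pass1 <- !is.na(q_line) & q_line <= q_cutoff
  q_sex_line <- rep(NA_real_, ng)
  q_sex_line[pass1] <- storey_qvalue(p_sex_line[pass1])
  concord <- !pass1 | is.na(q_sex_line) | q_sex_line > q_cutoff
  data.frame(gene_id = rownames(counts), p_line = p_line, q_line = q_line,
             p_sex_line = p_sex_line, q_sex_line = q_sex_line,
             parental_DE_pass = pass1,
             sex_concordance_pass = concord,
             focal = pass1 & concord,
             stringsAsFactors = FALSE)
}

#' Dominance coefficient from normalized group means
#'
#' For each sex s, `delta_s = ln(het_s / ((AA_s + BB_s) / 2))`, where the
#' heterozygote mean pools the two reciprocal directions and AA/BB are the
#' oriented parental homozygote means of that sex. Zero midparent or zero
#' heterozygote mean yields NA (flagged by the caller; cannot occur for
#' focal transcripts passing the low-count filter).
#'
#' @param norm Normalized count matrix.
#' @param samples Sample table (one cross, excluded dropped).
#' @param high_line Per-gene high line labels from [orient_alleles()].
#' @param lines Parental line pair.
#' @param sexes Sexes to estimate for (X-linked genes: `"female"` only).
#' @return Data frame with `delta_f`, `delta_m` and the per-sex group
#'   means `het_f`, `het_m`, `mid_f`, `mid_m`.
#' @export
estimate_delta <- function(norm, samples, high_line, lines,
                           sexes = c("female", "male")) {
  lines <- sort(lines)
  out <- data.frame(gene_id = rownames(norm),
                    delta_f = NA_real_, delta_m = NA_real_,
                    het_f = NA_real_, het_m = NA_real_,
                    mid_f = NA_real_, mid_m = NA_real_,
                    stringsAsFactors = FALSE)
  for (s in sexes) {
    ss <- samples[samples$sex == s & !samples$excluded, , drop = FALSE]
    het_ids <- ss$sample_id[!ss$homozygous]
    hom1 <- ss$sample_id[ss$genotype == paste0(lines[1], lines[1])]
    hom2 <- ss$sample_id[ss$genotype == paste0(lines[2], lines[2])]
    het <- rowMeans(norm[, het_ids, drop = FALSE])
    m1 <- rowMeans(norm[, hom1, drop = FALSE])
    m2 <- rowMeans(norm[, hom2, drop = FALSE])
    mid <- (m1 + m2) / 2
    delta <- ifelse(mid > 0 & het > 0, log(het / mid), NA_real_)
    suffix <- if (s == "female") "f" else "m"
    out[[paste0("delta_", suffix)]] <- delta
    out[[paste0("het_", suffix)]] <- het
    out[[paste0("mid_", suffix)]] <- mid
  }
  out
}

#' Change in sex-biased expression among heterozygotes
#'
#' Compares the absolute log2 sex difference of the heterozygote means
#' (`D_het`) with that of the midparent (`D_mid`): `"greater"` when
#' heterozygotes are more sexually dimorphic than expected under
#' additivity, `"lesser"` when less, `"equal"` on an exact tie.
#'
#' @param het_f,het_m,mid_f,mid_m Normalized group means.
#' @return List with `label`, `d_het`, `d_mid` (NA label on zero means).
#' @export
sb_change_in_hets <- function(het_f, het_m, mid_f, mid_m) {
  if (any(c(het_f, het_m, mid_f, mid_m) <= 0) ||
      anyNA(c(het_f, het_m, mid_f, mid_m)))
    return(list(label = NA_character_, d_het = NA_real_, d_mid = NA_real_))
  d_het <- abs(log2(het_f / het_m))
  d_mid <- abs(log2(mid_f / mid_m))
  label <- if (d_het > d_mid) "greater" else
           if (d_het < d_mid) "lesser" else "equal"
  list(label = label, d_het = d_het, d_mid = d_mid)
}

#' Classify one transcript's dominance pattern
#'
#' Per sex: `"dominant"` when `delta > 0` with nonadditivity `q <=
#' q_cutoff`, `"recessive"` when `delta < 0` with `q <= q_cutoff`, else
#' `"additive"`. Sex-specific dominance (SSD) requires the
#' sex-by-dominance interaction `q <= q_cutoff`; a reversal additionally
#' requires opposite signs of the two delta estimates.
#'
#' @param delta_f,delta_m Dominance coefficients.
#' @param q_nonadd_f,q_nonadd_m Per-sex nonadditivity q-values.
#' @param q_sexdom Sex-by-dominance interaction q-value.
#' @param q_cutoff Threshold.
#' @return List with `class_f`, `class_m`, `ssd`, `reversal`.
#' @export
classify_dominance <- function(delta_f, delta_m, q_nonadd_f, q_nonadd_m,
                               q_sexdom, q_cutoff = 0.05) {
  one <- function(delta, q) {
    if (is.na(delta) || is.na(q) || q > q_cutoff) return("additive")
    if (delta > 0) "dominant" else if (delta < 0) "recessive" else "additive"
  }
  ssd <- !is.na(q_sexdom) && q_sexdom <= q_cutoff
  reversal <- ssd && !is.na(delta_f) && !is.na(delta_m) &&
    delta_f != 0 && delta_m != 0 && sign(delta_f) != sign(delta_m)
  list(class_f = one(delta_f, q_nonadd_f),
       class_m = one(delta_m, q_nonadd_m),
       ssd = ssd, reversal = reversal)
}

#' Per-transcript dominance inference for one cross and chromosome class
#'
#' Runs the full inference battery on every focal transcript: the joint
#' NB model (intercept, sex, additive, dominance, parent-of-origin and
#' their sex interactions, with log size-factor offsets and a per-gene
#' Cox-Reid dispersion held fixed across nested fits), the 1-df
#' sex-by-dominance LRT, per-sex nonadditivity LRTs (dropping the
#' dominance term within each sex), per-sex parent-of-origin LRTs, the
#' dominance coefficients from normalized group means, the sex-bias log2
#' fold change (positive = female-biased), and the classification labels.
#' For X-linked genes males are hemizygous (no male heterozygote class),
#' so dominance is assessed in females only and no sex-by-dominance test
#' is performed.
#'
#' @param counts Count matrix for one cross and chromosome class
#'   (Y-linked and low-expression transcripts already removed).
#' @param samples Sample table for the cross.
#' @param sf Size factors (named by sample id, covering `counts`).
#' @param lines Parental line pair.
#' @param chrom_class `"autosome"` or `"X"`.
#' @param q_cutoff q-value threshold used throughout.
#' @param focal Optional precomputed [focal_filter()] table.
#' @param phi Optional per-gene dispersions; estimated once per gene under
#'   the saturated full-cross design when missing, and shared by every
#'   nested test on that gene.
#' @return A `data.frame` with one row per transcript (the
#'   DominanceResult layout used by [write_results()]).
#' @export
run_dominance <- function(counts, samples, sf, lines,
                          chrom_class = c("autosome", "X"),
                          q_cutoff = 0.05, focal = NULL, phi = NULL) {
  chrom_class <- match.arg(chrom_class)
  lines <- sort(lines)
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  keep <- !samples$excluded
  samples <- samples[keep, , drop = FALSE]
  counts <- counts[, keep, drop = FALSE]
  sf <- sf[match(samples$sample_id, names(sf))]
  norm <- sweep(counts, 2L, sf, "/")

  if (is.null(phi))
    phi <- dispersion_by_gene(counts, samples, sf, lines)
  if (is.null(focal))
    focal <- focal_filter(counts, samples, sf, lines, q_cutoff, phi = phi)
  high_line <- orient_alleles(norm, samples, lines)
  sexes <- if (chrom_class == "X") "female" else c("female", "male")
  deltas <- estimate_delta(norm, samples, high_line, lines, sexes)

  ng <- nrow(counts)
  res <- data.frame(
    gene_id = rownames(counts),
    cross_id = samples$cross[1L],
    chrom_class = chrom_class,
    high_line = unname(high_line),
    focal = focal$focal,
    parental_DE_pass = focal$parental_DE_pass,
    sex_concordance_pass = focal$sex_concordance_pass,
    delta_f = deltas$delta_f, delta_m = deltas$delta_m,
    beta_h = NA_real_, dispersion = NA_real_,
    p_nonadd_f = NA_real_, p_nonadd_m = NA_real_,
    p_sexdom = NA_real_, p_poe_f = NA_real_, p_poe_m = NA_real_,
    lfc_sex = NA_real_, d_het = NA_real_, d_mid = NA_real_,
    sb_change = NA_character_,
    converged = NA, stringsAsFactors = FALSE)

  sex_code <- ifelse(samples$sex == "female", 1, -1)
  offset_all <- log(sf)

  for (g in which(focal$focal & !is.na(phi))) {
    y <- counts[g, ]
    # oriented design: relabel lines so the gene's high line is "BB"
    lp <- if (high_line[g] == lines[2]) lines else rev(lines)
    fit <- try_gene_fit(y, samples, lp, offset_all, sex_code, chrom_class,
                        phi[g])
    if (is.null(fit)) { res$converged[g] <- FALSE; next }
    res$converged[g] <- fit$converged
    res$dispersion[g] <- fit$phi
    res$beta_h[g] <- fit$beta_h
    res$p_sexdom[g] <- fit$p_sexdom
    res$p_nonadd_f[g] <- fit$p_nonadd["female"]
    res$p_nonadd_m[g] <- fit$p_nonadd["male"]
    res$p_poe_f[g] <- fit$p_poe["female"]
    res$p_poe_m[g] <- fit$p_poe["male"]
    res$lfc_sex[g] <- fit$lfc_sex
    sb <- sb_change_in_hets(deltas$het_f[g], deltas$het_m[g],
                            deltas$mid_f[g], deltas$mid_m[g])
    res$d_het[g] <- sb$d_het
    res$d_mid[g] <- sb$d_mid
    res$sb_change[g] <- sb$label
  }

  # multiplicity correction within this cross x chromosome class
  usable <- res$focal & !is.na(res$converged) & res$converged
  qcol <- function(p) {
    q <- rep(NA_real_, ng)
    q[usable] <- storey_qvalue(p[usable])
    q
  }
  res$q_nonadd_f <- qcol(res$p_nonadd_f)
  res$q_nonadd_m <- qcol(res$p_nonadd_m)
  res$q_sexdom <- qcol(res$p_sexdom)
  res$q_poe_f <- qcol(res$p_poe_f)
  res$q_poe_m <- qcol(res$p_poe_m)
  res$poe_sex_consistent <- !is.na(res$q_poe_f) & res$q_poe_f <= q_cutoff &
    !is.na(res$q_poe_m) & res$q_poe_m <= q_cutoff

  res$class_f <- res$class_m <- NA_character_
  res$ssd <- res$reversal <- NA
  for (g in which(usable)) {
    cl <- classify_dominance(res$delta_f[g], res$delta_m[g],
                             res$q_nonadd_f[g], res$q_nonadd_m[g],
                             res$q_sexdom[g], q_cutoff)
    res$class_f[g] <- cl$class_f
    res$class_m[g] <- cl$class_m
    res$ssd[g] <- cl$ssd
    res$reversal[g] <- cl$reversal
  }
  if (chrom_class == "X") {
    # hemizygous males: no male dominance call, no sex x dominance test
    res$class_m <- NA_character_
    res$ssd <- NA
    res$reversal <- NA
  }
  res
}

#' Per-gene dispersion under the saturated cross design
#'
#' The saturated 4-genotype x 2-sex design spans every pattern of group
#' means (including X hemizygosity), so the Cox-Reid estimate is
#' orientation-free and valid for all downstream nested tests.
#' @noRd
dispersion_by_gene <- function(counts, samples, sf, lines) {
  X <- cross_design(samples, sort(lines))
  offset <- log(sf)
  vapply(seq_len(nrow(counts)), function(g) {
    tryCatch(as.numeric(estimate_dispersion(counts[g, ], X, offset)),
             error = function(e) NA_real_)
  }, numeric(1))
}

#' Fit the full per-gene model battery, trapping failures
#' @noRd
try_gene_fit <- function(y, samples, lines_oriented, offset, sex_code,
                         chrom_class, phi) {
  tryCatch({
    out <- list(phi = phi)
    if (chrom_class == "autosome") {
      X <- cross_design(samples, lines_oriented)
      sd_test <- nb_lrt_fit(y, X, "sex_h", offset, phi)
      out$beta_h <- unname(sd_test$fit_full$coef["h"])
      out$p_sexdom <- sd_test$p
      out$converged <- sd_test$ok && sd_test$fit_full$converged
    } else {
      # X-linked: no male heterozygote class; dominance in females only
      fem <- samples$sex == "female"
      Xf <- cross_design(samples[fem, ], lines_oriented)
      Xf <- Xf[, c("intercept", "a", "h", "p"), drop = FALSE]
      ff <- fit_nb(y[fem], Xf, offset[fem], phi)
      out$beta_h <- unname(ff$coef["h"])
      out$p_sexdom <- NA_real_
      out$converged <- ff$converged
    }
    out$p_nonadd <- c(female = NA_real_, male = NA_real_)
    out$p_poe <- c(female = NA_real_, male = NA_real_)
    sexes <- if (chrom_class == "X") "female" else c("female", "male")
    for (s in sexes) {
      sel <- samples$sex == s
      Xs <- cross_design(samples[sel, ], lines_oriented)
      Xs <- Xs[, c("intercept", "a", "h", "p"), drop = FALSE]
      out$p_nonadd[s] <- nb_lrt_fit(y[sel], Xs, "h", offset[sel],
                                    out$phi)$p
      out$p_poe[s] <- nb_lrt_fit(y[sel], Xs, "p", offset[sel],
                                 out$phi)$p
    }
    # sex-bias log2 fold change from the two-group NB fit (+ = female)
    Xsex <- cbind(intercept = 1, sex = sex_code)
    sfit <- fit_nb(y, Xsex, offset, out$phi)
    out$lfc_sex <- unname(2 * sfit$coef["sex"] / log(2))
    out
  }, error = function(e) NULL)
}
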