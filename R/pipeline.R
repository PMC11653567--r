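#' Run the full sex-specific dominance pipeline
#'
#' Reproduces the per-cross workflow: Y-linked removal, the per-sex
#' low-count filter, normalization, PCA-based mis-sexed sample flagging
#' and exclusion, the two-step focal filter, per-gene dominance inference
#' (separately for autosomal and X-linked transcripts), the post-hoc
#' statistics (major-axis regression of female on male dominance,
#' greater/lesser sex-bias chi-square, directional KS, Fisher's exact
#' association of sex-bias direction with sex-specific dominance) and,
#' when a GO map is supplied, GO over-representation of the SSD set
#' against the cross's focal set. All analytical steps run separately for
#' each cross; q-values are computed separately per cross and chromosome
#' class. The pipeline is deterministic: rerunning on the same inputs
#' reproduces every number.
#'
#' @param counts Count matrix covering all crosses.
#' @param samples Sample table (see [read_samples()]).
#' @param genes Gene annotation table (chromosome classes).
#' @param go_map Optional gene-to-GO map (see [read_go_map()]).
#' @param q_cutoff q-value threshold used throughout.
#' @param low_count_threshold Mean raw counts per sample below which a
#'   transcript is removed (strict `<`, within every sex).
#' @param low_count_scope Passed to [filter_low_expression()].
#' @param go_min_size Minimum GO term size in the universe.
#' @param exclude_mis_sexed Flag and exclude mis-sexed samples.
#' @param verbose Emit per-step log messages.
#' @return List of class `"ssdom_run"` with one element per cross, each
#'   containing `results` (per-transcript table), `posthoc`, `enrichment`
#'   (or NULL) and `report` (the per-step removal/retention counts).
#' @export
run_pipeline <- function(counts, samples, genes, go_map = NULL,
                         q_cutoff = 0.05, low_count_threshold = 3,
                         low_count_scope = "all_sexes",
                         go_min_size = 5L, exclude_mis_sexed = TRUE,
                         verbose = TRUE) {
  counts <- validate_counts(counts)
  samples <- make_sample_table(samples, counts)
  validate_design(samples)
  say <- function(...) if (verbose) message(sprintf(...))
  out <- list()
  for (cr in unique(samples$cross)) {
    say("== cross %s ==", cr)
    s_cr <- samples[samples$cross == cr, , drop = FALSE]
    c_cr <- counts[, s_cr$sample_id, drop = FALSE]
    lines <- sort(unique(c(s_cr$dam, s_cr$sire)))
    report <- list(cross = cr, n_input = nrow(c_cr))

    c1 <- suppressMessages(filter_y_linked(c_cr, genes))
    report$y_removed <- nrow(c_cr) - nrow(c1)
    say("removed %d Y-linked transcripts", report$y_removed)

    c2 <- suppressMessages(filter_low_expression(
      c1, s_cr, low_count_threshold, low_count_scope))
    report$low_removed <- nrow(c1) - nrow(c2)
    say("removed %d low-expression transcripts, %d remain",
        report$low_removed, nrow(c2))

    flagged <- character(0)
    if (exclude_mis_sexed) {
      sf0 <- size_factors(c2)
      flagged <- detect_mis_sexed(vst(c2, sf0), s_cr)
      s_cr <- exclude_samples(s_cr, flagged, "mis-sexed (PC outlier)")
      say("flagged %d mis-sexed sample(s)%s", length(flagged),
          if (length(flagged)) paste0(": ",
            paste(flagged, collapse = ", ")) else "")
    }
    report$samples_flagged <- flagged
    kept <- s_cr$sample_id[!s_cr$excluded]
    c2 <- c2[, kept, drop = FALSE]
    s_kept <- s_cr[!s_cr$excluded, , drop = FALSE]
    sf <- size_factors(c2)

    cls <- genes$chrom_class[match(rownames(c2), genes$gene_id)]
    res_list <- list()
    for (cc in intersect(c("autosome", "X"), unique(cls))) {
      c_cc <- c2[cls == cc, , drop = FALSE]
      say("analyzing %d %s transcripts", nrow(c_cc), cc)
      phi <- dispersion_by_gene(c_cc, s_kept, sf, lines)
      foc <- focal_filter(c_cc, s_kept, sf, lines, q_cutoff, phi = phi)
      report[[paste0(cc, "_step1_removed")]] <- sum(!foc$parental_DE_pass)
      report[[paste0(cc, "_step2_removed")]] <-
        sum(foc$parental_DE_pass & !foc$sex_concordance_pass)
      report[[paste0(cc, "_focal")]] <- sum(foc$focal)
      say("step 1 removed %d, step 2 removed %d, focal set %d (%s)",
          report[[paste0(cc, "_step1_removed")]],
          report[[paste0(cc, "_step2_removed")]],
          report[[paste0(cc, "_focal")]], cc)
      res_list[[cc]] <- run_dominance(c_cc, s_kept, sf, lines,
                                      chrom_class = cc,
                                      q_cutoff = q_cutoff, focal = foc,
                                      phi = phi)
    }
    results <- do.call(rbind, res_list)
    rownames(results) <- NULL

    auto <- results[results$chrom_class == "autosome", , drop = FALSE]
    report$ssd <- sum(auto$ssd, na.rm = TRUE)
    report$reversal <- sum(auto$reversal, na.rm = TRUE)
    report$class_f <- table(auto$class_f[auto$focal], useNA = "no")
    report$class_m <- table(auto$class_m[auto$focal], useNA = "no")
    report$x_female_nonadditive <- sum(
      results$chrom_class == "X" & results$focal &
        !is.na(results$q_nonadd_f) & results$q_nonadd_f <= q_cutoff)
    say("sex-specific dominance calls: %d (of %d focal autosomal)",
        report$ssd, sum(auto$focal))

    posthoc <- cross_posthoc(auto, q_cutoff)
    enr <- NULL
    if (!is.null(go_map)) {
      universe <- auto$gene_id[auto$focal]
      study <- auto$gene_id[!is.na(auto$ssd) & auto$ssd]
      if (length(study) > 0L && length(universe) > 1L)
        enr <- go_overrepresentation(study, universe, go_map,
                                     min_size = go_min_size)
    }
    out[[cr]] <- list(results = results, posthoc = posthoc,
                      enrichment = enr, report = report,
                      samples = s_cr)
  }
  structure(out, class = "ssdom_run")
}

#' Post-hoc statistics for one cross's autosomal results
#'
#' @param auto Autosomal results table from [run_dominance()].
#' @param q_cutoff q-value threshold.
#' @return List with `ma` (major-axis fit of female on male delta),
#'   `chisq_sb_change`, `ks_sb`, `fisher_sb`, `poe_consistent_fraction`
#'   and the underlying counts.
#' @export
cross_posthoc <- function(auto, q_cutoff = 0.05) {
  foc <- auto[auto$focal, , drop = FALSE]
  ssd <- !is.na(foc$ssd) & foc$ssd
  out <- list()
  ok <- is.finite(foc$delta_m) & is.finite(foc$delta_f)
  out$ma <- if (sum(ok) >= 3L)
    tryCatch(ma_regression(foc$delta_m[ok], foc$delta_f[ok]),
             error = function(e) NULL) else NULL

  lab <- foc$sb_change[ssd]
  k_greater <- sum(lab == "greater", na.rm = TRUE)
  n_cls <- k_greater + sum(lab == "lesser", na.rm = TRUE)
  out$n_greater <- k_greater
  out$n_lesser <- n_cls - k_greater
  out$chisq_sb_change <- if (n_cls > 0L)
    chisq_equal_proportions(k_greater, n_cls) else NULL

  if (any(ssd) && any(!ssd)) {
    out$ks_sb <- ks_plus(abs(foc$lfc_sex[!ssd]), abs(foc$lfc_sex[ssd]))
    fb <- foc$lfc_sex > 0
    tab <- rbind(female_biased = c(sum(fb & ssd, na.rm = TRUE),
                                   sum(fb & !ssd, na.rm = TRUE)),
                 male_biased = c(sum(!fb & ssd, na.rm = TRUE),
                                 sum(!fb & !ssd, na.rm = TRUE)))
    colnames(tab) <- c("ssd", "not_ssd")
    out$fisher_sb <- list(table = tab, p = fisher_exact_2x2(tab))
  } else {
    out$ks_sb <- NULL
    out$fisher_sb <- NULL
  }
  conv <- foc[!is.na(foc$converged) & foc$converged, , drop = FALSE]
  out$poe_consistent_fraction <- if (nrow(conv) > 0L)
    mean(conv$poe_sex_consistent) else NA_real_
  out
}

#' @export
print.ssdom_run <- function(x, ...) {
  for (cr in names(x)) {
    r <- x[[cr]]$report
    cat(sprintf("Cross %s: %d transcripts in\n", cr, r$n_input))
    cat(sprintf("  Y-linked removed:        %d\n", r$y_removed))
    cat(sprintf("  low-expression removed:  %d\n", r$low_removed))
    cat(sprintf("  samples flagged:         %d\n",
                length(r$samples_flagged)))
    for (cc in c("autosome", "X")) {
      key <- paste0(cc, "_focal")
      if (!is.null(r[[key]]))
        cat(sprintf(
          "  %s: step1 -%d, step2 -%d, focal %d\n", cc,
          r[[paste0(cc, "_step1_removed")]],
          r[[paste0(cc, "_step2_removed")]], r[[key]]))
    }
    cat(sprintf("  sex-specific dominance:  %d (reversals %d)\n",
                r$ssd, r$reversal))
    if (!is.null(r$x_female_nonadditive))
      cat(sprintf("  X female-nonadditive:    %d\n",
                  r$x_female_nonadditive))
  }
  invisible(x)
}
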