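#' Remove Y-linked transcripts
#'
#' @param counts Count matrix.
#' @param genes Gene annotation table covering every gene in `counts`.
#' @return Count matrix without Y-class rows, original order preserved.
#' @export
filter_y_linked <- function(counts, genes) {
  missing <- setdiff(rownames(counts), genes$gene_id)
  if (length(missing) > 0L)
    stop("genes without chromosome annotation: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  cls <- genes$chrom_class[match(rownames(counts), genes$gene_id)]
  keep <- cls != "Y"
  message(sprintf("removed %d Y-linked transcript(s), %d remain",
                  sum(!keep), sum(keep)))
  counts[keep, , drop = FALSE]
}

#' Remove transcripts below a mean raw-count threshold in every sex
#'
#' A transcript is removed when its mean raw count per sample is below
#' `threshold` within each sex (`scope = "all_sexes"`, the default), i.e.
#' it is kept as soon as either sex reaches the threshold. This retains
#' strongly sex-limited transcripts, which are expressed in one sex only.
#' `scope = "any_sex"` instead removes a transcript that is low in at
#' least one sex.
#'
#' @param counts Count matrix.
#' @param samples Sample table annotated with sex.
#' @param threshold Mean raw counts per sample (strict `<` comparison).
#' @param scope `"all_sexes"` or `"any_sex"`.
#' @return Filtered count matrix, original order preserved.
#' @export
filter_low_expression <- function(counts, samples, threshold = 3,
                                  scope = c("all_sexes", "any_sex")) {
  scope <- match.arg(scope)
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  sexes <- unique(samples$sex)
  below <- sapply(sexes, function(s) {
    rowMeans(counts[, samples$sex == s, drop = FALSE]) < threshold
  })
  below <- matrix(below, nrow = nrow(counts))
  remove <- if (scope == "all_sexes") rowSums(below) == length(sexes)
            else rowSums(below) > 0L
  message(sprintf("removed %d low-expression transcript(s), %d remain",
                  sum(remove), sum(!remove)))
  counts[!remove, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per gene, the geometric mean across samples forms a pseudo-reference
#' (genes with any zero count are excluded from it); each sample's factor
#' is the median over reference genes of count/reference, rescaled so the
#' factors have geometric mean 1.
#'
#' @param counts Count matrix.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  all_pos <- rowSums(counts == 0L) == 0L
  if (!any(all_pos))
    stop("no gene with all-positive counts; a pseudo-reference over a ",
         "positive subset per sample would be needed for these data")
  ref <- counts[all_pos, , drop = FALSE]
  log_geo <- rowMeans(log(ref))
  sf <- apply(ref, 2L, function(col) exp(stats::median(log(col) - log_geo)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Variance-stabilizing transform of normalized counts
#'
#' Computes `log2(count / size_factor + 1)`, a monotone shifted-log
#' transform used only for sample-level diagnostics (PCA, mis-sexed
#' detection), not for inference.
#'
#' @param counts Count matrix.
#' @param factors Size factors from [size_factors()].
#' @return Matrix of transformed values, same dimensions as `counts`.
#' @export
vst <- function(counts, factors = size_factors(counts)) {
  if (length(factors) != ncol(counts))
    stop("one size factor per sample required")
  log2(sweep(counts, 2L, factors, "/") + 1)
}

#' Principal component analysis of samples
#'
#' Gene-wise centered PCA of the transformed matrix; samples are the
#' observations. Optionally restricted to the `top_n` genes with highest
#' variance across samples.
#'
#' @param trans Transformed matrix (genes x samples), e.g. from [vst()].
#' @param top_n Number of most-variable genes to use, or `NULL` for all.
#' @return List with `scores` (samples x components), `percent_var`, and
#'   `rotation` (gene loadings).
#' @export
pca_samples <- function(trans, top_n = NULL) {
  if (ncol(trans) < 2L)
    stop("PCA requires at least 2 samples")
  if (!is.null(top_n) && top_n < nrow(trans)) {
    rv <- apply(trans, 1L, stats::var)
    trans <- trans[order(rv, decreasing = TRUE)[seq_len(top_n)], ,
                   drop = FALSE]
  }
  pc <- stats::prcomp(t(trans), center = TRUE, scale. = FALSE)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, percent_var = pv, rotation = pc$rotation)
}

#' Flag samples whose expression contradicts their annotated sex
#'
#' Because sex is the dominant axis of expression variation, a mislabeled
#' sample appears as a multivariate within-sex outlier. Each sample is
#' assigned to the nearer sex centroid in the top-2 principal-component
#' space, with the centroids computed leaving that sample out; samples
#' whose assigned sex disagrees with the annotation are flagged (not
#' removed).
#'
#' @param trans Transformed matrix (genes x samples).
#' @param samples Sample table.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_mis_sexed <- function(trans, samples) {
  samples <- samples[match(colnames(trans), samples$sample_id), ]
  tab <- table(samples$sex)
  if (length(tab) < 2L || any(tab < 2L)) {
    warning("need >= 2 samples of each sex; mis-sexed detection skipped")
    return(character(0))
  }
  sc <- pca_samples(trans)$scores[, 1:2, drop = FALSE]
  flagged <- character(0)
  for (i in seq_len(nrow(sc))) {
    d <- sapply(c("female", "male"), function(s) {
      idx <- which(samples$sex == s)
      idx <- setdiff(idx, i)
      ctr <- colMeans(sc[idx, , drop = FALSE])
      sqrt(sum((sc[i, ] - ctr)^2))
    })
    if (names(which.min(d)) != samples$sex[i])
      flagged <- c(flagged, samples$sample_id[i])
  }
  flagged
}

#' Mark samples as excluded in a sample table
#'
#' @param samples Sample table.
#' @param sample_ids Ids to exclude.
#' @param reason Reason recorded in `exclude_reason`.
#' @return Updated sample table.
#' @export
exclude_samples <- function(samples, sample_ids, reason = "flagged") {
  hit <- samples$sample_id %in% sample_ids
  samples$excluded[hit] <- TRUE
  samples$exclude_reason[hit] <- reason
  samples
}
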