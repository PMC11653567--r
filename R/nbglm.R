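#' Negative-binomial log-likelihood
#'
#' @param y Integer counts.
#' @param mu Fitted means (> 0, or 0 only where y is 0).
#' @param phi Dispersion; variance is `mu + phi * mu^2`.
#' @return Scalar log-likelihood.
#' @export
nb_loglik <- function(y, mu, phi) {
  phi <- max(phi, 1e-12)
  sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Design matrix for the reciprocal-cross model
#'
#' Encodes, per sample: intercept; sex (+1 female, -1 male); additive
#' genotype code `a` (-1 for the `lines[1]` homozygote, 0 for
#' heterozygotes, +1 for the `lines[2]` homozygote); dominance indicator
#' `h` (1 for heterozygotes); parent-of-origin code `p` (+1 when the dam
#' is `lines[2]`, -1 when the dam is `lines[1]`, 0 for homozygotes); and
#' the sex interactions `sex_a`, `sex_h`, `sex_p`. For a complete
#' 4-genotype x 2-sex design the matrix is saturated (8 columns, 8
#' groups) and of full column rank.
#'
#' @param samples Sample table (one cross).
#' @param lines Character pair ordering the two parental lines;
#'   `lines[2]` is the "high" (BB) line after orientation.
#' @return Numeric model matrix with one row per sample.
#' @export
cross_design <- function(samples, lines) {
  het <- samples$dam != samples$sire
  a <- ifelse(het, 0, ifelse(samples$dam == lines[2], 1, -1))
  h <- as.numeric(het)
  p <- ifelse(het, ifelse(samples$dam == lines[2], 1, -1), 0)
  sex <- ifelse(samples$sex == "female", 1, -1)
  X <- cbind(intercept = 1, sex = sex, a = a, h = h, p = p,
             sex_a = sex * a, sex_h = sex * h, sex_p = sex * p)
  rownames(X) <- samples$sample_id
  X
}

#' Fit a negative-binomial GLM with fixed dispersion
#'
#' Iteratively reweighted least squares with a log link and offsets
#' (delegated to [stats::glm.fit()] with the fixed-theta
#' [MASS::negative.binomial()] family), run to a relative deviance change
#' below 1e-10 or 100 iterations. A saturated one-parameter-per-group
#' design reproduces the (offset-adjusted) group means exactly.
#'
#' @param y Integer counts for one gene.
#' @param X Model matrix (full column rank).
#' @param offset Per-sample log offset (log size factors).
#' @param phi Fixed NB dispersion.
#' @param start Optional starting coefficients.
#' @return List with `coef`, `se`, `loglik`, `mu`, `phi`, `converged`.
#' @export
fit_nb <- function(y, X, offset = rep(0, length(y)), phi, start = NULL) {
  phi <- min(max(phi, 1e-8), 10)
  fam <- MASS::negative.binomial(theta = 1 / phi)
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, family = fam, offset = offset, start = start,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  mu <- fit$fitted.values
  w <- mu / (1 + phi * mu)
  cov <- tryCatch(chol2inv(chol(crossprod(X * sqrt(w)))),
                  error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(cov))
  names(se) <- colnames(X)
  list(coef = fit$coefficients, se = se,
       loglik = nb_loglik(y, mu, phi), mu = mu, phi = phi,
       converged = isTRUE(fit$converged))
}

#' Cox-Reid adjusted-profile-likelihood dispersion estimate
#'
#' Maximizes the NB log-likelihood penalized by half the log-determinant
#' of the Fisher information (the adjusted profile likelihood, which
#' corrects the downward bias of plain ML when the mean model uses many
#' degrees of freedom). The fitted means and the dispersion are updated in
#' two alternating cycles. The estimate is floored at 1e-8 and capped at
#' 10. No shrinkage across genes is applied: with a saturated design and
#' replicated cells the per-gene estimate is used as is.
#'
#' @param y Integer counts for one gene.
#' @param X Model matrix.
#' @param offset Per-sample log offset.
#' @return Dispersion estimate; attribute `"all_zero"` is TRUE when the
#'   gene had no nonzero count and the floor was returned.
#' @export
estimate_dispersion <- function(y, X, offset = rep(0, length(y))) {
  if (all(y == 0L))
    return(structure(1e-8, all_zero = TRUE))
  if (length(y) - ncol(X) < 2L)
    stop("dispersion estimation needs >= 2 residual degrees of freedom")
  apl <- function(log_phi, mu) {
    phi <- exp(log_phi)
    w <- mu / (1 + phi * mu)
    cr <- determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
    nb_loglik(y, mu, phi) - 0.5 * as.numeric(cr)
  }
  phi <- 0.1
  for (cycle in 1:2) {
    mu <- fit_nb(y, X, offset, phi)$mu
    opt <- stats::optimize(apl, interval = log(c(1e-8, 10)), mu = mu,
                           maximum = TRUE, tol = 1e-6)
    phi <- exp(opt$maximum)
  }
  structure(min(max(phi, 1e-8), 10), all_zero = FALSE)
}

#' Likelihood-ratio test between nested fixed-dispersion NB fits
#'
#' The same dispersion must be used for both fits. The statistic is
#' `2 * (ll_full - ll_reduced)` clipped at zero, referred to the
#' chi-square upper tail with `df` degrees of freedom.
#'
#' @param fit_full,fit_reduced Fits from [fit_nb()] on the same data.
#' @param df Difference in model degrees of freedom.
#' @return List with `stat`, `p` and `ok` (FALSE when the nesting
#'   inequality was violated beyond tolerance).
#' @export
nb_lrt <- function(fit_full, fit_reduced, df) {
  delta <- fit_full$loglik - fit_reduced$loglik
  ok <- delta > -1e-6
  stat <- max(2 * delta, 0)
  list(stat = stat, p = stats::pchisq(stat, df, lower.tail = FALSE),
       ok = ok)
}

#' Fit full and reduced models and run the LRT
#'
#' Fits the full model, then the reduced model obtained by dropping the
#' named columns. If the reduced fit's likelihood exceeds the full fit's
#' (a convergence failure, since the models are nested) the full model is
#' refit starting from the reduced solution; a persistent violation is
#' flagged.
#'
#' @param y Counts.
#' @param X Full model matrix.
#' @param drop Column names to drop for the reduced model.
#' @param offset Log offsets.
#' @param phi Fixed dispersion.
#' @return List with `stat`, `p`, `ok`, `fit_full`, `fit_reduced`.
#' @export
nb_lrt_fit <- function(y, X, drop, offset = rep(0, length(y)), phi) {
  keep <- setdiff(colnames(X), drop)
  if (length(keep) == ncol(X))
    stop("drop columns not found in design: ", paste(drop, collapse = ", "))
  Xr <- X[, keep, drop = FALSE]
  full <- fit_nb(y, X, offset, phi)
  red <- fit_nb(y, Xr, offset, phi)
  if (red$loglik > full$loglik + 1e-6) {
    start <- stats::setNames(numeric(ncol(X)), colnames(X))
    start[keep] <- red$coef
    refit <- fit_nb(y, X, offset, phi, start = start)
    if (refit$loglik > full$loglik) full <- refit
  }
  res <- nb_lrt(full, red, df = ncol(X) - ncol(Xr))
  res$fit_full <- full
  res$fit_reduced <- red
  res
}

#' Wald test for a single coefficient
#'
#' Provided for inspection; all headline calls in the pipeline use
#' likelihood-ratio tests, which behave better at low replication.
#'
#' @param fit A fit from [fit_nb()].
#' @param coef_name Name of the coefficient to test.
#' @return List with `estimate`, `se`, `z`, `p`.
#' @export
nb_wald <- function(fit, coef_name) {
  est <- fit$coef[[coef_name]]
  se <- fit$se[[coef_name]]
  z <- est / se
  list(estimate = est, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}
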