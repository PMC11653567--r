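#' Major-axis (type II) regression
#'
#' Symmetric regression appropriate when both variables carry error, as
#' for male versus female dominance coefficients. The slope is the
#' direction of the leading eigenvector of the 2x2 covariance matrix; its
#' confidence interval rotates the major axis by the Jolicoeur angle
#' `phi = asin(2 * sqrt(H)) / 2` with
#' `H = qf(1 - alpha, 1, n - 2) * l1 * l2 / ((n - 2) * (l1 - l2)^2)`,
#' where `l1 >= l2` are the eigenvalues.
#'
#' @param x,y Numeric vectors (e.g. male and female delta).
#' @param alpha CI level is `1 - alpha`.
#' @return List with `slope`, `intercept`, `ci` (length 2), `r`, `n`.
#' @export
ma_regression <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("major-axis regression needs n >= 3 finite pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  S <- stats::cov(cbind(x, y))
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (v[1] < 0) v <- -v           # orient along increasing x
  slope <- v[2] / v[1]
  l1 <- e$values[1L]; l2 <- e$values[2L]
  H <- stats::qf(1 - alpha, 1, n - 2) * l1 * l2 / ((n - 2) * (l1 - l2)^2)
  if (is.finite(H) && H >= 0 && 2 * sqrt(H) <= 1) {
    theta <- atan(slope)
    rot <- 0.5 * asin(2 * sqrt(H))
    ci <- sort(c(tan(theta - rot), tan(theta + rot)))
  } else {
    ci <- c(-Inf, Inf)            # axis direction unresolved at this alpha
  }
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       ci = ci, r = stats::cor(x, y), n = n)
}

#' Chi-square goodness-of-fit against equal proportions
#'
#' One-degree-of-freedom test of `k` successes out of `n` against the
#' 0.5/0.5 split, without continuity correction:
#' `(k - n/2)^2 / (n/2) + ((n - k) - n/2)^2 / (n/2)`.
#'
#' @param k Count in the first class.
#' @param n Total count.
#' @return List with `stat` and `p`.
#' @export
chisq_equal_proportions <- function(k, n) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  e <- n / 2
  stat <- (k - e)^2 / e + ((n - k) - e)^2 / e
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric p-value: the sum, over all tables with the
#' observed margins, of probabilities not exceeding the observed table's
#' probability (relative tie tolerance 1e-12).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab)))
    stop("tab must be a 2x2 matrix of non-negative integers")
  m <- sum(tab[1L, ])               # margin of row 1
  n2 <- sum(tab[2L, ])
  k <- sum(tab[, 1L])               # margin of column 1
  if (m == 0 || n2 == 0 || k == 0 || sum(tab[, 2L]) == 0) {
    message("empty margin in 2x2 table; p = 1 by convention")
    return(1)
  }
  support <- max(0L, k - n2):min(m, k)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(tab[1L, 1L], m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Directional (one-sided) two-sample Kolmogorov-Smirnov test
#'
#' Tests whether the `test` sample is stochastically larger than the
#' `reference` sample via `D+ = sup_t [ECDF_ref(t) - ECDF_test(t)]`, with
#' the one-sided asymptotic bound `p = exp(-2 D+^2 m n / (m + n))`.
#'
#' @param reference,test Numeric samples.
#' @return List with `stat` (D+) and `p`.
#' @export
ks_plus <- function(reference, test) {
  reference <- reference[is.finite(reference)]
  test <- test[is.finite(test)]
  m <- length(reference); n <- length(test)
  if (m == 0L || n == 0L) stop("both samples must be non-empty")
  grid <- sort(unique(c(reference, test)))
  ecdf_r <- stats::ecdf(reference)(grid)
  ecdf_t <- stats::ecdf(test)(grid)
  d_plus <- max(0, ecdf_r - ecdf_t)
  list(stat = d_plus,
       p = min(1, exp(-2 * d_plus^2 * m * n / (m + n))))
}

#' Storey q-values with fixed lambda
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #(p > lambda) / ((1 - lambda) * m))` and applies the
#' step-up rule `q_(i) = min_(j >= i) pi0 * m * p_(j) / j` on the sorted
#' p-values. With `pi0 = 1` this reduces to Benjamini-Hochberg adjusted
#' p-values. The fixed `lambda` (no smoother over a grid) keeps the
#' procedure deterministic.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs propagate).
#' @param lambda Null-proportion tuning parameter.
#' @return q-values in the input order.
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (length(pv) == 0L) return(out)
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  pi0 <- min(1, sum(pv > lambda) / ((1 - lambda) * m))
  pi0 <- max(pi0, 1 / m)           # guard: all p tiny implies pi0 ~ 0
  o <- order(pv)
  q_sorted <- pi0 * m * pv[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  qv <- numeric(m)
  qv[o] <- q_sorted
  out[ok] <- qv
  out
}
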