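#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' an all-positive count profile, of the ratio of each sample's count to the
#' gene's geometric mean across samples (the DESeq median-of-ratios scheme).
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Numeric vector of positive factors, one per column.
#' @examples
#' m <- rbind(g1 = c(2, 4), g2 = c(8, 16))
#' size_factors(m)  # c(0.7071, 1.4142)
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all-zero count matrix: size factors undefined")
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  if (!any(use)) {
    stop("no gene has positive counts in every sample; size factors undefined")
  }
  f <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - lg[use]))
  })
  unname(f)
}

#' Variance-stabilizing transform of normalized counts
#'
#' A monotone log-scale transform, `log2(count / factor + 1)`, applied after
#' size-factor normalization. Zero counts map to zero.
#'
#' @param counts Non-negative count matrix (genes x samples) or vector.
#' @param factors Positive size factors, one per sample (recycled for a vector).
#' @return Transformed matrix (or vector) of the same shape.
#' @export
vst <- function(counts, factors = size_factors(counts)) {
  if (any(factors <= 0)) stop("size factors must be positive")
  if (is.matrix(counts)) {
    if (length(factors) != ncol(counts)) {
      stop("need one size factor per column")
    }
    log2(sweep(counts, 2, factors, "/") + 1)
  } else {
    log2(counts / factors + 1)
  }
}

# Pooled method-of-moments NB dispersion for two groups of normalized counts.
# Var(K/s) = mu * E[1/s] + alpha * mu^2; solve for alpha from within-group
# residual variance, floored at a small positive value.
.mom_dispersion <- function(qa, qb, inv_sa, inv_sb) {
  na <- ncol(qa); nb <- ncol(qb)
  mua <- rowMeans(qa); mub <- rowMeans(qb)
  va <- apply(qa, 1, stats::var); vb <- apply(qb, 1, stats::var)
  num <- (na - 1) * (va - mua * mean(inv_sa)) + (nb - 1) * (vb - mub * mean(inv_sb))
  den <- (na - 1) * mua^2 + (nb - 1) * mub^2
  alpha <- ifelse(den > 0, num / den, 0)
  pmax(alpha, 1e-8)
}

#' Negative-binomial two-group Wald test
#'
#' Per-gene two-group differential expression on size-factor-normalized
#' counts: fold change `log2((mean_A + pc) / (mean_B + pc))`, a
#' method-of-moments dispersion estimate under the NB variance model
#' `mu + alpha * mu^2` moderated toward the across-gene median dispersion
#' (weight `prior_df` against the `nA + nB - 2` residual degrees of
#' freedom; gene-wise moment estimates are too noisy at typical replicate
#' numbers to use raw), and a two-sided normal-reference Wald test of the
#' log fold change. This is a documented approximation of a DESeq2-style
#' analysis, without fold-change shrinkage or independent filtering.
#'
#' @param a,b Count matrices (genes x samples; a vector is treated as one
#'   gene) for the two groups, at least 2 samples each.
#' @param size_factors_a,size_factors_b Positive per-sample size factors
#'   (default 1, i.e. counts already normalized).
#' @param pc Pseudocount added to group means before the fold change.
#' @param prior_df Weight of the across-gene median dispersion in the
#'   moderated estimate (default 10).
#' @return data.frame with columns `log2fc`, `pvalue` (one row per gene).
#' @export
nb_two_group_test <- function(a, b, size_factors_a = NULL, size_factors_b = NULL,
                              pc = 0.5, prior_df = 10) {
  if (is.vector(a)) a <- matrix(a, nrow = 1)
  if (is.vector(b)) b <- matrix(b, nrow = 1)
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) stop("need at least 2 samples per group")
  if (nrow(a) != nrow(b)) stop("groups must cover the same genes")
  if (is.null(size_factors_a)) size_factors_a <- rep(1, na)
  if (is.null(size_factors_b)) size_factors_b <- rep(1, nb)
  qa <- sweep(a, 2, size_factors_a, "/")
  qb <- sweep(b, 2, size_factors_b, "/")
  mua <- rowMeans(qa); mub <- rowMeans(qb)
  alpha <- .mom_dispersion(qa, qb, 1 / size_factors_a, 1 / size_factors_b)
  resid_df <- na + nb - 2
  prior <- stats::median(alpha, na.rm = TRUE)
  alpha <- (prior_df * prior + resid_df * alpha) / (prior_df + resid_df)
  log2fc <- log2((mua + pc) / (mub + pc))
  var_ma <- (mua * mean(1 / size_factors_a) + alpha * mua^2) / na
  var_mb <- (mub * mean(1 / size_factors_b) + alpha * mub^2) / nb
  se2 <- (var_ma / (mua + pc)^2 + var_mb / (mub + pc)^2) / log(2)^2
  se <- sqrt(se2)
  tstat <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * stats::pnorm(-abs(tstat))
  # genes at zero in both groups carry no information
  degen <- mua == 0 & mub == 0
  log2fc[degen] <- 0
  pvalue[degen] <- 1
  data.frame(log2fc = log2fc, pvalue = pmin(pvalue, 1),
             row.names = rownames(a))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment, applied per contrast.
#'
#' @param pvalues Numeric vector of p values in \[0, 1\] (NA passed through).
#' @return Adjusted values in \[0, 1\].
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# U statistic (number of (x, y) pairs with x > y, ties counted 1/2),
# computed from midranks.
.mann_whitney_u <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n)]) - n * (n + 1) / 2
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact two-sided p by full enumeration of all `choose(n + m, n)` group
#' labelings when `n + m <= 14` (ties handled by midranks; p is the
#' proportion of labelings whose U deviates from `n * m / 2` at least as much
#' as observed). Larger samples use the tie-corrected normal approximation
#' with a 0.5 continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with elements `U` and `pvalue`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  u_obs <- .mann_whitney_u(x, y)
  mu <- n * m / 2
  if (n + m <= 14) {
    z <- c(x, y)
    idx <- utils::combn(n + m, n)
    dev_obs <- abs(u_obs - mu)
    hits <- apply(idx, 2, function(i) {
      abs(.mann_whitney_u(z[i], z[-i]) - mu) >= dev_obs - 1e-9
    })
    p <- mean(hits)
  } else {
    N <- n + m
    r <- rank(c(x, y))
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zstat <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(zstat, 0)))
    }
  }
  list(U = u_obs, pvalue = p)
}

#' Welch's unequal-variances t test
#'
#' Two-sided Welch t test with Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric samples with at least 2 observations each; at least one
#'   group must have nonzero variance.
#' @return List with elements `t`, `df`, `pvalue`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 observations per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("both groups have zero variance; Welch test undefined")
  }
  fit <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       pvalue = fit$p.value)
}

#' Pearson product-moment correlation
#'
#' Returns NA (an explicit "undefined" signal, propagated as missing rather
#' than coerced to 0) when either vector is constant.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\], or NA if undefined.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Geometric mean
#'
#' `exp(mean(log(values)))`. Flow-cytometry intensities can be non-positive
#' after compensation; by default that is an error, but a positive `floor`
#' may be supplied to clamp values before the log.
#'
#' @param values Numeric vector.
#' @param floor Optional positive floor applied before the log; default NULL
#'   (non-positive values are an error).
#' @return Positive scalar.
#' @export
geometric_mean <- function(values, floor = NULL) {
  if (length(values) == 0) stop("empty input")
  if (!is.null(floor)) {
    if (floor <= 0) stop("floor must be positive")
    values <- pmax(values, floor)
  }
  if (any(values <= 0)) stop("geometric mean requires positive values (set floor= to clamp)")
  exp(mean(log(values)))
}

#' One-sided hypergeometric enrichment p value
#'
#' `P(X >= k)` for the overlap X between a query of size `n` and a set of
#' size `K` drawn from a universe of size `N`.
#'
#' @param k Observed overlap.
#' @param n Query size.
#' @param K Set size.
#' @param N Universe size.
#' @return Upper-tail p value.
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop("inconsistent hypergeometric counts")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
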