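# Independent brute-force oracles used to validate the statistical
# primitives. Each is deliberately written from first principles, on a
# different computational path than the implementation it checks.

# step-up BH by explicit sorting and cumulative minimum from the largest p
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / seq(n, 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact two-sided Mann-Whitney p by enumerating every group labeling;
# U computed by explicit pair counting (not midranks)
oracle_ranksum <- function(x, y) {
  u_pairs <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  n <- length(x); m <- length(y)
  z <- c(x, y)
  mu <- n * m / 2
  dev_obs <- abs(u_pairs(x, y) - mu)
  idx <- utils::combn(n + m, n)
  hits <- apply(idx, 2, function(i) {
    abs(u_pairs(z[i], z[-i]) - mu) >= dev_obs - 1e-9
  })
  mean(hits)
}

# hypergeometric upper tail by direct enumeration over all draws of size n
# from a universe of N items of which K are special
oracle_hypergeom <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  special <- seq_len(K)
  overlaps <- apply(draws, 2, function(d) sum(d %in% special))
  mean(overlaps >= k)
}

# Welch statistic from the textbook formulas
oracle_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, pvalue = 2 * stats::pt(-abs(t), df))
}

# naive all-pairs half-open interval overlap scan
oracle_intersect <- function(mapped, annot) {
  out <- list()
  for (i in seq_len(nrow(mapped))) for (j in seq_len(nrow(annot))) {
    if (mapped$chrom[i] == annot$chrom[j] &&
        mapped$start[i] < annot$end[j] && annot$start[j] < mapped$end[i]) {
      out[[length(out) + 1]] <- data.frame(query_id = mapped$gene_id[i],
                                           annot_id = annot$gene_id[j])
    }
  }
  if (!length(out)) {
    return(data.frame(query_id = character(), annot_id = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$query_id, res$annot_id), , drop = FALSE]
}

# compare two liftover results (both NULL, or same interval and fraction)
same_lift <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  identical(a[c("chrom", "start", "end", "strand")],
            b[c("chrom", "start", "end", "strand")]) &&
    isTRUE(all.equal(a$mapped_fraction, b$mapped_fraction))
}
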