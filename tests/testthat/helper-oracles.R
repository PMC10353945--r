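# Independent brute-force oracles; deliberately naive implementations that
# never share code with the package paths they check.

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration with the
# probability-mass rule (tables no more probable than the observed one).
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact Mann-Whitney p by enumerating every assignment of the
# pooled values to the first sample (tie-free samples only).
mw_p_oracle <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  idx <- utils::combn(length(pool), nx)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">"))
  us <- apply(idx, 2, function(ii) u_of(pool[ii], pool[-ii]))
  u_obs <- u_of(x, y)
  p1 <- if (u_obs > nx * length(y) / 2) mean(us >= u_obs) else mean(us <= u_obs)
  min(1, 2 * p1)
}

# Kendall tau-b by explicit pair counting.
kendall_tau_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) sum(sapply(table(v), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tie_pairs(x)) * (n0 - tie_pairs(y)))
}

# Benjamini-Hochberg step-up written from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- pmin(1, rev(cummin(rev(adj))))
  out <- numeric(n)
  out[o] <- adj
  out
}
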