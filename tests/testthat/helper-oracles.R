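# Independent oracles used to cross-check the package implementations.
# These are deliberately written from first principles (normal equations,
# the step-up definition of BH, hypergeometric summation, all-pairs overlap
# enumeration) and never call the code paths they verify.

# Closed-form OLS via the normal equations, textbook standard errors.
ols_oracle <- function(y, X) {
  XtXi <- solve(crossprod(X))
  beta <- drop(XtXi %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(XtXi))
  t <- beta / se
  p <- 2 * pt(-abs(t), df)
  k <- ncol(X)
  list(beta = unname(beta[k]), se = unname(se[k]), t = unname(t[k]),
       p = unname(p[k]), df = df)
}

# Direct step-up Benjamini-Hochberg: sort ascending, q_(i) = min_{j>=i}
# m p_(j) / j, capped at 1, returned in input order.
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(m * p[o] / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-sided Fisher exact p for a 2x2 table (a b / c d): sum of
# hypergeometric probabilities not exceeding the observed table's
# probability (with the conventional relative tie tolerance).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force all-pairs half-open interval overlap count per window.
count_windows_brute <- function(windows, features) {
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sum(features$chrom == w$chrom &
          features$start < w$end &
          features$end > w$start)
  }, numeric(1))
}
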