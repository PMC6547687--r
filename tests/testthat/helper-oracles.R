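# Independent brute-force oracles used to pin expected values.

# Two-sided exact Mann-Whitney p by enumerating every assignment of the
# pooled values into groups of the observed sizes. Assumes no ties.
mw_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum the
# probability of every table with the observed margins whose probability
# does not exceed the observed table's (with fisher.test's relative slack).
fisher_enumeration_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand-executed BH step-up: q_i = min over sorted j >= i of m * p_(j) / j.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, m * p[ord] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Pearson chi-square on a 2x2 without continuity correction, closed form.
chisq_closed_form <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}
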