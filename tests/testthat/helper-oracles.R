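# Independent oracles used across tests. These deliberately re-derive each
# statistic from its definition, not via the package's code paths.

# Random valid genus abundance table (rows renormalized to sum to 1).
random_genus_table <- function(n_samples, n_genera, seed) {
  set.seed(seed)
  m <- matrix(rexp(n_samples * n_genera), n_samples,
              dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                              sprintf("G%03d", seq_len(n_genera))))
  genus_table(m / rowSums(m))
}

# Tie-corrected Kruskal-Wallis H from its rank-sum definition.
kw_h_oracle <- function(x, g) {
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Exact permutation null of the two-group KW H statistic: enumerates every
# assignment of n1 observations to group 1. Returns the exact p and the
# largest single-atom mass of the null distribution (its discreteness).
kw_exact_perm <- function(x, g) {
  g <- factor(g)
  n1 <- sum(g == levels(g)[1])
  idx <- utils::combn(length(x), n1)
  Hs <- apply(idx, 2, function(ii) {
    kw_h_oracle(x, factor(ifelse(seq_along(x) %in% ii, "a", "b")))
  })
  Hobs <- kw_h_oracle(x, g)
  list(p = mean(Hs >= Hobs - 1e-12),
       max_atom = max(table(round(Hs, 10))) / length(Hs),
       H = Hobs)
}

# Benjamini-Hochberg step-up from its definition: q_(i) = min over j >= i of
# m * p_(j) / j, capped at 1, mapped back to the input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Pooled-variance two-sample t-test from the closed-form formula.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# Signal-to-noise from its definition, one genus at a time.
snr_oracle <- function(values, labels, pseudocount = 1e-6) {
  L <- log(values + pseudocount)
  (mean(L[labels == "case"]) - mean(L[labels == "control"])) / sd(L)
}
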