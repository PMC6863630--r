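# Independent brute-force oracles for the exact tests. These are kept
# deliberately naive (full enumeration, no shortcuts) so that they share
# no code path with the package implementations they check.

# two-sided Fisher p: sum of hypergeometric probabilities of all tables
# with the observed margins whose point probability does not exceed the
# observed one
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  xs <- lo:hi
  probs <- dhyper(xs, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided rank-sum p by enumerating every assignment of the pooled
# values to the two groups (no ties assumed)
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2 # Mann-Whitney U
  mu <- nx * (n - nx) / 2
  splits <- combn(n, nx)
  ws <- apply(splits, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# two-sided signed-rank p vs mu by enumerating all 2^n sign patterns
oracle_signed_rank_p <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu_v <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  mean(abs(vs - mu_v) >= abs(v_obs - mu_v) - 1e-9)
}

# exact Kruskal-Wallis permutation p by enumerating all n! orderings
# (practical for n <= 8)
oracle_kw_p <- function(groups) {
  sizes <- lengths(groups)
  n <- sum(sizes)
  gidx <- rep(seq_along(groups), sizes)
  h_stat <- function(r) {
    12 / (n * (n + 1)) *
      sum(tapply(r, gidx, function(z) sum(z)^2 / length(z))) - 3 * (n + 1)
  }
  obs <- h_stat(rank(unlist(groups)))
  perms <- all_perms(n)
  hs <- apply(perms, 1, h_stat)
  mean(hs >= obs - 1e-9)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# KS D statistic by direct CDF scan over the pooled support
oracle_ks_d <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(fx - fy))
}
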