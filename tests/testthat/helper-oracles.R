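# Independent brute-force oracles used to cross-check the implementation.

# Rg via the mean pairwise squared distance identity:
# Rg^2 = (1 / 2N^2) * sum_i sum_j |r_i - r_j|^2
oracle_rg_pairwise <- function(xyz) {
  n <- nrow(xyz)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    acc <- acc + sum((xyz[i, ] - xyz[j, ])^2)
  sqrt(acc / (2 * n^2))
}

# RMSD via an explicit per-atom loop
oracle_rmsd_loop <- function(a, b) {
  acc <- 0
  for (i in seq_len(nrow(a))) acc <- acc + sum((a[i, ] - b[i, ])^2)
  sqrt(acc / nrow(a))
}

# AUC by comparing every (active, decoy) pair; ties count 1/2
oracle_auc_allpairs <- function(lib) {
  sa <- lib$score[lib$label == "active"]
  sd_ <- lib$score[lib$label == "decoy"]
  wins <- 0
  for (x in sa) for (y in sd_)
    wins <- wins + if (x < y) 1 else if (x == y) 0.5 else 0
  wins / (length(sa) * length(sd_))
}

# Exact Mann-Whitney two-sided p by direct enumeration over label
# assignments (independent of the package's combn-based path: walks the
# assignments via an explicit recursion).
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  rk <- rank(pooled, ties.method = "average")
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  us <- c()
  recurse <- function(start, chosen) {
    if (length(chosen) == na) {
      us[length(us) + 1L] <<- sum(rk[chosen]) - na * (na + 1) / 2
      return(invisible())
    }
    if (start > n) return(invisible())
    for (k in start:n) recurse(k + 1L, c(chosen, k))
  }
  recurse(1L, integer(0))
  lo <- mean(us <= u_obs + 1e-9); hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Exact Wilcoxon signed-rank two-sided p by explicit enumeration of the
# 2^n sign patterns.
oracle_wsr_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d), ties.method = "average")
  w_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(signs, 1, function(s) sum(rk[as.logical(s)]))
  lo <- mean(ws <= w_obs + 1e-9); hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}
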