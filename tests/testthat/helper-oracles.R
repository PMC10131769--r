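# Independent brute-force oracles used to validate the package's statistics.
# These are deliberately naive implementations (hand formulas, exhaustive
# enumeration, normal-equations solves) kept separate from the code paths
# they check.

# midranks without using rank()
oracle_midrank <- function(x) {
  sapply(seq_along(x), function(i) sum(x < x[i]) + (1 + sum(x == x[i])) / 2)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), n - 2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# OLS by explicit normal equations, with classical covariance and t p-values
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  V <- sigma2 * solve(XtX)
  se <- sqrt(diag(V))
  list(beta = drop(beta), se = se, vcov = V, sigma2 = sigma2, df = df,
       p = 2 * stats::pt(-abs(drop(beta) / se), df))
}

# tie-corrected Kruskal-Wallis H from the textbook formula
oracle_kw <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  r <- oracle_midrank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(values)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  k <- length(unique(groups))
  list(H = H, p = stats::pchisq(H, k - 1, lower.tail = FALSE))
}

# exact two-sided rank-sum p by exhaustive enumeration of group assignments
oracle_ranksum_exact <- function(va, vb) {
  pooled <- c(va, vb)
  n1 <- length(va)
  r <- oracle_midrank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  w_all <- apply(sets, 2, function(ix) sum(r[ix]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# exhaustive best 2-partition of rows by within-cluster sum of squares
oracle_best_partition2 <- function(m) {
  n <- nrow(m)
  best <- NULL; best_ss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {       # fix row 1 in cluster 1
    assign <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    ss <- 0
    for (g in 1:2) {
      rows <- m[assign == g, , drop = FALSE]
      if (nrow(rows) == 0) { ss <- Inf; break }
      ctr <- colMeans(rows)
      ss <- ss + sum(sweep(rows, 2, ctr)^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- assign }
  }
  list(assignment = best, ss = best_ss)
}

# Cohen kappa recomputed from an explicit contingency table
oracle_kappa <- function(a, b) {
  cats <- union(a, b)
  tab <- table(factor(a, cats), factor(b, cats)) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  (p_o - p_e) / (1 - p_e)
}
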