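# Independent oracles used across the suite. These are deliberately naive
# re-derivations (rank formulas, grid searches, normal equations) that never
# share code with the package implementation they check.

# Tie-corrected Kruskal-Wallis H from the classical rank-sum formula:
# H = (1/S2) * (sum R_j^2 / n_j - N (N+1)^2 / 4), with
# S2 = (1/(N-1)) * (sum r_i^2 - N (N+1)^2 / 4) over midranks.
oracle_kruskal_h <- function(values, groups) {
  groups <- factor(groups)
  n_tot <- length(values)
  r <- rank(values)
  rj <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  c4 <- n_tot * (n_tot + 1)^2 / 4
  s2 <- (sum(r^2) - c4) / (n_tot - 1)
  (sum(rj^2 / nj) - c4) / s2
}

# Spearman's rho as the Pearson correlation of midranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Ordinary least squares coefficients via the normal equations.
oracle_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# 1-D LDA boundary by brute-force scan: the point where the two
# prior-weighted Gaussian class densities (pooled SD) cross.
oracle_lda_threshold <- function(yhat, y01, grid_n = 200001) {
  m1 <- mean(yhat[y01 == 1])
  m2 <- mean(yhat[y01 == 0])
  n1 <- sum(y01 == 1)
  n2 <- sum(y01 == 0)
  s <- sqrt((sum((yhat[y01 == 1] - m1)^2) + sum((yhat[y01 == 0] - m2)^2)) /
              (n1 + n2 - 2))
  pi1 <- n1 / (n1 + n2)
  pi2 <- n2 / (n1 + n2)
  lo <- min(m1, m2) - 3 * s
  hi <- max(m1, m2) + 3 * s
  g <- seq(lo, hi, length.out = grid_n)
  diff <- pi1 * dnorm(g, m1, s) - pi2 * dnorm(g, m2, s)
  # crossing between the two class means
  inb <- g > min(m1, m2) & g < max(m1, m2)
  gi <- g[inb]
  di <- abs(diff[inb])
  gi[which.min(di)]
}

# Dunn z statistic for one pair, from first principles.
oracle_dunn_z <- function(values, groups, g1, g2) {
  r <- rank(values)
  n_tot <- length(values)
  ties <- table(values)
  corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  v <- n_tot * (n_tot + 1) / 12 - corr
  r1 <- mean(r[groups == g1])
  r2 <- mean(r[groups == g2])
  (r1 - r2) / sqrt(v * (1 / sum(groups == g1) + 1 / sum(groups == g2)))
}
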