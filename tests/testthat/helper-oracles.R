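# Independent oracles used to check package computations.
# Each is written directly from the defining formula, not via the package.

# closed-form OLS through the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1L], slope = beta[2L], r2 = r2)
}

# classical balanced two-way ANOVA sums of squares from cell/marginal means
oracle_anova_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y)
  r <- n / (nlevels(a) * nlevels(b))   # replicates per cell (balanced)
  gm <- mean(y)
  ma <- tapply(y, a, mean)
  mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ssA <- r * nlevels(b) * sum((ma - gm)^2)
  ssB <- r * nlevels(a) * sum((mb - gm)^2)
  ssAB <- r * sum((sweep(sweep(mab, 1, ma), 2, mb) + gm)^2)
  ssTot <- sum((y - gm)^2)
  ssRes <- ssTot - ssA - ssB - ssAB
  list(ssA = ssA, ssB = ssB, ssAB = ssAB, ssRes = ssRes, ssTot = ssTot)
}

# Spearman rho as Pearson correlation of mid-ranks
oracle_rank_pearson <- function(x, y) cor(rank(x), rank(y))

# Shannon entropy straight from the formula (natural log)
oracle_shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Benjamini-Hochberg step-up adjustment from the formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# one-sample t statistic on paired differences, straight from the formula
oracle_paired_t <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# ALR -> CLR contrast matrix applied explicitly (reference last)
oracle_alr_to_clr <- function(lambda_alr) {
  D <- length(lambda_alr) + 1L
  F <- rbind(diag(D - 1L), 0)
  F <- F - matrix(colMeans(F), D, D - 1L, byrow = TRUE)
  as.vector(F %*% lambda_alr)
}
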