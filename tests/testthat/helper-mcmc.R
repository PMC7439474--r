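# Independent uncollapsed Gibbs / Metropolis-within-Gibbs sampler for the
# multinomial logistic-normal regression.  Written directly from the model
# statement (own density code, own conjugate formulas) so it can serve as an
# oracle for the package's collapsed Laplace fit.  State: (eta, Lambda,
# Sigma); Lambda and Sigma are drawn from their exact conditionals, eta is
# updated per sample by a random-walk Metropolis step.

mcmc_mvn_logdens <- function(x, mu, SigmaInv, logDetSigma) {
  d <- length(x)
  -0.5 * (d * log(2 * pi) + logDetSigma +
          as.numeric(t(x - mu) %*% SigmaInv %*% (x - mu)))
}

mcmc_multinom_loglik <- function(y, eta_j) {
  # reference coordinate appended as 0; unnormalised multinomial loglik
  full <- c(eta_j, 0)
  full <- full - max(full)
  p <- exp(full) / sum(exp(full))
  sum(y * log(p))
}

run_pibble_gibbs <- function(Y, X, Theta, Gamma, Xi, upsilon,
                             nIter = 20000, burn = 4000, thin = 4,
                             propSd = 0.3, seed = 42) {
  set.seed(seed)
  D <- nrow(Y); N <- ncol(Y); d <- D - 1L; Q <- nrow(X)
  GammaInv <- solve(Gamma)
  GN <- solve(GammaInv + X %*% t(X))
  cGN_L <- t(chol(GN))
  # init eta at ALR of pseudocounted proportions
  P <- sweep(Y + 0.5, 2L, colSums(Y + 0.5), "/")
  eta <- log(P[-D, , drop = FALSE]) -
    matrix(log(P[D, ]), d, N, byrow = TRUE)
  Lambda <- matrix(0, d, Q)
  Sigma <- diag(d)
  keep <- floor((nIter - burn) / thin)
  LambdaDraws <- array(NA_real_, c(d, Q, keep))
  k <- 0L
  acc <- 0L
  for (it in seq_len(nIter)) {
    ## -- (Lambda, Sigma) | eta : exact conjugate conditionals ------------
    ThetaN <- (Theta %*% GammaInv + eta %*% t(X)) %*% GN
    R1 <- eta - ThetaN %*% X
    R2 <- ThetaN - Theta
    XiN <- Xi + R1 %*% t(R1) + R2 %*% GammaInv %*% t(R2)
    XiN <- (XiN + t(XiN)) / 2
    K <- rWishart(1L, upsilon + N, solve(XiN))[, , 1L]
    Sigma <- solve(K)
    Sigma <- (Sigma + t(Sigma)) / 2
    Lambda <- ThetaN +
      t(chol(Sigma)) %*% matrix(rnorm(d * Q), d, Q) %*% t(cGN_L)
    ## -- eta | Lambda, Sigma, Y : random-walk MH per sample --------------
    SigmaInv <- solve(Sigma)
    logDetSigma <- determinant(Sigma, logarithm = TRUE)$modulus
    Mu <- Lambda %*% X
    for (j in seq_len(N)) {
      cur <- eta[, j]
      prop <- cur + rnorm(d, 0, propSd)
      lcur <- mcmc_multinom_loglik(Y[, j], cur) +
        mcmc_mvn_logdens(cur, Mu[, j], SigmaInv, logDetSigma)
      lprop <- mcmc_multinom_loglik(Y[, j], prop) +
        mcmc_mvn_logdens(prop, Mu[, j], SigmaInv, logDetSigma)
      if (log(runif(1)) < lprop - lcur) {
        eta[, j] <- prop
        acc <- acc + 1L
      }
    }
    if (it > burn && (it - burn) %% thin == 0L) {
      k <- k + 1L
      if (k <= keep) LambdaDraws[, , k] <- Lambda
    }
  }
  list(LambdaDraws = LambdaDraws[, , seq_len(k), drop = FALSE],
       acceptance = acc / (nIter * N))
}

# Monte-Carlo standard error of the mean of a (possibly autocorrelated)
# scalar chain, by non-overlapping batch means.
mcmc_se <- function(x, nBatch = 20) {
  n <- length(x)
  b <- floor(n / nBatch)
  bm <- vapply(seq_len(nBatch), function(i)
    mean(x[((i - 1) * b + 1):(i * b)]), numeric(1))
  sd(bm) / sqrt(nBatch)
}
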