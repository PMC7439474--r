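#' @include AllClasses.R logratio.R
NULL

#' Build the covariate matrix for the compositional regression
#'
#' Assembles the Q x N design matrix whose columns are samples (donors) and
#' whose rows are an intercept of ones followed by one row per prebiotic
#' holding that donor's total-SCFA fold change over control (replicates are
#' averaged per donor x prebiotic).  Row order follows `prebiotics`;
#' column order follows sorted donor labels, so shuffled input rows give an
#' identical matrix.
#'
#' @param foldChanges data.frame from [foldChange()] (columns `donor`,
#'   `prebiotic`, `replicate`, `fold_change`).
#' @param prebiotics ordered prebiotic names to include (default: all
#'   present, sorted).
#' @param includeIntercept prepend an intercept row of ones (default TRUE).
#' @return Q x N numeric matrix with row names
#'   `c("intercept", prebiotics)` and donor column names.
#' @export
buildCovariates <- function(foldChanges, prebiotics = NULL,
                            includeIntercept = TRUE) {
  needed <- c("donor", "prebiotic", "fold_change")
  if (!all(needed %in% names(foldChanges)))
    stop("foldChanges needs columns: ", paste(needed, collapse = ", "))
  if (is.null(prebiotics))
    prebiotics <- sort(unique(foldChanges$prebiotic))
  donors <- sort(unique(foldChanges$donor))
  agg <- aggregate(fold_change ~ donor + prebiotic, data = foldChanges,
                   FUN = mean)
  X <- matrix(NA_real_, length(prebiotics), length(donors),
              dimnames = list(prebiotics, donors))
  for (k in seq_len(nrow(agg))) {
    if (agg$prebiotic[k] %in% prebiotics)
      X[agg$prebiotic[k], agg$donor[k]] <- agg$fold_change[k]
  }
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    stop("missing fold change for ",
         paste(rownames(X)[bad[, 1L]], colnames(X)[bad[, 2L]],
               sep = " x ", collapse = "; "))
  }
  if (includeIntercept)
    X <- rbind(intercept = rep(1, ncol(X)), X)
  X
}

#' Default priors of the compositional regression
#'
#' Builds the [PibblePriors-class] used by default: `Theta` a zero matrix
#' (no prior association between any covariate and any taxon); `Gamma`
#' diagonal `interceptVar` for the intercept and `slopeVar` for each slope,
#' with `slopeCov` on every slope-slope off-diagonal (implying a prior
#' correlation of `slopeCov / slopeVar` = 0.3 between the effects of any two
#' prebiotics at the defaults); `upsilon = D + 3`; and `Xi` the
#' (D-1) x (D-1) matrix with diagonal `upsilon - D` and off-diagonal
#' `(upsilon - D) / 2`, a weak statement that taxa are uncorrelated in
#' absolute abundance (its compositional ALR image has exactly this
#' half-diagonal off-diagonal structure).
#'
#' @param D number of taxa (>= 2).
#' @param Q number of covariates (first treated as the intercept when
#'   `hasIntercept`).
#' @param interceptVar prior variance of the intercept effect (default
#'   500: the mean composition is essentially unconstrained).
#' @param slopeVar prior variance of each slope effect (default 2).
#' @param slopeCov prior covariance between slope effects (default 0.6).
#' @param hasIntercept logical; if FALSE all Q covariates are slopes.
#' @return a [PibblePriors-class].
#' @examples
#' pr <- defaultPriors(D = 97, Q = 5)
#' pr@upsilon        # 100
#' pr@Xi[1, 1]       # 3
#' pr@Xi[1, 2]       # 1.5
#' @export
defaultPriors <- function(D, Q, interceptVar = 500, slopeVar = 2,
                          slopeCov = 0.6, hasIntercept = TRUE) {
  D <- as.integer(D); Q <- as.integer(Q)
  if (D < 2L) stop("D must be >= 2")
  if (Q < 1L) stop("Q must be >= 1")
  Gamma <- matrix(slopeCov, Q, Q)
  diag(Gamma) <- slopeVar
  if (hasIntercept && Q >= 1L) {
    Gamma[1L, ] <- 0
    Gamma[, 1L] <- 0
    Gamma[1L, 1L] <- interceptVar
  }
  if (inherits(try(chol(Gamma), silent = TRUE), "try-error"))
    stop("slopeCov = ", slopeCov, " makes Gamma non-positive-definite")
  upsilon <- D + 3
  d <- D - 1L
  Xi <- matrix((upsilon - D) / 2, d, d)
  diag(Xi) <- upsilon - D
  new("PibblePriors",
      Theta = matrix(0, d, Q),
      Gamma = Gamma, Xi = Xi, upsilon = upsilon)
}

#' Construct a pibble model
#'
#' Pairs counts, covariates and priors into a validated
#' [PibbleModel-class]; priors default to [defaultPriors()] at the data's
#' dimensions.
#'
#' @param Y D x N non-negative integer count matrix (taxa x samples).
#' @param X Q x N covariate matrix (same samples).
#' @param priors a [PibblePriors-class]; default [defaultPriors()].
#' @return a [PibbleModel-class].
#' @export
pibbleModel <- function(Y, X, priors = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (ncol(Y) != ncol(X))
    stop("Y and X must have the same number of columns (samples): ",
         ncol(Y), " vs ", ncol(X))
  if (is.null(rownames(Y))) rownames(Y) <- paste0("Taxon_", seq_len(nrow(Y)))
  if (is.null(rownames(X))) rownames(X) <- paste0("x", seq_len(nrow(X)))
  if (is.null(priors)) priors <- defaultPriors(nrow(Y), nrow(X))
  new("PibbleModel", Y = Y, X = X, priors = priors)
}

## ---- collapsed posterior machinery ------------------------------------
## After marginalising Lambda ~ MN(Theta, Sigma, Gamma) and
## Sigma ~ IW(Xi, upsilon), the latent ALR matrix eta has a matrix-T prior:
##   p(eta) propto |Xi + E B E'|^{-(upsilon + N)/2},
## with E = eta - Theta X and B = (I_N + X' Gamma X)^{-1}.
## The collapsed log posterior adds the multinomial log likelihood in eta.

.collapsedEnv <- function(model) {
  Y <- model@Y; X <- model@X; pr <- model@priors
  D <- nrow(Y); N <- ncol(Y); d <- D - 1L
  A <- diag(N) + crossprod(X, pr@Gamma %*% X)
  B <- chol2inv(chol(A))
  list(Y = Y, Yd = Y[-D, , drop = FALSE], n = colSums(Y),
       M0 = pr@Theta %*% X, B = B, Xi = pr@Xi,
       vN = pr@upsilon + N, d = d, N = N, D = D)
}

# stabilised per-sample softmax including the implicit zero reference row
.etaToPi <- function(eta) {
  full <- rbind(eta, 0)
  full <- sweep(full, 2L, apply(full, 2L, max), "-")
  ef <- exp(full)
  sweep(ef, 2L, colSums(ef), "/")
}

.collapsedLogPost <- function(eta, env) {
  # multinomial part (log-sum-exp stabilised, reference coordinate = 0)
  mx <- pmax(apply(eta, 2L, max), 0)
  lse <- mx + log(exp(-mx) + colSums(exp(sweep(eta, 2L, mx, "-"))))
  ll <- sum(env$Yd * eta) - sum(env$n * lse)
  E <- eta - env$M0
  S <- env$Xi + E %*% env$B %*% t(E)
  cS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(cS)) return(-Inf)
  ll - (env$vN / 2) * 2 * sum(log(diag(cS)))
}

.collapsedGrad <- function(eta, env) {
  pi <- .etaToPi(eta)
  gMult <- env$Yd - sweep(pi[-env$D, , drop = FALSE], 2L, env$n, "*")
  E <- eta - env$M0
  S <- env$Xi + E %*% env$B %*% t(E)
  W <- chol2inv(chol(S))
  gMult - env$vN * (W %*% E %*% env$B)
}

.collapsedHessian <- function(eta, env) {
  d <- env$d; N <- env$N
  pi <- .etaToPi(eta)
  E <- eta - env$M0
  C <- E %*% env$B
  S <- env$Xi + C %*% t(E)
  W <- chol2inv(chol(S))
  P <- W %*% C
  Q2 <- crossprod(C, P) - env$B
  H <- env$vN * kronecker(Q2, W)
  M1 <- P[rep(seq_len(d), N), rep(seq_len(N), each = d)]
  H <- H + env$vN * (M1 * t(M1))
  # multinomial blocks: -n_j (diag(p) - p p') on the first d coordinates
  for (j in seq_len(N)) {
    p <- pi[seq_len(d), j]
    idx <- (j - 1L) * d + seq_len(d)
    H[idx, idx] <- H[idx, idx] - env$n[j] * (diag(p, d) - tcrossprod(p))
  }
  H
}

#' Fit the multinomial logistic-normal regression
#'
#' Fits the pibble model `Y_j ~ Multinomial(pi_j)`,
#' `pi_j = alrInv(eta_j)`, `eta_j ~ N(Lambda x_j, Sigma)`,
#' `Lambda ~ MN(Theta, Sigma, Gamma)`, `Sigma ~ IW(Xi, upsilon)` by
#' marginal Laplace approximation: (1) `Lambda` and `Sigma` are integrated
#' out analytically, leaving `eta` a matrix-T prior; (2) the collapsed log
#' posterior is maximised over `eta` (L-BFGS warm-up followed by damped
#' Newton steps with the exact dense Hessian) to a gradient sup-norm
#' tolerance; (3) posterior draws of `eta` come from the Gaussian (Laplace)
#' approximation at the mode; (4) each `eta` draw is "uncollapsed" by
#' sampling `Sigma` from its conjugate inverse-Wishart conditional and
#' `Lambda` from its conjugate matrix-normal conditional.  `eta` is
#' initialised at the ALR of the count proportions with a 0.5 pseudocount
#' (initialisation only; the likelihood never sees the pseudocount).
#'
#' @param Y D x N count matrix, or a [PibbleModel-class] (then `X` and
#'   `priors` are ignored), or a SummarizedExperiment (first assay used).
#' @param X Q x N covariate matrix.
#' @param priors a [PibblePriors-class]; default [defaultPriors()].
#' @param nSamples number of posterior draws (default 2000).
#' @param seed RNG seed for posterior sampling (optional).
#' @param gradTol convergence tolerance on the gradient sup-norm (default
#'   1e-6).
#' @param maxIter maximum total optimizer iterations (default 10000).
#' @return a [PibbleFit-class].  If the optimizer fails to reach `gradTol`
#'   a warning reports the final gradient norm and
#'   `diagnostics$converged` is `FALSE`.
#' @export
pibble <- function(Y, X = NULL, priors = NULL, nSamples = 2000, seed = NULL,
                   gradTol = 1e-6, maxIter = 10000) {
  model <- if (is(Y, "PibbleModel")) Y else {
    if (is(Y, "SummarizedExperiment"))
      Y <- as.matrix(SummarizedExperiment::assay(Y, 1L))
    pibbleModel(Y, X, priors)
  }
  validObject(model)
  env <- .collapsedEnv(model)
  d <- env$d; N <- env$N
  # init: ALR of pseudocount proportions
  eta <- alr(model@Y + 0.5)
  eta <- matrix(eta, d, N)
  lpInit <- .collapsedLogPost(eta, env)
  # L-BFGS warm-up on the vectorised problem
  opt <- optim(as.vector(eta),
               fn = function(v) -.collapsedLogPost(matrix(v, d, N), env),
               gr = function(v) -as.vector(.collapsedGrad(matrix(v, d, N),
                                                          env)),
               method = "L-BFGS-B",
               control = list(maxit = min(500, maxIter)))
  eta <- matrix(opt$par, d, N)
  # Newton polish with exact Hessian
  iter <- opt$counts[1L]
  g <- .collapsedGrad(eta, env)
  lp <- .collapsedLogPost(eta, env)
  H <- NULL
  while (max(abs(g)) > gradTol && iter < maxIter) {
    H <- .collapsedHessian(eta, env)
    step <- tryCatch(
      matrix(solve(-H, as.vector(g)), d, N),
      error = function(e) g / max(1, max(abs(g))))  # fall back to gradient
    stp <- 1
    repeat {
      etaNew <- eta + stp * step
      lpNew <- .collapsedLogPost(etaNew, env)
      if (lpNew >= lp - 1e-12 || stp < 1e-8) break
      stp <- stp / 2
    }
    if (lpNew < lp && stp < 1e-8) break  # no ascent possible
    eta <- etaNew; lp <- lpNew
    g <- .collapsedGrad(eta, env)
    iter <- iter + 1L
  }
  gradNorm <- max(abs(g))
  converged <- gradNorm <= gradTol
  if (!converged)
    warning("optimizer did not reach gradient tolerance: sup-norm ",
            format(gradNorm, digits = 4), " after ", iter, " iterations")
  if (is.null(H)) H <- .collapsedHessian(eta, env)
  # Laplace draws of eta, then conjugate uncollapsing
  nH <- -(H + t(H)) / 2
  cU <- tryCatch(chol(nH), error = function(e)
    chol(nH + diag(1e-8 * max(diag(nH)), nrow(nH))))
  pr <- model@priors
  GammaInv <- chol2inv(chol(pr@Gamma))
  GN <- chol2inv(chol(GammaInv + tcrossprod(model@X)))
  cGN <- t(chol(GN))
  drawOne <- function() {
    z <- rnorm(d * N)
    etaS <- eta + matrix(backsolve(cU, z), d, N)
    E0 <- etaS - env$M0
    XiN <- env$Xi + E0 %*% env$B %*% t(E0)
    XiN <- (XiN + t(XiN)) / 2
    Sigma <- chol2inv(chol(rWishart(1L, env$vN, chol2inv(chol(XiN)))[, , 1L]))
    ThetaN <- (pr@Theta %*% GammaInv + etaS %*% t(model@X)) %*% GN
    Lambda <- ThetaN +
      t(chol(Sigma)) %*% matrix(rnorm(d * ncol(ThetaN)), d) %*% t(cGN)
    list(eta = etaS, Sigma = Sigma, Lambda = Lambda)
  }
  sampler <- function() {
    LambdaDraws <- array(NA_real_, c(d, nrow(model@X), nSamples))
    SigmaDraws <- array(NA_real_, c(d, d, nSamples))
    etaDraws <- array(NA_real_, c(d, N, nSamples))
    for (s in seq_len(nSamples)) {
      dr <- drawOne()
      LambdaDraws[, , s] <- dr$Lambda
      SigmaDraws[, , s] <- dr$Sigma
      etaDraws[, , s] <- dr$eta
    }
    list(LambdaDraws = LambdaDraws, SigmaDraws = SigmaDraws,
         etaDraws = etaDraws)
  }
  draws <- if (is.null(seed)) sampler() else withr::with_seed(seed, sampler())
  dimnames(draws$LambdaDraws) <-
    list(rownames(model@Y)[-env$D], rownames(model@X), NULL)
  new("PibbleFit",
      model = model,
      LambdaDraws = draws$LambdaDraws,
      SigmaDraws = draws$SigmaDraws,
      etaDraws = draws$etaDraws,
      etaMap = eta,
      diagnostics = list(converged = converged, gradNorm = gradNorm,
                         iterations = as.integer(iter),
                         logPosterior = lp, logPosteriorInit = lpInit),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Conjugate conditional draws of (Lambda, Sigma) given eta
#'
#' Exposes step (4) of [pibble()] for a fixed latent matrix: samples
#' `Sigma ~ IW(Xi + E B E', upsilon + N)` and
#' `Lambda | Sigma ~ MN(ThetaN, Sigma, GammaN)` where
#' `GammaN = (Gamma^-1 + X X')^-1` and
#' `ThetaN = (Theta Gamma^-1 + eta X') GammaN`.  Used mainly for
#' conjugacy checks against the closed-form posterior moments.
#'
#' @param model a [PibbleModel-class].
#' @param eta fixed (D-1) x N latent ALR matrix.
#' @param nSamples number of draws.
#' @param seed optional RNG seed.
#' @return list with arrays `LambdaDraws` ((D-1) x Q x nSamples) and
#'   `SigmaDraws`, plus closed-form `ThetaN`, `GammaN`, `XiN`, `upsilonN`.
#' @export
uncollapsePibble <- function(model, eta, nSamples = 1000, seed = NULL) {
  validObject(model)
  pr <- model@priors
  env <- .collapsedEnv(model)
  d <- env$d
  GammaInv <- chol2inv(chol(pr@Gamma))
  GN <- chol2inv(chol(GammaInv + tcrossprod(model@X)))
  E0 <- eta - env$M0
  XiN <- env$Xi + E0 %*% env$B %*% t(E0)
  XiN <- (XiN + t(XiN)) / 2
  ThetaN <- (pr@Theta %*% GammaInv + eta %*% t(model@X)) %*% GN
  cGN <- t(chol(GN))
  body <- function() {
    LambdaDraws <- array(NA_real_, c(d, nrow(model@X), nSamples))
    SigmaDraws <- array(NA_real_, c(d, d, nSamples))
    XiNinv <- chol2inv(chol(XiN))
    for (s in seq_len(nSamples)) {
      Sigma <- chol2inv(chol(rWishart(1L, env$vN, XiNinv)[, , 1L]))
      SigmaDraws[, , s] <- Sigma
      LambdaDraws[, , s] <- ThetaN +
        t(chol(Sigma)) %*% matrix(rnorm(d * ncol(ThetaN)), d) %*% t(cGN)
    }
    list(LambdaDraws = LambdaDraws, SigmaDraws = SigmaDraws)
  }
  draws <- if (is.null(seed)) body() else withr::with_seed(seed, body())
  c(draws, list(ThetaN = ThetaN, GammaN = GN, XiN = XiN,
                upsilonN = env$vN))
}

#' Prior predictive simulation
#'
#' Simulates count tables from the prior and likelihood:
#' `Sigma ~ IW(Xi, upsilon)`, `Lambda ~ MN(Theta, Sigma, Gamma)`,
#' `eta ~ N(Lambda X, Sigma)` column-wise, counts multinomial through the
#' inverse ALR transform.  Used to check that prior settings generate
#' plausible data.
#'
#' @param model a [PibbleModel-class] (its observed per-sample depths are
#'   reused for the simulated counts).
#' @param nSims number of simulated datasets.
#' @param seed optional RNG seed.
#' @return list with `counts` (list of D x N matrices), and arrays
#'   `LambdaDraws`, `SigmaDraws` of the prior draws used.
#' @export
priorPredictive <- function(model, nSims = 100, seed = NULL) {
  validObject(model)
  pr <- model@priors
  d <- nrow(pr@Theta); Q <- ncol(pr@Theta); N <- ncol(model@X)
  D <- d + 1L
  depths <- colSums(model@Y)
  XiInv <- chol2inv(chol(pr@Xi))
  cG <- t(chol(pr@Gamma))
  body <- function() {
    LambdaDraws <- array(NA_real_, c(d, Q, nSims))
    SigmaDraws <- array(NA_real_, c(d, d, nSims))
    counts <- vector("list", nSims)
    for (s in seq_len(nSims)) {
      Sigma <- chol2inv(chol(rWishart(1L, pr@upsilon, XiInv)[, , 1L]))
      cS <- t(chol(Sigma))
      Lambda <- pr@Theta + cS %*% matrix(rnorm(d * Q), d) %*% t(cG)
      eta <- Lambda %*% model@X + cS %*% matrix(rnorm(d * N), d)
      pi <- alrInv(eta)
      counts[[s]] <- vapply(seq_len(N), function(j)
        rmultinom(1L, depths[j], pi[, j])[, 1L], integer(D))
      LambdaDraws[, , s] <- Lambda
      SigmaDraws[, , s] <- Sigma
    }
    list(counts = counts, LambdaDraws = LambdaDraws,
         SigmaDraws = SigmaDraws)
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}
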