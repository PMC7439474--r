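mkFc <- function() {
  expand.grid(donor = c("D01", "D02", "D03"),
              prebiotic = c("FOS", "GOS", "XOS", "dextrin", "inulin"),
              replicate = 1:2, stringsAsFactors = FALSE) |>
    transform(fold_change = 2 + as.integer(factor(donor)) * 0.5 +
                as.integer(factor(prebiotic)) * 0.1 + replicate * 0.01)
}

test_that("covariate matrices carry an intercept plus per-prebiotic fold changes", {
  fc <- mkFc()
  X0 <- buildCovariates(fc, prebiotics = character(0))
  expect_equal(dim(X0), c(1L, 3L))
  expect_true(all(X0 == 1))
  # default: all five prebiotics plus intercept -> Q = 6
  X6 <- buildCovariates(fc)
  expect_equal(nrow(X6), 6L)
  # the four-prebiotic covariate set -> Q = 5
  X5 <- buildCovariates(fc, prebiotics = c("inulin", "GOS", "XOS", "dextrin"))
  expect_equal(nrow(X5), 5L)
  expect_equal(rownames(X5),
               c("intercept", "inulin", "GOS", "XOS", "dextrin"))
  # replicate-averaged entries
  sub <- fc[fc$donor == "D02" & fc$prebiotic == "GOS", "fold_change"]
  expect_equal(X6["GOS", "D02"], mean(sub))
  # shuffled input rows give the identical matrix
  expect_equal(buildCovariates(fc[sample(nrow(fc)), ]), X6)
  expect_error(
    buildCovariates(fc[!(fc$prebiotic == "GOS" & fc$donor == "D02"), ]),
    "GOS x D02")
})

test_that("default priors reproduce the documented hyperparameter structure", {
  pr <- defaultPriors(D = 97, Q = 5)
  gammaExpected <- rbind(
    c(500, 0, 0, 0, 0),
    c(0, 2, .6, .6, .6),
    c(0, .6, 2, .6, .6),
    c(0, .6, .6, 2, .6),
    c(0, .6, .6, .6, 2))
  expect_equal(unname(pr@Gamma), gammaExpected)
  # implied prior correlation between any two slope effects
  expect_equal(pr@Gamma[2, 3] / pr@Gamma[2, 2], 0.3)
  expect_equal(pr@upsilon, 100)
  expect_equal(unname(diag(pr@Xi)), rep(3, 96))
  expect_equal(pr@Xi[1, 2], 1.5)
  expect_equal(pr@Theta, matrix(0, 96, 5))
  expect_error(defaultPriors(10, 3, slopeVar = 1, slopeCov = 2),
               "positive-definite")
})

test_that("model construction enforces dimensional consistency", {
  Y <- matrix(1:12, 3, 4)
  X <- matrix(1, 1, 5)
  expect_error(pibbleModel(Y, X), "same number of columns")
  expect_error(pibble(Y, X), "same number of columns")
  Yz <- Y; Yz[, 2] <- 0
  expect_error(pibbleModel(Yz, matrix(1, 1, 4)), "positive total")
})

test_that("pibble recovers known effects from model-simulated data", {
  set.seed(31)
  LambdaTrue <- matrix(c(0.8, -0.6, 0.3, 1.2, 0, -1.2), 3, 2)
  X <- rbind(intercept = rep(1, 50), x = rnorm(50))
  scen <- compositionScenario(D = 4, Q = 2, LambdaTrue = LambdaTrue,
                              SigmaTrue = 0.5 * diag(3), depth = 5000,
                              seed = 13)
  Y <- simulateCounts(scen, X)
  fit <- pibble(Y, X, priors = defaultPriors(4, 2, interceptVar = 5),
                nSamples = 1000, seed = 7)
  expect_true(fit@diagnostics$converged)
  postMean <- apply(fit@LambdaDraws, c(1, 2), mean)
  postSd <- apply(fit@LambdaDraws, c(1, 2), sd)
  lo <- apply(fit@LambdaDraws, c(1, 2), quantile, 0.025)
  hi <- apply(fit@LambdaDraws, c(1, 2), quantile, 0.975)
  # posterior means within 3 posterior SDs of truth, and truth mostly
  # inside the fit's own 95% intervals
  expect_true(all(abs(postMean - LambdaTrue) < 3 * postSd))
  expect_gte(mean(LambdaTrue >= lo & LambdaTrue <= hi), 5 / 6)
})

test_that("the collapsed optimum improves on the initialisation point", {
  set.seed(41)
  X <- rbind(rep(1, 12))
  Y <- simulateCounts(compositionScenario(5, 1, depth = 300, seed = 2), X)
  fit <- pibble(Y, X, priors = defaultPriors(5, 1), nSamples = 10, seed = 1)
  expect_gte(fit@diagnostics$logPosterior,
             fit@diagnostics$logPosteriorInit)
  expect_lte(fit@diagnostics$gradNorm, 1e-6)
})

test_that("conjugate uncollapsing matches closed-form posterior moments", {
  set.seed(51)
  D <- 4; Q <- 2; N <- 30
  X <- rbind(rep(1, N), rnorm(N))
  Y <- simulateCounts(compositionScenario(D, Q, depth = 400, seed = 3), X)
  model <- pibbleModel(Y, X, defaultPriors(D, Q, interceptVar = 3))
  eta <- alr(Y + 0.5)
  un <- uncollapsePibble(model, eta, nSamples = 4000, seed = 9)
  d <- D - 1
  # E[Sigma | eta] = XiN / (upsilonN - d - 1)
  expSigma <- un$XiN / (un$upsilonN - d - 1)
  simSigma <- apply(un$SigmaDraws, c(1, 2), mean)
  expect_true(max(abs(simSigma - expSigma)) < 0.05)
  # E[Lambda | eta] = ThetaN
  simLambda <- apply(un$LambdaDraws, c(1, 2), mean)
  seLambda <- apply(un$LambdaDraws, c(1, 2), sd) / sqrt(4000)
  expect_true(all(abs(simLambda - un$ThetaN) < 4 * seLambda + 1e-8))
  # Var[Lambda_ij | eta] = E[Sigma_ii] * GammaN_jj (matrix-T marginal)
  varLambda <- apply(un$LambdaDraws, c(1, 2), var)
  expVar <- outer(diag(expSigma), diag(un$GammaN))
  expect_true(max(abs(varLambda / expVar - 1)) < 0.2)
})

test_that("prior predictive draws recover the prior moments", {
  D <- 4; Q <- 2; N <- 25
  X <- rbind(rep(1, N), rnorm(N))
  Y <- matrix(5L, D, N, dimnames = list(paste0("t", 1:D), NULL))
  pr <- defaultPriors(D, Q, interceptVar = 2)
  model <- pibbleModel(Y, X, pr)
  pp <- priorPredictive(model, nSims = 3000, seed = 17)
  # E[Lambda] = Theta (zero)
  expect_true(max(abs(apply(pp$LambdaDraws, c(1, 2), mean))) < 0.1)
  # E[Sigma] = Xi / (upsilon - (D-1) - 1); off-diagonals half the diagonal
  expSigma <- pr@Xi / (pr@upsilon - (D - 1) - 1)
  expect_equal(expSigma[1, 2], expSigma[1, 1] / 2)
  simSigma <- apply(pp$SigmaDraws, c(1, 2), mean)
  expect_true(max(abs(simSigma - expSigma)) < 0.15)
  # counts honour the observed depths; identical seed reproduces exactly
  expect_equal(colSums(pp$counts[[1]]), colSums(Y), ignore_attr = TRUE)
  pp2 <- priorPredictive(model, nSims = 3, seed = 99)
  pp3 <- priorPredictive(model, nSims = 3, seed = 99)
  expect_identical(pp2$counts, pp3$counts)
})

test_that("posterior summaries report nested CLR intervals and flags", {
  # degenerate draws: all zero -> intervals [0,0], not credible
  z <- array(0, c(2, 1, 50))
  s0 <- summarizePosterior(z)
  tab <- summaryTable(s0)
  expect_true(all(tab$lower95 == 0 & tab$upper95 == 0))
  expect_false(any(tab$credible))
  # all draws at +1 on one coordinate -> flagged
  o <- array(rep(c(1, 0), 50), c(2, 1, 50))
  tabO <- summaryTable(summarizePosterior(o))
  # CLR of ALR (1, 0) with ref third: centred, nonzero everywhere
  expect_equal(tabO$mean, oracle_alr_to_clr(c(1, 0)))
  expect_true(tabO$credible[1])
  # real fit: nesting and zero-sum of the CLR taxon dimension
  set.seed(61)
  X <- rbind(rep(1, 20), rnorm(20))
  Y <- simulateCounts(compositionScenario(4, 2, depth = 800, seed = 5), X)
  fit <- pibble(Y, X, priors = defaultPriors(4, 2, interceptVar = 3),
                nSamples = 400, seed = 3)
  tab <- summaryTable(summarizePosterior(fit))
  expect_true(all(tab$lower50 >= tab$lower80 & tab$lower80 >= tab$lower95 &
                  tab$lower95 >= tab$lower99))
  expect_true(all(tab$upper50 <= tab$upper80 & tab$upper80 <= tab$upper95 &
                  tab$upper95 <= tab$upper99))
  sums <- tapply(tab$mean, tab$covariate, sum)
  expect_true(all(abs(sums) < 1e-10))
  expect_error(summarizePosterior(array(0, c(2, 1, 1))), "at least 2")
})

test_that("CLR summaries are invariant to the internal ALR reference taxon", {
  # moving a different taxon to the reference (last) position changes the
  # ALR basis but must leave CLR-scale conclusions unchanged up to
  # Monte-Carlo error
  set.seed(71)
  X <- rbind(rep(1, 40), rnorm(40))
  LambdaTrue <- matrix(c(0.5, -0.2, 0.4, 1, -0.5, 0), 3, 2)
  Y <- simulateCounts(compositionScenario(4, 2, LambdaTrue = LambdaTrue,
                                          depth = 8000, seed = 8), X)
  perm <- c(2, 3, 4, 1)  # taxon 1 becomes the reference
  fits <- lapply(list(Y, Y[perm, ]), function(Yp)
    pibble(Yp, X, priors = defaultPriors(4, 2, interceptVar = 3),
           nSamples = 2000, seed = 11))
  tabs <- lapply(fits, function(f) summaryTable(summarizePosterior(f)))
  m1 <- tabs[[1]]$mean
  m2 <- tabs[[2]]$mean[match(paste(tabs[[1]]$taxon, tabs[[1]]$covariate),
                             paste(tabs[[2]]$taxon, tabs[[2]]$covariate))]
  expect_true(max(abs(m1 - m2)) < 0.05)
})
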