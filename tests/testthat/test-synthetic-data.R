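test_that("noise-free unit-effect scenario gives flat totals and unit fold changes", {
  scen <- fermentationScenario(nDonors = 4, prebiotics = c("inulin", "FOS"),
                               controlMeanMM = 12, noiseCV = 0, seed = 2)
  prof <- simulateFermentation(scen)
  totals <- totalScfa(prof)
  expect_equal(totals$total_mM, rep(12, nrow(totals)))
  fc <- foldChange(prof)
  expect_equal(fc$fold_change, rep(1, nrow(fc)))
  # one control and one vessel per prebiotic per replicate per donor
  expect_equal(nrow(totals), 4 * (2 + 1) * 2)
})

test_that("fermentation simulation is deterministic in the seed", {
  scen <- fermentationScenario(nDonors = 3, prebiotics = c("inulin", "GOS"),
                               noiseCV = 0.2, seed = 33)
  expect_identical(simulateFermentation(scen), simulateFermentation(scen))
  scen2 <- fermentationScenario(nDonors = 3, prebiotics = c("inulin", "GOS"),
                                noiseCV = 0.2, seed = 34)
  expect_false(identical(simulateFermentation(scen)$concentration_mM,
                         simulateFermentation(scen2)$concentration_mM))
})

test_that("invalid fermentation scenarios are rejected", {
  expect_error(fermentationScenario(3, "inulin", donorEffects = c(1, -1, 1)),
               "positive")
  expect_error(fermentationScenario(3, "inulin", noiseCV = -0.1), ">= 0")
  expect_error(fermentationScenario(3, c("inulin", "control")), "reserved")
})

test_that("noisy fold changes centre on the prebiotic effect", {
  # effect 3.0, CV 0.1, many replicates: the empirical mean fold change
  # sits within 3 Monte-Carlo standard errors of 3.0
  scen <- fermentationScenario(nDonors = 1, prebiotics = "inulin",
                               prebioticEffects = 3, nReplicates = 200,
                               noiseCV = 0.1, seed = 55)
  fc <- foldChange(simulateFermentation(scen))$fold_change
  se <- sd(fc) / sqrt(length(fc))
  expect_lt(abs(mean(fc) - 3), 3 * se)
})

test_that("count simulation respects depth, dimensions and the ALR map", {
  X <- rbind(rep(1, 8))
  scen <- compositionScenario(D = 5, Q = 1, depth = 700, seed = 3)
  Y <- simulateCounts(scen, X)
  expect_equal(dim(Y), c(5L, 8L))
  expect_true(all(Y >= 0) && all(Y == round(Y)))
  expect_equal(colSums(Y), rep(700, 8), ignore_attr = TRUE)
  # depth 0 gives all-zero counts
  Y0 <- simulateCounts(compositionScenario(5, 1, depth = 0, seed = 3), X)
  expect_true(all(Y0 == 0))
  expect_error(simulateCounts(scen, rbind(X, X)), "Q = 1")
})

test_that("near-zero covariance with zero effects approaches uniform compositions", {
  X <- rbind(rep(1, 30))
  scen <- compositionScenario(D = 4, Q = 1,
                              SigmaTrue = diag(3) * 1e-12,
                              depth = 50000, seed = 5)
  Y <- simulateCounts(scen, X)
  props <- sweep(Y, 2, colSums(Y), "/")
  expect_true(max(abs(props - 0.25)) < 0.02)
})

test_that("large-depth proportions match the inverse-ALR target", {
  # D = 3, fixed eta per sample (Sigma -> 0), depth 1e5: empirical
  # proportions within 3 binomial standard errors of alrInv(eta)
  eta <- c(0.7, -0.3)
  # with LambdaTrue = I and x_1 = eta, the latent coordinates equal eta
  scen <- compositionScenario(D = 3, Q = 2,
                              LambdaTrue = diag(2),
                              SigmaTrue = diag(2) * 1e-14,
                              depth = 1e5, seed = 6)
  Y <- simulateCounts(scen, matrix(eta, 2, 1))
  target <- alrInv(eta)
  phat <- Y[, 1] / sum(Y[, 1])
  se <- sqrt(target * (1 - target) / 1e5)
  expect_true(all(abs(phat - target) <= 3 * se))
})

test_that("simulated eta covariance converges to SigmaTrue", {
  Sig <- matrix(c(1, 0.4, 0.4, 0.8), 2, 2)
  frob <- function(n, seed) {
    scen <- compositionScenario(D = 3, Q = 1, SigmaTrue = Sig,
                                depth = 2e5, seed = seed)
    Y <- simulateCounts(scen, rbind(rep(1, n)) * 0)
    # at depth 2e5 the ALR of the proportions is eta up to tiny counting noise
    etaHat <- alr(Y + 0.5)
    sqrt(sum((cov(t(etaHat)) - Sig)^2))
  }
  expect_lt(frob(2000, 9), frob(40, 9))
})

test_that("study-like bundle has the study's shape and bookkeeping", {
  ds <- makeStudyLikeDataset(seed = 4)
  Y <- SummarizedExperiment::assay(ds$counts)
  expect_equal(dim(Y), c(97L, 17L))
  expect_equal(dim(ds$covariates), c(6L, 17L))
  expect_equal(rownames(ds$covariates)[1], "intercept")
  # duplicate vessels: 17 donors x (5 prebiotics + control) x 2 replicates
  expect_equal(nrow(totalScfa(ds$scfa)), 17 * 6 * 2)
  # ground truth identifies which taxon x prebiotic effects were injected
  gt <- ds$groundTruth
  expect_equal(dim(gt$signalMask), dim(gt$LambdaClr))
  expect_true(all(abs(gt$LambdaClr[gt$signalMask]) > 0.5))
  expect_true(all(abs(colSums(gt$LambdaClr[, -1])) < 1e-10))
  # different seeds: different counts, identical shapes
  ds2 <- makeStudyLikeDataset(seed = 5)
  Y2 <- SummarizedExperiment::assay(ds2$counts)
  expect_equal(dim(Y2), dim(Y))
  expect_false(identical(Y, Y2))
  expect_identical(SummarizedExperiment::assay(
    makeStudyLikeDataset(seed = 4)$counts), Y)
})
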