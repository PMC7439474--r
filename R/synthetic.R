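#' @include AllClasses.R logratio.R
NULL

#' Construct a fermentation scenario
#'
#' Builds a validated [FermentationScenario-class].  Effects default to 1
#' (no donor, prebiotic or interaction effect).
#'
#' @param nDonors number of donors.
#' @param prebiotics character vector of treatment names.
#' @param nReplicates vessels per donor x treatment (default 2, duplicate
#'   reactions).
#' @param donorEffects,prebioticEffects,interactionEffects positive
#'   multiplicative effects; scalars are recycled.
#' @param controlMeanMM baseline control total SCFA in mM (default 10).
#' @param noiseCV replicate coefficient of variation (default 0).
#' @param seed RNG seed.
#' @return a [FermentationScenario-class].
#' @export
fermentationScenario <- function(nDonors,
                                 prebiotics,
                                 nReplicates = 2L,
                                 donorEffects = 1,
                                 prebioticEffects = 1,
                                 interactionEffects = 1,
                                 controlMeanMM = 10,
                                 noiseCV = 0,
                                 seed = 1L) {
  nP <- length(prebiotics)
  if (length(donorEffects) == 1L) donorEffects <- rep(donorEffects, nDonors)
  if (length(prebioticEffects) == 1L)
    prebioticEffects <- rep(prebioticEffects, nP)
  if (!is.matrix(interactionEffects))
    interactionEffects <- matrix(interactionEffects, nDonors, nP)
  new("FermentationScenario",
      nDonors = as.integer(nDonors),
      prebiotics = as.character(prebiotics),
      nReplicates = as.integer(nReplicates),
      donorEffects = as.numeric(donorEffects),
      prebioticEffects = as.numeric(prebioticEffects),
      interactionEffects = interactionEffects,
      controlMeanMM = as.numeric(controlMeanMM),
      noiseCV = as.numeric(noiseCV),
      seed = as.integer(seed))
}

# Fractional composition of total SCFA across the C2:C5 acids used by the
# generator (acetate-dominated, as in fecal fermentations).
.acidSplit <- c(acetate = 0.60, propionate = 0.18, isobutyrate = 0.03,
                butyrate = 0.15, isovalerate = 0.03, valerate = 0.01)

#' Simulate an in vitro fermentation screen
#'
#' Generates per-vessel SCFA profiles for every donor x treatment x
#' replicate combination, including one unsupplemented control vessel per
#' donor x replicate.  Expected totals are `controlMeanMM * donorEffect`
#' for controls and `controlMeanMM * donorEffect * prebioticEffect *
#' interactionEffect` for treatments, so noise-free fold changes over
#' control equal `prebioticEffect * interactionEffect` exactly.  Replicate
#' noise is multiplicative lognormal with coefficient of variation
#' `noiseCV`, mean-preserving (`E[multiplier] = 1`).  The vessel total is
#' split across the six C2:C5 acids in fixed acetate-dominated proportions.
#' Identical scenarios (including seed) give identical tables.
#'
#' @param scenario a [FermentationScenario-class].
#' @return long-format data.frame with columns `donor`, `treatment`,
#'   `replicate`, `acid`, `concentration_mM`.
#' @export
simulateFermentation <- function(scenario) {
  stopifnot(is(scenario, "FermentationScenario"))
  validObject(scenario)
  sigma2 <- log(1 + scenario@noiseCV^2)
  donors <- sprintf("D%02d", seq_len(scenario@nDonors))
  treatments <- c("control", scenario@prebiotics)
  grid <- expand.grid(replicate = seq_len(scenario@nReplicates),
                      treatment = treatments, donor = seq_len(scenario@nDonors),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withr::with_seed(scenario@seed, {
    expected <- vapply(seq_len(nrow(grid)), function(k) {
      d <- grid$donor[k]; tr <- grid$treatment[k]
      base <- scenario@controlMeanMM * scenario@donorEffects[d]
      if (tr == "control") return(base)
      p <- match(tr, scenario@prebiotics)
      base * scenario@prebioticEffects[p] * scenario@interactionEffects[d, p]
    }, numeric(1L))
    mult <- if (sigma2 > 0)
      exp(rnorm(nrow(grid), -sigma2 / 2, sqrt(sigma2))) else
      rep(1, nrow(grid))
    totals <- expected * mult
  })
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    data.frame(donor = donors[grid$donor[k]],
               treatment = grid$treatment[k],
               replicate = grid$replicate[k],
               acid = names(.acidSplit),
               concentration_mM = unname(totals[k] * .acidSplit),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Construct a compositional count scenario
#'
#' @param D number of taxa.
#' @param Q number of covariates.
#' @param LambdaTrue (D-1) x Q matrix of ALR-scale effects (default zero).
#' @param SigmaTrue (D-1) x (D-1) positive-definite ALR covariance
#'   (default identity).
#' @param depth per-sample sequencing depth (default 10000).
#' @param seed RNG seed.
#' @return a [CompositionScenario-class].
#' @export
compositionScenario <- function(D, Q,
                                LambdaTrue = matrix(0, D - 1L, Q),
                                SigmaTrue = diag(D - 1L),
                                depth = 10000,
                                seed = 1L) {
  new("CompositionScenario",
      D = as.integer(D), Q = as.integer(Q),
      LambdaTrue = LambdaTrue, SigmaTrue = SigmaTrue,
      depth = as.numeric(depth), seed = as.integer(seed))
}

#' Simulate multinomial counts under the logistic-normal linear model
#'
#' For each sample `j` draws latent ALR coordinates
#' `eta_j ~ N(LambdaTrue %*% x_j, SigmaTrue)` (reference = last taxon),
#' maps them through the inverse ALR transform to a composition and draws
#' multinomial counts at the sample's depth.  Seed-reproducible.
#'
#' @param scenario a [CompositionScenario-class].
#' @param X Q x N covariate matrix (columns are samples).
#' @return D x N integer count matrix (taxa named `Taxon_1..D` unless `X`
#'   has column names, which become sample names).
#' @export
simulateCounts <- function(scenario, X) {
  stopifnot(is(scenario, "CompositionScenario"))
  validObject(scenario)
  X <- as.matrix(X)
  if (nrow(X) != scenario@Q)
    stop("X must have Q = ", scenario@Q, " rows, got ", nrow(X))
  N <- ncol(X)
  d <- scenario@D - 1L
  depth <- rep_len(scenario@depth, N)
  L <- t(chol(scenario@SigmaTrue))
  withr::with_seed(scenario@seed, {
    eta <- scenario@LambdaTrue %*% X + L %*% matrix(rnorm(d * N), d, N)
    pi <- alrInv(eta)
    Y <- vapply(seq_len(N), function(j) {
      if (depth[j] == 0) return(integer(scenario@D))
      rmultinom(1L, size = depth[j], prob = pi[, j])[, 1L]
    }, integer(scenario@D))
  })
  dimnames(Y) <- list(paste0("Taxon_", seq_len(scenario@D)),
                      colnames(X) %||% paste0("S", seq_len(N)))
  Y
}

#' Generate a full study-like synthetic dataset
#'
#' Emulates the design of the fermentation screen end to end with known
#' ground truth: 17 donors x 5 prebiotics (inulin, FOS, GOS, XOS, dextrin)
#' with duplicate vessels plus unsupplemented controls; control-corrected
#' fold changes; and a 97-genus count table (one stool sample per donor)
#' generated from the multinomial logistic-normal linear model whose
#' covariates are the simulated fold changes.  A sparse known set of
#' (genus, prebiotic) pairs carries non-zero CLR effects of unit magnitude
#' (the scale at which one unit of fold change maps to one CLR unit); all
#' other slope effects are null up to the zero-sum centring of CLR columns.
#'
#' @param seed integer RNG seed driving every stage.
#' @param nDonors number of donors (default 17).
#' @param prebiotics treatment names (default the five study prebiotics).
#' @param nGenera number of genus-level taxa (default 97).
#' @param depth mean per-sample sequencing depth (default 20000).
#' @param noiseCV replicate noise CV of the fermentation stage (default
#'   0.1).
#' @param nSignals number of non-zero (genus, prebiotic) effects (default
#'   15, of which 4 negative).
#' @param effectSize magnitude of injected CLR effects (default 1).
#' @return list with elements `scfa` (long profile table), `foldChange`,
#'   `counts` (a SummarizedExperiment, genera x donors, taxonomy in
#'   rowData), `covariates` (Q x N matrix: intercept + one row per
#'   prebiotic), `taxonomy` (data.frame), `groundTruth` (list: `LambdaClr`
#'   D x Q true CLR effects, `signalMask` D x Q logical for injected
#'   effects, `sigmaTrue`, generator settings) and `seed`.
#' @export
makeStudyLikeDataset <- function(seed = 1L,
                                 nDonors = 17L,
                                 prebiotics = c("inulin", "FOS", "GOS",
                                                "XOS", "dextrin"),
                                 nGenera = 97L,
                                 depth = 20000,
                                 noiseCV = 0.1,
                                 nSignals = 15L,
                                 effectSize = 1) {
  seed <- as.integer(seed)
  nP <- length(prebiotics)
  D <- as.integer(nGenera)
  Q <- nP + 1L
  # --- fermentation stage -------------------------------------------------
  ferm <- withr::with_seed(seed, {
    donorEffects <- rlnorm(nDonors, -0.4^2 / 2, 0.4)
    # per-prebiotic mean fold changes spanning the 2.35 (inulin) to 3.55
    # (GOS) range characteristic of this assay class; other substrates
    # spaced within the range
    base <- c(inulin = 2.35, GOS = 3.55, FOS = 2.73, XOS = 3.25,
              dextrin = 2.95)
    prebioticEffects <- setNames(
      ifelse(prebiotics %in% names(base), base[prebiotics],
             mean(c(2.35, 3.55))), prebiotics)
    # donor-specific acidogenic response (ratio scale) times idiosyncratic
    # donor x prebiotic variation; both mean-preserving (E = 1)
    donorResponse <- rlnorm(nDonors, -0.3^2 / 2, 0.3)
    eps <- matrix(rlnorm(nDonors * nP, -0.25^2 / 2, 0.25), nDonors, nP)
    list(donorEffects = donorEffects,
         prebioticEffects = prebioticEffects,
         interactionEffects = donorResponse * eps)
  })
  scen <- fermentationScenario(
    nDonors = nDonors, prebiotics = prebiotics,
    donorEffects = ferm$donorEffects,
    prebioticEffects = unname(ferm$prebioticEffects),
    interactionEffects = ferm$interactionEffects,
    controlMeanMM = 10, noiseCV = noiseCV, seed = seed + 1L)
  scfa <- simulateFermentation(scen)
  fc <- foldChange(scfa)
  X <- buildCovariates(fc, prebiotics = prebiotics)
  # --- composition stage --------------------------------------------------
  truth <- withr::with_seed(seed + 2L, {
    LambdaClr <- matrix(0, D, Q,
                        dimnames = list(sprintf("Genus_%03d", seq_len(D)),
                                        rownames(X)))
    LambdaClr[, 1L] <- scale(rnorm(D, 0, 1.5), scale = FALSE)
    mask <- matrix(FALSE, D, Q, dimnames = dimnames(LambdaClr))
    sigTaxa <- sample.int(D, nSignals, replace = TRUE)
    sigPreb <- sample.int(nP, nSignals, replace = TRUE) + 1L
    signs <- rep(c(1, -1), c(nSignals - 4L, 4L))[sample.int(nSignals)]
    for (k in seq_len(nSignals)) {
      LambdaClr[sigTaxa[k], sigPreb[k]] <-
        LambdaClr[sigTaxa[k], sigPreb[k]] + signs[k] * effectSize
      mask[sigTaxa[k], sigPreb[k]] <- TRUE
    }
    # centre slope columns so true effects live on the CLR scale
    LambdaClr[, -1L] <- sweep(LambdaClr[, -1L, drop = FALSE], 2L,
                              colMeans(LambdaClr[, -1L, drop = FALSE]), "-")
    depths <- round(runif(ncol(X), 0.75, 1.25) * depth)
    list(LambdaClr = LambdaClr, mask = mask, depths = depths)
  })
  # ALR-scale generator quantities (reference = last genus)
  LambdaAlr <- truth$LambdaClr[-D, , drop = FALSE] -
    matrix(truth$LambdaClr[D, ], D - 1L, Q, byrow = TRUE)
  SigmaTrue <- matrix(0.5, D - 1L, D - 1L); diag(SigmaTrue) <- 1
  cscen <- compositionScenario(D = D, Q = Q, LambdaTrue = LambdaAlr,
                               SigmaTrue = SigmaTrue,
                               depth = truth$depths, seed = seed + 3L)
  Y <- simulateCounts(cscen, X)
  rownames(Y) <- rownames(truth$LambdaClr)
  taxonomy <- data.frame(
    taxon_id = rownames(Y),
    kingdom = "Bacteria",
    phylum = paste0("Phylum_", LETTERS[(seq_len(D) - 1L) %% 6L + 1L]),
    class = paste0("Class_", LETTERS[(seq_len(D) - 1L) %% 9L + 1L]),
    order = paste0("Order_", sprintf("%02d", (seq_len(D) - 1L) %% 14L + 1L)),
    family = paste0("Family_", sprintf("%02d", (seq_len(D) - 1L) %% 25L + 1L)),
    genus = rownames(Y),
    stringsAsFactors = FALSE)
  se <- taxaCountExperiment(Y, taxonomy)
  S4Vectors::metadata(se)$seed <- seed
  list(scfa = scfa,
       foldChange = fc,
       counts = se,
       covariates = X,
       taxonomy = taxonomy,
       groundTruth = list(LambdaClr = truth$LambdaClr,
                          signalMask = truth$mask,
                          sigmaTrue = SigmaTrue,
                          depths = truth$depths,
                          prebioticEffects = ferm$prebioticEffects,
                          interactionEffects = ferm$interactionEffects,
                          noiseCV = noiseCV,
                          effectSize = effectSize),
       seed = seed)
}
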