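#' @include scfaferm-package.R
NULL

# Canonical C2:C5 acid vocabulary used throughout the package.
SCFA_ACIDS <- c("acetate", "propionate", "isobutyrate", "butyrate",
                "isovalerate", "valerate")

#' Calibration curve for one SCFA
#'
#' Ordinary least-squares line relating detector response to analyte
#' concentration, fitted from an external standard series
#' (`response = slope * concentration + intercept`).
#'
#' @slot acid acid name (one of the C2:C5 vocabulary, or `""` if generic).
#' @slot slope response units per mM; must be positive.
#' @slot intercept response at 0 mM.
#' @slot rSquared coefficient of determination of the fit, in \[0, 1\].
#' @slot standardConcentrations mM values of the standards used.
#' @seealso [fitStandardCurve()], [quantifyScfa()]
#' @export
setClass("CalibrationCurve",
  representation(
    acid = "character",
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    standardConcentrations = "numeric"
  )
)

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    msg <- c(msg, "slope must be a single positive finite number")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (length(object@rSquared) != 1L || is.na(object@rSquared) ||
      object@rSquared < -1e-8 || object@rSquared > 1 + 1e-8)
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve", if (nzchar(object@acid)) paste0("[", object@acid, "]"),
      "\n  response =", format(object@slope, digits = 5), "* mM +",
      format(object@intercept, digits = 5),
      sprintf("  (R^2 = %.4f, %d standards)\n", object@rSquared,
              length(object@standardConcentrations)))
})

#' Fermentation study scenario
#'
#' Generative description of an in vitro fermentation screen: each donor's
#' stool slurry is incubated with each prebiotic (plus an unsupplemented
#' control) in replicate vessels.  Expected treatment total SCFA is
#' `controlMeanMM * donorEffect * prebioticEffect * interactionEffect`;
#' control vessels carry the donor effect only, so noise-free fold changes
#' equal `prebioticEffect * interactionEffect`.  Replicate noise is
#' multiplicative lognormal with coefficient of variation `noiseCV`.
#'
#' @slot nDonors number of stool donors.
#' @slot prebiotics treatment names (controls are added automatically).
#' @slot nReplicates vessels per donor x treatment.
#' @slot donorEffects per-donor multiplicative acidogenic capacity (> 0).
#' @slot prebioticEffects per-prebiotic multiplicative effect (> 0).
#' @slot interactionEffects donors x prebiotics matrix of multipliers (> 0).
#' @slot controlMeanMM baseline total SCFA (mM) of a control vessel.
#' @slot noiseCV coefficient of variation of replicate noise (>= 0).
#' @slot seed integer RNG seed.
#' @seealso [fermentationScenario()], [simulateFermentation()]
#' @export
setClass("FermentationScenario",
  representation(
    nDonors = "integer",
    prebiotics = "character",
    nReplicates = "integer",
    donorEffects = "numeric",
    prebioticEffects = "numeric",
    interactionEffects = "matrix",
    controlMeanMM = "numeric",
    noiseCV = "numeric",
    seed = "integer"
  )
)

setValidity("FermentationScenario", function(object) {
  msg <- character()
  if (object@nDonors < 1L) msg <- c(msg, "nDonors must be >= 1")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (!length(object@prebiotics) || anyDuplicated(object@prebiotics))
    msg <- c(msg, "prebiotics must be a non-empty set of unique names")
  if ("control" %in% object@prebiotics)
    msg <- c(msg, "'control' is reserved for the unsupplemented vessel")
  if (length(object@donorEffects) != object@nDonors ||
      any(!is.finite(object@donorEffects)) || any(object@donorEffects <= 0))
    msg <- c(msg, "donorEffects must be nDonors positive numbers")
  if (length(object@prebioticEffects) != length(object@prebiotics) ||
      any(!is.finite(object@prebioticEffects)) ||
      any(object@prebioticEffects <= 0))
    msg <- c(msg, "prebioticEffects must be positive, one per prebiotic")
  if (!identical(dim(object@interactionEffects),
                 c(object@nDonors, length(object@prebiotics))) ||
      any(!is.finite(object@interactionEffects)) ||
      any(object@interactionEffects <= 0))
    msg <- c(msg, "interactionEffects must be a positive nDonors x nPrebiotics matrix")
  if (object@controlMeanMM <= 0)
    msg <- c(msg, "controlMeanMM must be positive")
  if (!is.finite(object@noiseCV) || object@noiseCV < 0)
    msg <- c(msg, "noiseCV must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "FermentationScenario", function(object) {
  cat("FermentationScenario:", object@nDonors, "donors x",
      length(object@prebiotics), "prebiotics (+ control) x",
      object@nReplicates, "replicates\n",
      " control mean =", object@controlMeanMM, "mM; noise CV =",
      object@noiseCV, "; seed =", object@seed, "\n")
})

#' Compositional count scenario
#'
#' Generative description of genus-level 16S count tables under the
#' multinomial logistic-normal linear model: latent additive log-ratio (ALR)
#' coordinates `eta_j ~ N(LambdaTrue %*% x_j, SigmaTrue)` are mapped through
#' the inverse ALR transform (reference = last taxon) to a composition, then
#' multinomial counts are drawn at the given depth.
#'
#' @slot D number of taxa.
#' @slot Q number of covariates.
#' @slot LambdaTrue (D-1) x Q matrix of true ALR-scale effects.
#' @slot SigmaTrue (D-1) x (D-1) symmetric positive-definite covariance.
#' @slot depth sequencing depth per sample (counts, >= 0; one value recycled
#'   or one per sample).
#' @slot seed integer RNG seed.
#' @seealso [compositionScenario()], [simulateCounts()]
#' @export
setClass("CompositionScenario",
  representation(
    D = "integer",
    Q = "integer",
    LambdaTrue = "matrix",
    SigmaTrue = "matrix",
    depth = "numeric",
    seed = "integer"
  )
)

setValidity("CompositionScenario", function(object) {
  msg <- character()
  d <- object@D - 1L
  if (object@D < 2L) msg <- c(msg, "D must be >= 2")
  if (object@Q < 1L) msg <- c(msg, "Q must be >= 1")
  if (!identical(dim(object@LambdaTrue), c(d, object@Q)))
    msg <- c(msg, "LambdaTrue must be (D-1) x Q")
  if (!identical(dim(object@SigmaTrue), c(d, d)) ||
      !isSymmetric(unname(object@SigmaTrue), tol = 1e-8))
    msg <- c(msg, "SigmaTrue must be symmetric (D-1) x (D-1)")
  else if (inherits(try(chol(object@SigmaTrue), silent = TRUE), "try-error"))
    msg <- c(msg, "SigmaTrue must be positive-definite")
  if (any(object@depth < 0) || any(!is.finite(object@depth)))
    msg <- c(msg, "depth must be non-negative and finite")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "CompositionScenario", function(object) {
  cat("CompositionScenario: D =", object@D, "taxa, Q =", object@Q,
      "covariates, depth ~", round(mean(object@depth)),
      "; seed =", object@seed, "\n")
})

#' Priors of the multinomial logistic-normal regression
#'
#' Conjugate prior block of the pibble model on ALR coordinates
#' (reference = last taxon):
#' `Lambda ~ MatrixNormal(Theta, Sigma, Gamma)` and
#' `Sigma ~ InverseWishart(Xi, upsilon)`.
#'
#' @slot Theta (D-1) x Q prior mean of ALR-scale effects.
#' @slot Gamma Q x Q covariance across covariates (positive-definite).
#' @slot Xi (D-1) x (D-1) inverse-Wishart scale matrix (positive-definite).
#' @slot upsilon inverse-Wishart degrees of freedom; must exceed (D-1) + 1 so
#'   that `E[Sigma] = Xi / (upsilon - (D-1) - 1)` exists.
#' @seealso [defaultPriors()], [pibble()]
#' @export
setClass("PibblePriors",
  representation(
    Theta = "matrix",
    Gamma = "matrix",
    Xi = "matrix",
    upsilon = "numeric"
  )
)

setValidity("PibblePriors", function(object) {
  msg <- character()
  d <- nrow(object@Theta)
  q <- ncol(object@Theta)
  if (any(!is.finite(object@Theta)))
    msg <- c(msg, "Theta must be finite")
  if (!identical(dim(object@Gamma), c(q, q)) ||
      !isSymmetric(unname(object@Gamma), tol = 1e-8))
    msg <- c(msg, "Gamma must be symmetric Q x Q")
  else if (inherits(try(chol(object@Gamma), silent = TRUE), "try-error"))
    msg <- c(msg, "Gamma must be positive-definite")
  if (!identical(dim(object@Xi), c(d, d)) ||
      !isSymmetric(unname(object@Xi), tol = 1e-8))
    msg <- c(msg, "Xi must be symmetric (D-1) x (D-1)")
  else if (inherits(try(chol(object@Xi), silent = TRUE), "try-error"))
    msg <- c(msg, "Xi must be positive-definite")
  if (length(object@upsilon) != 1L || object@upsilon <= d + 1)
    msg <- c(msg, "upsilon must exceed (D-1) + 1")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PibblePriors", function(object) {
  d <- nrow(object@Theta)
  cat("PibblePriors: D =", d + 1L, "taxa (ALR dim", d, "), Q =",
      ncol(object@Theta), "covariates, upsilon =", object@upsilon, "\n")
})

#' Multinomial logistic-normal regression model
#'
#' Data and priors of the pibble model: counts `Y` (D taxa x N samples),
#' covariates `X` (Q x N, first row conventionally an intercept of ones) and
#' a [PibblePriors-class] block.  The generative model is
#' `Y_j ~ Multinomial(pi_j)`, `pi_j = alrInv(eta_j)`,
#' `eta_j ~ N(Lambda x_j, Sigma)`, `Lambda ~ MN(Theta, Sigma, Gamma)`,
#' `Sigma ~ IW(Xi, upsilon)`.
#'
#' @slot Y D x N non-negative integer count matrix with taxon row names.
#' @slot X Q x N real covariate matrix with covariate row names.
#' @slot priors a [PibblePriors-class] object of matching dimension.
#' @seealso [pibbleModel()], [pibble()]
#' @export
setClass("PibbleModel",
  representation(
    Y = "matrix",
    X = "matrix",
    priors = "PibblePriors"
  )
)

setValidity("PibbleModel", function(object) {
  msg <- character()
  Y <- object@Y; X <- object@X
  if (any(Y < 0) || any(Y != round(Y)))
    msg <- c(msg, "Y must contain non-negative integers")
  if (ncol(Y) != ncol(X))
    msg <- c(msg, "Y and X must have the same number of samples (columns)")
  if (any(colSums(Y) <= 0))
    msg <- c(msg, "every sample must have a positive total count")
  if (nrow(object@priors@Theta) != nrow(Y) - 1L)
    msg <- c(msg, "priors have wrong taxon dimension (need (D-1) rows)")
  if (ncol(object@priors@Theta) != nrow(X))
    msg <- c(msg, "priors have wrong covariate dimension")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PibbleModel", function(object) {
  cat("PibbleModel: D =", nrow(object@Y), "taxa, N =", ncol(object@Y),
      "samples, Q =", nrow(object@X), "covariates\n")
})

#' Posterior sample from a fitted pibble model
#'
#' Holds posterior draws of the ALR-scale effect matrix `Lambda`, the ALR
#' covariance `Sigma` and the latent coordinates `eta`, together with the
#' Laplace-approximation mode and optimizer diagnostics.
#'
#' @slot model the [PibbleModel-class] that was fitted.
#' @slot LambdaDraws (D-1) x Q x nSamples array of effect draws (ALR scale).
#' @slot SigmaDraws (D-1) x (D-1) x nSamples array of covariance draws.
#' @slot etaDraws (D-1) x N x nSamples array of latent coordinate draws.
#' @slot etaMap the MAP estimate of eta under the collapsed posterior.
#' @slot diagnostics list: `converged`, `gradNorm`, `iterations`,
#'   `logPosterior` (at the mode), `logPosteriorInit`.
#' @slot seed seed used for posterior sampling (NA if none supplied).
#' @seealso [pibble()], [summarizePosterior()]
#' @export
setClass("PibbleFit",
  representation(
    model = "PibbleModel",
    LambdaDraws = "array",
    SigmaDraws = "array",
    etaDraws = "array",
    etaMap = "matrix",
    diagnostics = "list",
    seed = "integer"
  )
)

#' @export
setMethod("show", "PibbleFit", function(object) {
  cat("PibbleFit:", dim(object@LambdaDraws)[3], "posterior draws;",
      "D =", nrow(object@model@Y), ", Q =", nrow(object@model@X),
      ", N =", ncol(object@model@Y), "\n",
      " MAP gradient sup-norm:",
      format(object@diagnostics$gradNorm, digits = 3),
      if (isTRUE(object@diagnostics$converged)) "(converged)" else
        "(NOT converged)", "\n")
})

#' Posterior effect summary on the CLR scale
#'
#' Per (taxon, covariate) posterior mean and equal-tailed credible intervals
#' of the centred log-ratio (CLR) effect, with a credible-association flag
#' (95% interval excluding zero).
#'
#' @slot summary data.frame with columns `taxon`, `covariate`, `mean`, then
#'   `lowerXX`/`upperXX` per interval level, and `credible`.
#' @slot levels the credible-interval levels summarised.
#' @slot nDraws number of posterior draws summarised.
#' @seealso [summarizePosterior()]
#' @export
setClass("PibbleSummary",
  representation(
    summary = "data.frame",
    levels = "numeric",
    nDraws = "integer"
  )
)

#' @export
setMethod("show", "PibbleSummary", function(object) {
  ncred <- sum(object@summary$credible)
  cat("PibbleSummary:", nrow(object@summary), "taxon x covariate effects,",
      object@nDraws, "draws;", ncred,
      "credible at 95% (interval excludes 0)\n")
})
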