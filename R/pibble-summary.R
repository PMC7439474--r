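#' @include AllClasses.R pibble.R
NULL

#' Summarise posterior effects on the CLR scale
#'
#' Transforms every posterior draw of the ALR-scale effect matrix `Lambda`
#' to centred log-ratio coordinates (reference-free, taxon dimension summing
#' to zero), then reports per (taxon, covariate) the posterior mean and
#' equal-tailed credible intervals at the requested levels.  An effect is
#' flagged as a credible association when its 95% interval excludes zero.
#' On this scale an effect of 1 means a unit fold change in SCFA
#' concentration over control is associated with a unit change in the
#' CLR-transformed relative abundance of the taxon.
#'
#' @param fit a [PibbleFit-class] from [pibble()], or a (D-1) x Q x S array
#'   of ALR-scale effect draws.
#' @param levels credible-interval levels (default 0.5, 0.8, 0.95, 0.99).
#' @param taxa optional taxon names of length D (derived from the fit when
#'   omitted).
#' @return a [PibbleSummary-class]; its `summary` slot has one row per
#'   (taxon, covariate) with columns `mean`, `lowerXX`/`upperXX` per level
#'   and `credible`.
#' @export
summarizePosterior <- function(fit, levels = c(0.5, 0.8, 0.95, 0.99),
                               taxa = NULL) {
  draws <- if (is(fit, "PibbleFit")) fit@LambdaDraws else fit
  if (length(dim(draws)) != 3L)
    stop("expected a 3-d array of effect draws")
  S <- dim(draws)[3L]
  if (S < 2L) stop("need at least 2 posterior draws")
  levels <- sort(levels)
  if (any(levels <= 0 | levels >= 1)) stop("levels must lie in (0, 1)")
  if (!0.95 %in% levels) levels <- sort(c(levels, 0.95))
  d <- dim(draws)[1L]; Q <- dim(draws)[2L]; D <- d + 1L
  if (is.null(taxa)) {
    taxa <- if (is(fit, "PibbleFit")) rownames(fit@model@Y) else NULL
    if (is.null(taxa)) taxa <- paste0("Taxon_", seq_len(D))
  }
  covariates <- dimnames(draws)[[2L]] %||% paste0("x", seq_len(Q))
  # CLR transform of each draw
  clrDraws <- array(NA_real_, c(D, Q, S))
  for (s in seq_len(S))
    clrDraws[, , s] <- alrEffectsToClr(draws[, , s, drop = FALSE][, , 1L])
  flat <- matrix(clrDraws, D * Q, S)  # rows: taxon fastest, then covariate
  means <- rowMeans(flat)
  probs <- as.vector(rbind((1 - levels) / 2, 1 - (1 - levels) / 2))
  qs <- t(apply(flat, 1L, quantile, probs = probs, names = FALSE))
  lvltag <- function(l) sub("^0\\.", "", format(l * 100))
  colnames(qs) <- as.vector(rbind(paste0("lower", lvltag(levels)),
                                  paste0("upper", lvltag(levels))))
  credible <- qs[, paste0("lower", lvltag(0.95))] > 0 |
              qs[, paste0("upper", lvltag(0.95))] < 0
  out <- data.frame(
    taxon = rep(taxa, times = Q),
    covariate = rep(covariates, each = D),
    mean = means,
    qs,
    credible = unname(credible),
    row.names = NULL,
    stringsAsFactors = FALSE)
  new("PibbleSummary", summary = out, levels = levels,
      nDraws = as.integer(S))
}

#' Extract the summary table
#'
#' @param object a [PibbleSummary-class].
#' @return the per-effect summary data.frame.
#' @export
summaryTable <- function(object) {
  stopifnot(is(object, "PibbleSummary"))
  object@summary
}

#' Credibly associated effects
#'
#' Convenience accessor returning the (taxon, covariate) rows whose 95%
#' credible interval excludes zero, excluding the intercept row by default.
#'
#' @param object a [PibbleSummary-class].
#' @param excludeIntercept drop effects of the covariate named
#'   `"intercept"` (default TRUE).
#' @return subset of the summary data.frame.
#' @export
credibleAssociations <- function(object, excludeIntercept = TRUE) {
  tab <- summaryTable(object)
  tab <- tab[tab$credible, , drop = FALSE]
  if (excludeIntercept)
    tab <- tab[tab$covariate != "intercept", , drop = FALSE]
  tab
}
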