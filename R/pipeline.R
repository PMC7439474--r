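#' @include io.R pibble.R pibble-summary.R stats.R
NULL

#' Assemble a pipeline configuration
#'
#' @param scfaPath path to the long-format SCFA CSV.
#' @param countPath path to the taxa x samples count TSV.
#' @param taxonomyPath path to the taxonomy TSV (optional; when given,
#'   counts are amalgamated to the genus level before filtering).
#' @param outDir output directory (created if missing).
#' @param prebiotics prebiotic set used as covariates (default: all present
#'   in the fold-change table).
#' @param minCount,minSamples prevalence-filter thresholds (default 3, 3).
#' @param nSamples posterior draws (default 2000).
#' @param seed RNG seed recorded in all outputs.
#' @param priorArgs named list of overrides passed to [defaultPriors()]
#'   (e.g. `list(slopeVar = 2, slopeCov = 0.6)`).
#' @return config list for [runPipeline()].
#' @export
pipelineConfig <- function(scfaPath, countPath, taxonomyPath = NULL,
                           outDir = "scfaferm-out", prebiotics = NULL,
                           minCount = 3, minSamples = 3, nSamples = 2000,
                           seed = 1L, priorArgs = list()) {
  list(scfaPath = scfaPath, countPath = countPath,
       taxonomyPath = taxonomyPath, outDir = outDir,
       prebiotics = prebiotics, minCount = minCount,
       minSamples = minSamples, nSamples = nSamples,
       seed = as.integer(seed), priorArgs = priorArgs)
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: SCFA quantification (totals and control-corrected
#' fold changes), univariate statistics (two-way donor x prebiotic ANOVA on
#' replicate-level fold changes, and a Spearman correlation between each
#' donor's mean fold change and the Shannon diversity of their community),
#' compositional preprocessing (optional genus amalgamation, prevalence
#' filtering), and the multinomial logistic-normal regression with CLR
#' posterior summaries.  All outputs are written under `config$outDir`
#' together with a provenance manifest (package version, seed, config
#' hash).  Any stage failure aborts with the stage name and cause.
#'
#' @param config list from [pipelineConfig()].
#' @return (invisibly) list with elements `foldChange`, `anova`,
#'   `correlation`, `counts` (filtered matrix), `fit`, `summary`,
#'   `manifest`.
#' @export
runPipeline <- function(config) {
  for (p in c("scfaPath", "countPath")) {
    if (is.null(config[[p]]) || !file.exists(config[[p]]))
      stop("config$", p, " does not exist: ",
           if (is.null(config[[p]])) "(unset)" else config[[p]])
  }
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)

  scfa <- .stage("read-scfa", readScfaTable(config$scfaPath))
  fc <- .stage("fold-change", foldChange(scfa))
  writeFoldChange(fc, out("fold_change.csv"))

  anova <- .stage("anova",
    twoWayAnova(fc$fold_change, fc$donor, fc$prebiotic))
  write.csv(cbind(term = rownames(anova), anova), out("anova.csv"),
            row.names = FALSE)

  counts <- .stage("read-counts", readCountTable(config$countPath))
  if (!is.null(config$taxonomyPath)) {
    tax <- .stage("read-taxonomy", readTaxonomy(config$taxonomyPath))
    counts <- .stage("amalgamate", amalgamateToGenus(counts, tax))
  }
  filtered <- .stage("prevalence-filter",
    filterPrevalence(counts, minCount = config$minCount,
                     minSamples = config$minSamples))
  writeJson(list(minCount = config$minCount,
                 minSamples = config$minSamples,
                 retainedFraction = attr(filtered, "retainedFraction"),
                 retainedTaxa = attr(filtered, "retainedTaxa")),
            out("prevalence_filter.json"))
  writeCountTable(filtered, out("filtered_counts.tsv"))

  corr <- .stage("correlation", {
    meanFc <- aggregate(fold_change ~ donor, data = fc, FUN = mean)
    common <- intersect(meanFc$donor, colnames(filtered))
    if (length(common) >= 3L) {
      sh <- shannonDiversity(filtered[, common, drop = FALSE])
      spearmanCorrelation(meanFc$fold_change[match(common, meanFc$donor)],
                          sh)
    } else NULL
  })
  if (!is.null(corr))
    writeJson(corr, out("correlation.json"))

  fit <- .stage("regression", {
    X <- buildCovariates(fc, prebiotics = config$prebiotics)
    common <- intersect(colnames(X), colnames(filtered))
    if (length(common) < 2L)
      stop("covariate and count samples do not overlap")
    priors <- do.call(defaultPriors,
                      c(list(D = nrow(filtered), Q = nrow(X)),
                        config$priorArgs))
    pibble(filtered[, common, drop = FALSE], X[, common, drop = FALSE],
           priors = priors, nSamples = config$nSamples,
           seed = config$seed)
  })
  summ <- .stage("summarize", summarizePosterior(fit))
  write.csv(summaryTable(summ), out("posterior_summary.csv"),
            row.names = FALSE)

  manifest <- list(
    package = "scfaferm",
    version = as.character(packageVersion("scfaferm")),
    seed = config$seed,
    configHash = .configHash(config),
    converged = fit@diagnostics$converged,
    nSamples = config$nSamples,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  writeJson(manifest, out("manifest.json"))

  invisible(list(foldChange = fc, anova = anova, correlation = corr,
                 counts = filtered, fit = fit, summary = summ,
                 manifest = manifest))
}
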