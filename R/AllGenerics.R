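#' @include AllClasses.R
NULL

#' Amalgamate sequence-variant counts to the genus level
#'
#' Sums the counts of sequence variants (SVs) sharing a genus label into one
#' row per genus.  Column (sample) sums are preserved exactly.  SVs whose
#' genus is unresolved are grouped under `unclassified_<lowest resolved rank>`
#' rather than dropped, so no counts are lost.
#'
#' @param x a taxa x samples count matrix, or a
#'   [SummarizedExperiment::SummarizedExperiment-class] whose first assay
#'   holds counts and whose `rowData` holds the taxonomy ranks.
#' @param taxonomy for the matrix method, a data.frame with a `taxon_id`
#'   column matching `rownames(x)` and rank columns
#'   (`kingdom`,...,`genus`).
#' @param ... passed between methods.
#' @return an object of the same class as `x` with one row per genus.
#' @export
setGeneric("amalgamateToGenus",
           function(x, taxonomy, ...) standardGeneric("amalgamateToGenus"))

#' Prevalence filtering of a count table
#'
#' Retains taxa observed with at least `minCount` counts in each of at least
#' `minSamples` samples (i.e. `sum(counts >= minCount) >= minSamples` per
#' taxon row).  The retained fraction of total counts and the retained taxon
#' set are recorded on the result.
#'
#' @param x a taxa x samples count matrix or a
#'   [SummarizedExperiment::SummarizedExperiment-class].
#' @param minCount minimum per-sample count for a taxon to be "observed"
#'   in that sample (default 3).
#' @param minSamples minimum number of qualifying samples (default 3).
#' @param ... passed between methods.
#' @return filtered object of the same class as `x`.  Matrix results carry
#'   attributes `retainedFraction` and `retainedTaxa`; SummarizedExperiment
#'   results record the same under `metadata(x)$prevalenceFilter`.
#' @export
setGeneric("filterPrevalence",
           function(x, minCount = 3, minSamples = 3, ...)
             standardGeneric("filterPrevalence"))
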