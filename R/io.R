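#' @include AllClasses.R counts.R scfa.R
NULL

#' Read / write SCFA measurement tables
#'
#' Long-format CSV with columns `donor,treatment,replicate,acid,
#' concentration_mM`.  Acid names are validated against the C2:C5
#' vocabulary; unknown names are rejected naming the offender.
#'
#' @param path file path.
#' @return `readScfaTable`: the validated data.frame.
#' @export
readScfaTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .checkProfiles(df)
  df
}

#' @rdname readScfaTable
#' @param profiles long-format SCFA table (see [totalScfa()]).
#' @export
writeScfaTable <- function(profiles, path) {
  .checkProfiles(profiles)
  write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write taxa x samples count tables
#'
#' Tab-separated, first column `taxon_id`, remaining columns one per sample
#' (header row of sample IDs).  Entries must be non-negative integers and
#' labels unique.
#'
#' @param path file path.
#' @return `readCountTable`: integer matrix with taxon row names.
#' @export
readCountTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a taxon column plus samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate taxon labels in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample labels in ", path)
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) ||
      any(m != round(m)))
    stop("count table must contain non-negative integers: ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname readCountTable
#' @param counts taxa x samples integer matrix.
#' @export
writeCountTable <- function(counts, path) {
  .checkCounts(counts)
  df <- data.frame(taxon_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write taxonomy tables
#'
#' Tab-separated with a `taxon_id` column and rank columns (kingdom to
#' genus).
#'
#' @param path file path.
#' @return `readTaxonomy`: data.frame of rank labels.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(df))
    stop("taxonomy table needs a 'taxon_id' column: ", path)
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id in ", path)
  df
}

#' @rdname readTaxonomy
#' @param taxonomy data.frame with `taxon_id` and rank columns.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  if (!"taxon_id" %in% names(taxonomy))
    stop("taxonomy table needs a 'taxon_id' column")
  write.table(taxonomy, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write fold-change tables
#'
#' Tidy CSV with columns `donor,prebiotic,replicate,fold_change`.
#'
#' @param path file path.
#' @return `readFoldChange`: the data.frame.
#' @export
readFoldChange <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("donor", "prebiotic", "replicate", "fold_change")
  if (!all(needed %in% names(df)))
    stop("fold-change table needs columns: ", paste(needed, collapse = ", "))
  if (any(!is.finite(df$fold_change)) || any(df$fold_change <= 0))
    stop("fold changes must be positive and finite")
  df
}

#' @rdname readFoldChange
#' @param foldChanges data.frame from [foldChange()].
#' @export
writeFoldChange <- function(foldChanges, path) {
  write.csv(foldChanges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write covariate matrices
#'
#' CSV with a `covariate` label column and one column per sample.
#'
#' @param path file path.
#' @return `readCovariates`: Q x N numeric matrix.
#' @export
readCovariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("covariates must be finite numbers: ", path)
  m
}

#' @rdname readCovariates
#' @param X Q x N covariate matrix with row and column names.
#' @export
writeCovariates <- function(X, path) {
  df <- data.frame(covariate = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground truth or generic results as JSON
#'
#' @param x list to serialise (matrices become row-major nested arrays with
#'   dimnames preserved by jsonlite conventions).
#' @param path file path.
#' @export
writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
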