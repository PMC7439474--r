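#' @include AllGenerics.R
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                    "genus")

.checkCounts <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("count table must be a numeric matrix (taxa x samples)")
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("count table must contain non-negative integers")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("count table must have unique taxon row names")
  invisible(x)
}

# Resolve a genus label per taxonomy row; unresolved genera are grouped as
# unclassified_<lowest resolved rank>.
.genusLabels <- function(taxonomy) {
  ranks <- intersect(TAXONOMY_RANKS, colnames(taxonomy))
  if (!"genus" %in% ranks)
    stop("taxonomy must contain a 'genus' column")
  vapply(seq_len(nrow(taxonomy)), function(i) {
    g <- taxonomy[i, "genus"]
    if (!is.na(g) && nzchar(g)) return(as.character(g))
    for (r in rev(setdiff(ranks, "genus"))) {
      v <- taxonomy[i, r]
      if (!is.na(v) && nzchar(v))
        return(paste0("unclassified_", v))
    }
    "unclassified_unknown"
  }, character(1L))
}

#' @rdname amalgamateToGenus
#' @export
setMethod("amalgamateToGenus", signature(x = "matrix", taxonomy = "data.frame"),
  function(x, taxonomy, ...) {
    .checkCounts(x)
    idcol <- if ("taxon_id" %in% colnames(taxonomy)) taxonomy$taxon_id
             else rownames(taxonomy)
    missing <- setdiff(rownames(x), idcol)
    if (length(missing))
      stop("taxa missing from taxonomy: ", paste(missing, collapse = ", "))
    taxonomy <- taxonomy[match(rownames(x), idcol), , drop = FALSE]
    genus <- .genusLabels(taxonomy)
    out <- rowsum(x, group = genus, reorder = TRUE)
    storage.mode(out) <- storage.mode(x)
    out
  })

#' @rdname amalgamateToGenus
#' @export
setMethod("amalgamateToGenus",
  signature(x = "SummarizedExperiment", taxonomy = "missing"),
  function(x, taxonomy, ...) {
    tax <- as.data.frame(SummarizedExperiment::rowData(x))
    tax$taxon_id <- rownames(x)
    counts <- SummarizedExperiment::assay(x, 1L)
    agg <- amalgamateToGenus(as.matrix(counts), tax)
    genus <- .genusLabels(tax)
    ranks <- intersect(TAXONOMY_RANKS, colnames(tax))
    # carry over ranks above genus where they are constant within a genus
    rd <- do.call(rbind, lapply(rownames(agg), function(g) {
      rows <- tax[genus == g, ranks, drop = FALSE]
      out <- lapply(rows, function(col) {
        u <- unique(col)
        if (length(u) == 1L) u else NA_character_
      })
      as.data.frame(out, stringsAsFactors = FALSE)
    }))
    rd$genus <- rownames(agg)
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = agg),
      rowData = S4Vectors::DataFrame(rd, row.names = rownames(agg)),
      colData = SummarizedExperiment::colData(x),
      metadata = S4Vectors::metadata(x))
  })

#' @rdname filterPrevalence
#' @export
setMethod("filterPrevalence", "matrix",
  function(x, minCount = 3, minSamples = 3, ...) {
    .checkCounts(x)
    keep <- rowSums(x >= minCount) >= minSamples
    if (!any(keep))
      stop("prevalence filter removed all taxa; downstream model undefined")
    out <- x[keep, , drop = FALSE]
    attr(out, "retainedFraction") <- sum(out) / sum(x)
    attr(out, "retainedTaxa") <- rownames(out)
    out
  })

#' @rdname filterPrevalence
#' @export
setMethod("filterPrevalence", "SummarizedExperiment",
  function(x, minCount = 3, minSamples = 3, ...) {
    counts <- as.matrix(SummarizedExperiment::assay(x, 1L))
    filt <- filterPrevalence(counts, minCount = minCount,
                             minSamples = minSamples)
    out <- x[rownames(filt), ]
    S4Vectors::metadata(out)$prevalenceFilter <- list(
      minCount = minCount, minSamples = minSamples,
      retainedFraction = attr(filt, "retainedFraction"),
      retainedTaxa = rownames(filt))
    out
  })

#' Assemble a taxa x samples SummarizedExperiment
#'
#' Convenience constructor pairing a count matrix with its taxonomy table in
#' the standard Bioconductor container.
#'
#' @param counts taxa x samples non-negative integer matrix with row and
#'   column names.
#' @param taxonomy data.frame of rank labels, either with a `taxon_id`
#'   column or with row names matching `rownames(counts)`.
#' @return a [SummarizedExperiment::SummarizedExperiment-class] with assay
#'   `counts` and the taxonomy in `rowData`.
#' @export
taxaCountExperiment <- function(counts, taxonomy = NULL) {
  .checkCounts(counts)
  rd <- NULL
  if (!is.null(taxonomy)) {
    idcol <- if ("taxon_id" %in% colnames(taxonomy)) taxonomy$taxon_id
             else rownames(taxonomy)
    missing <- setdiff(rownames(counts), idcol)
    if (length(missing))
      stop("taxa missing from taxonomy: ", paste(missing, collapse = ", "))
    taxonomy <- taxonomy[match(rownames(counts), idcol), , drop = FALSE]
    taxonomy$taxon_id <- NULL
    rd <- S4Vectors::DataFrame(taxonomy, row.names = rownames(counts))
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd)
}
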