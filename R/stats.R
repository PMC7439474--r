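#' @include AllClasses.R
NULL

#' Two-way fixed-effects ANOVA with interaction
#'
#' Classical balanced two-way ANOVA decomposing a response (e.g. total-SCFA
#' fold change over control) into main effects of two crossed factors
#' (donor, prebiotic), their interaction and residual replicate variation.
#' Technical replicates enter as individual rows, not as cell means.
#' Unbalanced designs are rejected: in a balanced design the classical
#' decomposition is unique, whereas unbalanced data would silently commit to
#' a sums-of-squares convention.
#'
#' @param response numeric response values, one per vessel.
#' @param factorA first factor labels (e.g. donor).
#' @param factorB second factor labels (e.g. prebiotic).
#' @param nameA,nameB row labels used in the output table.
#' @return data.frame with rows `nameA`, `nameB`, `nameA:nameB`,
#'   `Residuals` and columns `Df`, `SumSq`, `MeanSq`, `F`, `p`.  When the
#'   response is constant all sums of squares are 0, F is reported as `NaN`
#'   and p as 1 (no evidence against the null).
#' @export
twoWayAnova <- function(response, factorA, factorB,
                        nameA = "donor", nameB = "prebiotic") {
  if (length(response) != length(factorA) ||
      length(response) != length(factorB))
    stop("response and factors must have equal length")
  a <- factor(factorA); b <- factor(factorB)
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("each factor needs at least 2 levels")
  cells <- table(a, b)
  if (any(cells == 0L) || length(unique(as.vector(cells))) != 1L)
    stop("unbalanced design: all factor-level combinations must have the ",
         "same number of replicates")
  if (cells[1L] < 2L)
    stop("interaction term requires >= 2 replicates per cell")
  terms <- c(nameA, nameB, paste0(nameA, ":", nameB), "Residuals")
  dfs <- c(nlevels(a) - 1L, nlevels(b) - 1L,
           (nlevels(a) - 1L) * (nlevels(b) - 1L))
  if (sd(response) == 0) {
    # constant response: no variation to attribute, F undefined
    out <- data.frame(Df = c(dfs, length(response) - 1L - sum(dfs)),
                      SumSq = 0, MeanSq = 0,
                      F = c(NaN, NaN, NaN, NA), p = c(1, 1, 1, NA))
    rownames(out) <- terms
    return(out)
  }
  fit <- aov(response ~ a * b)
  tab <- summary(fit)[[1L]]
  out <- data.frame(
    Df = tab$Df,
    SumSq = tab$`Sum Sq`,
    MeanSq = tab$`Mean Sq`,
    F = c(tab$`F value`),
    p = c(tab$`Pr(>F)`)
  )
  rownames(out) <- terms
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties).  The two-sided
#' p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom; an
#' exact permutation p-value is available for small samples without ties.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param exact logical; exact permutation p-value (only possible without
#'   ties).  Default: exact when `n <= 10` and tie-free, else t
#'   approximation.
#' @return list with elements `rho`, `p.value`, `n`, `method`.
#' @export
spearmanCorrelation <- function(x, y, exact = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("rho undefined for a constant input vector")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (is.null(exact)) exact <- n <= 10L && !ties
  if (exact && ties) {
    warning("ties present; falling back to the t approximation")
    exact <- FALSE
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = n,
       method = if (exact) "exact permutation" else "t approximation")
}

#' Shannon diversity
#'
#' Shannon entropy `H = -sum p_i log p_i` (natural log, nats) of a sample's
#' taxon proportions `p = counts / sum(counts)`, zero-count taxa excluded.
#'
#' @param counts non-negative numeric vector of taxon counts for one sample,
#'   or a taxa x samples matrix (computed per column).
#' @return numeric diversity value(s) in nats.
#' @export
shannonDiversity <- function(counts) {
  if (is.null(dim(counts))) {
    if (any(counts < 0)) stop("counts must be non-negative")
    if (sum(counts) == 0) stop("all-zero sample: diversity undefined")
    unname(vegan::diversity(counts, index = "shannon"))
  } else {
    apply(counts, 2L, shannonDiversity)
  }
}

#' Paired t test
#'
#' Two-sided paired t test on the per-subject differences, e.g. pre- versus
#' post-fermentation Shannon diversity of the same slurries.
#'
#' @param pre,post numeric vectors of equal length n >= 2, paired by
#'   position.
#' @return list with elements `t`, `p.value`, `df`, `meanDifference`.  When
#'   `post` equals `pre` exactly the test is reported as `t = 0`, `p = 1`;
#'   a constant non-zero difference (zero variance) is an error.
#' @export
pairedT <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  n <- length(pre)
  if (n < 2L) stop("need at least 2 pairs")
  d <- post - pre
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p.value = 1, df = n - 1L, meanDifference = 0))
    stop("zero-variance non-zero differences: t statistic undefined")
  }
  tt <- t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), meanDifference = unname(tt$estimate))
}

#' Differential relative abundance between two sample groups
#'
#' Per-taxon two-sided Wilcoxon rank-sum tests on relative abundances
#' (computed per sample before testing), using the tie-corrected normal
#' approximation, followed by Benjamini-Hochberg step-up adjustment across
#' taxa.  Significance is called at adjusted p < `alpha`.  A taxon whose
#' relative abundance is constant across all samples in both groups carries
#' no evidence and is reported with p = 1.
#'
#' @param groupA,groupB taxa x samples count matrices with identical taxon
#'   rows and >= 2 samples each.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame with columns `taxon`, `statistic` (rank-sum W),
#'   `p.value`, `p.adjusted`, `significant`.
#' @export
differentialAbundance <- function(groupA, groupB, alpha = 0.05) {
  .checkCounts(groupA); .checkCounts(groupB)
  if (!identical(rownames(groupA), rownames(groupB)))
    stop("groups must share the same taxon rows in the same order")
  if (ncol(groupA) < 2L || ncol(groupB) < 2L)
    stop("need at least 2 samples per group")
  relA <- sweep(groupA, 2L, colSums(groupA), "/")
  relB <- sweep(groupB, 2L, colSums(groupB), "/")
  res <- t(vapply(seq_len(nrow(relA)), function(i) {
    xa <- relA[i, ]; xb <- relB[i, ]
    if (sd(c(xa, xb)) == 0)
      return(c(stat = NA_real_, p = 1))
    wt <- suppressWarnings(
      wilcox.test(xa, xb, exact = FALSE, correct = FALSE))
    c(stat = unname(wt$statistic), p = wt$p.value)
  }, numeric(2L)))
  padj <- p.adjust(res[, "p"], method = "BH")
  data.frame(taxon = rownames(groupA),
             statistic = res[, "stat"],
             p.value = res[, "p"],
             p.adjusted = padj,
             significant = padj < alpha,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
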