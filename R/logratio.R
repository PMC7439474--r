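#' @include AllClasses.R
NULL

# Normalise a positive vector/matrix to column-wise compositions.
.closure <- function(p) {
  if (is.null(dim(p))) p / sum(p) else sweep(p, 2L, colSums(p), "/")
}

#' Additive log-ratio transform
#'
#' Maps a strictly positive D-part composition to D-1 real coordinates
#' `alr_i = log(p_i / p_ref)` relative to a reference part.  Vectors are
#' treated as a single composition; matrices are taken parts x samples and
#' transformed column-wise.  Inputs are renormalised to sum to one, so
#' positive counts or concentrations may be passed directly.
#'
#' @param p strictly positive vector (length D) or D x N matrix.
#' @param ref index of the reference part (default: last).
#' @return numeric vector of length D-1, or (D-1) x N matrix, with the
#'   reference recorded in attribute `ref`.
#' @examples
#' alr(c(2, 3, 1))        # (log 2, log 3)
#' alrInv(alr(c(.2, .3, .5)))
#' @export
alr <- function(p, ref = NULL) {
  vec <- is.null(dim(p))
  m <- if (vec) matrix(p, ncol = 1L) else as.matrix(p)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("alr() requires strictly positive entries (no zeros)")
  D <- nrow(m)
  if (D < 2L) stop("need at least two parts")
  if (is.null(ref)) ref <- D
  ref <- as.integer(ref)
  if (ref < 1L || ref > D) stop("ref out of range")
  lm_ <- log(.closure(m))
  out <- lm_[-ref, , drop = FALSE] -
    matrix(lm_[ref, ], nrow = D - 1L, ncol = ncol(m), byrow = TRUE)
  if (vec) out <- drop(out)
  attr(out, "ref") <- ref
  out
}

#' Inverse additive log-ratio transform
#'
#' Maps ALR coordinates back to the simplex: a zero is inserted at the
#' reference position, coordinates are exponentiated and renormalised.
#'
#' @param coords numeric vector (length D-1) or (D-1) x N matrix of real
#'   coordinates.
#' @param ref reference part index in the reconstructed composition
#'   (default: attribute `ref` of `coords`, else last).
#' @return composition vector of length D, or D x N matrix, columns summing
#'   to one.
#' @export
alrInv <- function(coords, ref = NULL) {
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, ncol = 1L) else as.matrix(coords)
  if (any(!is.finite(m))) stop("coords must be finite")
  D <- nrow(m) + 1L
  if (is.null(ref)) ref <- attr(coords, "ref") %||% D
  ref <- as.integer(ref)
  if (ref < 1L || ref > D) stop("ref out of range")
  full <- matrix(0, D, ncol(m))
  full[-ref, ] <- m
  # stabilised softmax per column
  full <- sweep(full, 2L, apply(full, 2L, max), "-")
  out <- .closure(exp(full))
  if (vec) out <- drop(out)
  out
}

#' Centred log-ratio transform
#'
#' `clr_i = log p_i - mean_j log p_j`; reference-free coordinates summing to
#' zero across parts.
#'
#' @inheritParams alr
#' @return vector of length D or D x N matrix whose columns sum to zero.
#' @export
clr <- function(p) {
  vec <- is.null(dim(p))
  m <- if (vec) matrix(p, ncol = 1L) else as.matrix(p)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("clr() requires strictly positive entries (no zeros)")
  lm_ <- log(.closure(m))
  out <- sweep(lm_, 2L, colMeans(lm_), "-")
  if (vec) drop(out) else out
}

#' Map ALR-scale effects to the CLR scale
#'
#' Applies the linear contrast taking effects expressed in ALR coordinates
#' (reference part `ref`) to centred log-ratio coordinates: a zero row is
#' inserted at the reference position and the column mean of the augmented
#' matrix is subtracted from every row.  Used to report regression effects on
#' the reference-free CLR scale.
#'
#' @param Lambda (D-1) x Q matrix of ALR-scale effects (rows indexed by the
#'   non-reference parts in order).
#' @param ref reference part position in the D-part output (default: last).
#' @return D x Q matrix of CLR-scale effects; each column sums to zero.
#' @export
alrEffectsToClr <- function(Lambda, ref = NULL) {
  Lambda <- as.matrix(Lambda)
  D <- nrow(Lambda) + 1L
  if (is.null(ref)) ref <- D
  ref <- as.integer(ref)
  if (ref < 1L || ref > D) stop("ref out of range")
  full <- matrix(0, D, ncol(Lambda))
  full[-ref, ] <- Lambda
  sweep(full, 2L, colMeans(full), "-")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
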