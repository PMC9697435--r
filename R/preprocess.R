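#' Methylation score (beta value) from probe intensities
#'
#' For a locus with methylated-probe intensity M and unmethylated-probe
#' intensity U, the methylation score is M / (M + U): 0 when nothing is
#' methylated, 1 when everything is, 0.5 at equal intensities. The score
#' is scale-invariant (multiplying both intensities by c > 0 leaves it
#' unchanged). A locus with M + U = 0 carries no information and returns
#' NA (missing), not 0 and not an error.
#'
#' Vectorised: M and U may be equal-shaped vectors or matrices, in which
#' case a matrix/vector of betas is returned.
#'
#' @param M methylated signal intensity(ies), >= 0
#' @param U unmethylated signal intensity(ies), >= 0
#' @return beta value(s) in [0, 1], NA where M + U = 0
#' @examples
#' computeBeta(50, 50)   # 0.5
#' computeBeta(0, 120)   # 0
#' computeBeta(80, 0)    # 1
#' @export
computeBeta <- function(M, U) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  tot <- M + U
  out <- ifelse(!is.na(tot) & tot > 0, M / tot, NA_real_)
  if (is.matrix(M)) {
    out <- matrix(out, nrow = nrow(M), dimnames = dimnames(M))
  }
  out
}

#' Beta-value matrix from paired intensity matrices
#'
#' Applies [computeBeta()] elementwise to matched methylated/unmethylated
#' intensity matrices (same features, same samples).
#'
#' @param methylated,unmethylated \linkS4class{OmicsMatrix}-compatible
#'   numeric matrices (features x samples) of non-negative intensities
#' @param annotation optional feature annotation for the result
#' @return an \linkS4class{OmicsMatrix} of kind \code{methylation_beta}
#' @export
betaFromIntensities <- function(methylated, unmethylated, annotation = NULL) {
  if (!identical(dim(methylated), dim(unmethylated)) ||
      !identical(dimnames(methylated), dimnames(unmethylated)))
    stop("methylated and unmethylated matrices must share features and samples")
  OmicsMatrix(computeBeta(methylated, unmethylated),
              kind = "methylation_beta", annotation = annotation)
}

#' Quantile normalization of an expression matrix
#'
#' Forces every sample to the same empirical distribution: the reference
#' distribution is the across-sample mean of the sorted value vectors, and
#' each sample's values are replaced by the reference value at their rank.
#' Ties receive the mean of the reference values at the tied ranks.
#' Missing cells are excluded from rank computation (the sample's
#' non-missing values are mapped onto the reference grid by linear
#' interpolation of quantiles) and restored as missing. The operation is
#' idempotent and equalises column means on complete data.
#'
#' @param x an \linkS4class{OmicsMatrix} of kind \code{expression_log2}
#'   (or a bare numeric matrix)
#' @return object of the same type with normalized values
#' @export
quantileNormalize <- function(x) {
  is_om <- is(x, "OmicsMatrix")
  m <- if (is_om) omicsValues(x) else as.matrix(x)
  if (is_om && omicsKind(x) != "expression_log2")
    stop("quantile normalization is defined for expression_log2 matrices")
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 samples")
  nobs <- colSums(!is.na(m))
  if (any(nobs == 0))
    stop(sprintf("sample '%s' is all-missing", colnames(m)[nobs == 0][1]))

  n <- nrow(m)
  # reference quantile grid on n points; columns with missing values
  # contribute their sorted non-missing values interpolated onto the grid
  grid <- if (n == 1) 0.5 else seq(0, 1, length.out = n)
  ref_cols <- vapply(seq_len(ncol(m)), function(j) {
    v <- sort(m[, j], na.last = NA)
    if (length(v) == n) v
    else stats::approx(seq(0, 1, length.out = length(v)), v, xout = grid,
                       rule = 2)$y
  }, numeric(n))
  ref <- rowMeans(ref_cols)

  out <- m
  for (j in seq_len(ncol(m))) {
    ok <- !is.na(m[, j])
    v <- m[ok, j]
    k <- length(v)
    # target values for this sample: reference grid interpolated to k points
    tgt <- if (k == n) ref
           else stats::approx(grid, ref, xout = seq(0, 1, length.out = k),
                              rule = 2)$y
    r <- rank(v, ties.method = "average")
    # fractional average ranks (ties) -> interpolate between target values
    out[ok, j] <- stats::approx(seq_len(k), tgt, xout = r, rule = 2)$y
  }
  if (is_om) {
    y <- x
    SummarizedExperiment::assay(y, "values") <- out
    y
  } else out
}
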