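#' Z-score the columns of a matrix
#'
#' Centres each column to mean 0 and scales it to unit variance using
#' the sample (n - 1) variance convention, so that cross products of
#' z-scored columns divided by n - 1 are exact Pearson correlations.
#'
#' @param M numeric matrix with at least 2 rows.
#' @return Matrix of the same shape with standardized columns.
#' @examples
#' zscoreColumns(cbind(a = c(1, 3), b = c(2, 8)))
#' @export
zscoreColumns <- function(M) {
  M <- .asNumericMatrix(M, "M")
  if (nrow(M) < 2L)
    stop("z-scoring needs at least 2 rows", call. = FALSE)
  bad <- .constantColumns(M)
  if (length(bad))
    stop("zero-variance column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  mu <- colMeans(M)
  Mc <- sweep(M, 2L, mu, "-")
  sdv <- sqrt(colSums(Mc^2) / (nrow(M) - 1L))
  sweep(Mc, 2L, sdv, "/")
}

#' Cross-correlation matrix between two blocks
#'
#' Computes \eqn{C = X_z^\top Y_z / (n - 1)} with both blocks z-scored
#' internally, so entry (i, j) is the Pearson correlation between X
#' column i and Y column j.
#'
#' @param data a [TwoBlockDataset-class].
#' @return p x q matrix of Pearson correlations.
#' @export
crossCorrelation <- function(data) {
  stopifnot(is(data, "TwoBlockDataset"))
  Xz <- zscoreColumns(xBlock(data))
  Yz <- zscoreColumns(yBlock(data))
  crossprod(Xz, Yz) / (nrow(Xz) - 1L)
}

#' PLS correlation decomposition
#'
#' Performs the singular value decomposition of the cross-correlation
#' matrix between the two z-scored blocks, \eqn{C = U \Sigma V^\top}.
#' Matched columns of U and V together with their singular value form a
#' latent variable (LV); LVs are ranked by singular value and their
#' number is always \code{k = min(p, q)} (trailing near-zero singular
#' values are retained so null-distribution bookkeeping has a fixed LV
#' count). Covariance explained is the squared singular values over
#' their sum.
#'
#' Sign convention: SVD signs are arbitrary, so each LV's sign is fixed
#' so that the element of its V column with largest absolute value is
#' positive; this makes results reproducible across platforms.
#'
#' @param data a [TwoBlockDataset-class].
#' @return A [PLSDecomposition-class] with k = min(p, q) LVs.
#' @examples
#' set.seed(1)
#' d <- TwoBlockDataset(matrix(rnorm(300), 30), matrix(rnorm(90), 30))
#' dec <- plsDecompose(d)
#' singularValues(dec)
#' covarianceExplained(dec)
#' @export
plsDecompose <- function(data) {
  C <- crossCorrelation(data)
  dec <- .plsFromC(C)
  rownames(dec@U) <- colnames(xBlock(data))
  rownames(dec@V) <- colnames(yBlock(data))
  dec
}

# SVD of a cross-correlation matrix with the package sign convention
.plsFromC <- function(C) {
  k <- min(dim(C))
  s <- La.svd(C, nu = k, nv = k)
  U <- s$u
  V <- t(s$vt)
  for (j in seq_len(k)) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  d <- s$d[seq_len(k)]
  tot <- sum(d^2)
  ce <- if (tot > 0) d^2 / tot else rep(NA_real_, k)
  new("PLSDecomposition", U = U, V = V, d = d, covExplained = ce)
}

# fast path used inside permutation / resampling loops: no sign fixing,
# no names (null values and Procrustes rotations are sign-invariant)
.svdCross <- function(Xz, Yz, k) {
  C <- crossprod(Xz, Yz) / (nrow(Xz) - 1L)
  s <- La.svd(C, nu = k, nv = k)
  list(u = s$u, v = t(s$vt), d = s$d[seq_len(k)])
}

#' @rdname accessors
setMethod("leftVectors", "PLSDecomposition", function(object) object@U)
#' @rdname accessors
setMethod("rightVectors", "PLSDecomposition", function(object) object@V)
#' @rdname accessors
setMethod("singularValues", "PLSDecomposition", function(object) object@d)
#' @rdname accessors
setMethod("covarianceExplained", "PLSDecomposition",
          function(object) object@covExplained)
#' @rdname accessors
setMethod("numLV", "PLSDecomposition", function(object) length(object@d))

setMethod("show", "PLSDecomposition", function(object) {
  k <- length(object@d)
  cat("PLSDecomposition:", k, "latent variable(s)\n")
  show <- min(k, 5L)
  cat("  singular values: ",
      paste(signif(object@d[seq_len(show)], 4), collapse = ", "),
      if (k > show) ", ..." else "", "\n", sep = "")
  cat("  covariance explained: ",
      paste(signif(object@covExplained[seq_len(show)], 3), collapse = ", "),
      if (k > show) ", ..." else "", "\n", sep = "")
})

#' Write a decomposition to CSV files
#'
#' Writes \code{U.csv}, \code{V.csv} and \code{lv.csv} (singular values
#' and covariance explained per LV) into a directory.
#'
#' @param decomp a [PLSDecomposition-class].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeDecomposition <- function(decomp, dir) {
  stopifnot(is(decomp, "PLSDecomposition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(leftVectors(decomp), file.path(dir, "U.csv"))
  utils::write.csv(rightVectors(decomp), file.path(dir, "V.csv"))
  utils::write.csv(data.frame(lv = seq_len(numLV(decomp)),
                              singular_value = singularValues(decomp),
                              covariance_explained = covarianceExplained(decomp)),
                   file.path(dir, "lv.csv"), row.names = FALSE)
  invisible(dir)
}
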