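#' Solve the orthogonal Procrustes problem
#'
#' Finds the k x k orthogonal matrix R (rotation and/or reflection)
#' minimising \eqn{\|W_{perm} R - W_{ref}\|_F} over orthogonal
#' matrices, for two matrices with orthonormal columns of equal shape.
#' The closed-form solution comes from the SVD of
#' \eqn{W_{perm}^\top W_{ref} = N O P^\top}: \eqn{R = N P^\top}.
#'
#' @param Wperm,Wref numeric matrices of equal shape with orthonormal
#'   columns (e.g. permuted and reference singular vectors).
#' @return k x k orthogonal matrix R.
#' @examples
#' V <- qr.Q(qr(matrix(rnorm(8), 4)))
#' solveProcrustes(V, V)            # identity
#' solveProcrustes(V[, 2:1], V)     # column swap
#' @export
solveProcrustes <- function(Wperm, Wref) {
  if (!is.matrix(Wperm) || !is.matrix(Wref) ||
      !identical(dim(Wperm), dim(Wref)))
    stop("Wperm and Wref must be matrices of identical shape",
         call. = FALSE)
  .procrustesR(crossprod(Wperm, Wref))
}

.procrustesR <- function(M) {
  s <- La.svd(M)
  s$u %*% s$vt
}

#' Rotated null values for one permuted decomposition
#'
#' Computes the Procrustes-rotated surrogate singular values used by the
#' rotated permutation tests. The rotation R aligning the selected
#' permuted component to its reference is computed, each row i of R is
#' scaled by the i-th permuted singular value, and the L2 norm of each
#' column of the scaled transform is returned: with orthonormal permuted
#' columns this equals the column norms of
#' \eqn{\tilde V^{(p)} = V^{(p)} \Sigma^{(p)} R}. The rotation can
#' reorder the permuted LVs and redistribute covariance across them but
#' conserves the total: \eqn{\sum_i val_i^2 = \sum_i \sigma^{(p)2}_i},
#' and no value can exceed the largest permuted singular value.
#'
#' @param permDecomp [PLSDecomposition-class] of a permuted dataset.
#' @param ref reference [PLSDecomposition-class] (original data).
#' @param component \code{"v"} to align the behaviour-side vectors
#'   (V(p) to V) or \code{"u"} for the brain side.
#' @return Length-k vector of null values, one per LV.
#' @export
rotatedNullValues <- function(permDecomp, ref, component = c("v", "u")) {
  component <- match.arg(component)
  stopifnot(is(permDecomp, "PLSDecomposition"), is(ref, "PLSDecomposition"))
  if (numLV(permDecomp) != numLV(ref))
    stop("permuted and reference decompositions disagree on the number of LVs",
         call. = FALSE)
  Wp <- if (component == "v") rightVectors(permDecomp) else leftVectors(permDecomp)
  Wr <- if (component == "v") rightVectors(ref) else leftVectors(ref)
  .rotatedValues(singularValues(permDecomp), crossprod(Wp, Wr))
}

# column norms of diag(d) %*% R with R from the Procrustes SVD of M
.rotatedValues <- function(d, M) {
  R <- .procrustesR(M)
  sqrt(colSums((d * R)^2))
}
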