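#' Build a permutation-test configuration
#'
#' @param method rotation method: \code{"none"} (permuted singular
#'   values scored directly), \code{"behaviour"} (Procrustes rotation of
#'   the permuted behaviour-side vectors), \code{"brain"} (rotation of
#'   the brain-side vectors), or \code{"both"} (the two rotated value
#'   sets averaged elementwise).
#' @param nPerm number of permutation instances (study default 10000).
#' @param seed integer seed for the shuffle indices.
#' @param shuffleIndices optional precomputed nPerm x n table; each row
#'   a permutation of 1..n. When supplied, \code{seed} is ignored for
#'   index generation (tests sharing a table consume identical
#'   permutation instances).
#' @param addOne use the (count + 1)/(nPerm + 1) p-value estimator;
#'   default \code{FALSE}, the literal proportion.
#' @return A [PermutationConfig-class].
#' @export
permutationConfig <- function(method = c("none", "behaviour", "brain", "both"),
                              nPerm = 10000L, seed = 1L,
                              shuffleIndices = NULL, addOne = FALSE) {
  method <- match.arg(method)
  new("PermutationConfig", method = method, nPerm = as.integer(nPerm),
      seed = as.integer(seed), shuffleIndices = shuffleIndices,
      addOne = isTRUE(addOne))
}

#' Draw a table of shared shuffle indices
#'
#' Generates the nPerm x n table of row permutations consumed by the
#' permutation tests. Generating the table once and passing it to every
#' method (or simply reusing one seed) guarantees that all methods see
#' identical permutation instances, so p-value differences between
#' methods are attributable to the rotation alone. Degenerate draws
#' (e.g. the identity permutation) are kept: rejecting them would bias
#' the null.
#'
#' @param n number of observations.
#' @param nPerm number of permutation instances.
#' @param seed integer seed.
#' @return nPerm x n integer matrix; each row a permutation of 1..n.
#' @export
makeShuffleIndices <- function(n, nPerm, seed) {
  withr::with_seed(as.integer(seed), {
    idx <- matrix(0L, nrow = nPerm, ncol = n)
    for (i in seq_len(nPerm)) idx[i, ] <- sample.int(n)
    idx
  })
}

.checkPermutation <- function(perm, n) {
  perm <- as.integer(perm)
  if (length(perm) != n || anyNA(perm) ||
      !identical(sort(perm), seq_len(n)))
    stop("perm must be a permutation of 1..", n, call. = FALSE)
  perm
}

#' Decomposition of a row-shuffled dataset
#'
#' Re-runs the PLS decomposition with the rows of one block shuffled by
#' a given permutation while the other block stays intact (the
#' elementary step of the permutation tests). Z-scoring is unaffected
#' by row shuffling, so the permuted cross-correlation is the
#' cross-correlation between the intact z-scored block and the
#' row-shuffled z-scored block.
#'
#' @param data a [TwoBlockDataset-class].
#' @param perm integer vector, a permutation of 1..n.
#' @param side which block's rows to shuffle: \code{"y"} (used by the
#'   none/behaviour/both tests) or \code{"x"} (brain test).
#' @return A [PLSDecomposition-class] of the permuted pair.
#' @export
permutedDecomposition <- function(data, perm, side = c("y", "x")) {
  side <- match.arg(side)
  stopifnot(is(data, "TwoBlockDataset"))
  perm <- .checkPermutation(perm, nObs(data))
  X <- xBlock(data)
  Y <- yBlock(data)
  if (side == "y") Y <- Y[perm, , drop = FALSE]
  else X <- X[perm, , drop = FALSE]
  plsDecompose(TwoBlockDataset(X, Y))
}

# permutation engine: scores the requested methods on shared instances.
# One permuted decomposition per instance serves all four methods: the
# brain test is defined as shuffling X's rows by the inverse of the
# shared index row, which pairs rows identically to shuffling Y by the
# row itself, so the same permuted cross-correlation is scored by every
# method and differences are due to the rotation alone.
.permutationEngine <- function(data, idx, methods) {
  Xz <- zscoreColumns(xBlock(data))
  Yz <- zscoreColumns(yBlock(data))
  ref <- plsDecompose(data)
  k <- numLV(ref)
  U <- leftVectors(ref)
  V <- rightVectors(ref)
  nPerm <- nrow(idx)
  out <- lapply(methods, function(m) matrix(NA_real_, nPerm, k))
  names(out) <- methods
  needV <- any(methods %in% c("behaviour", "both"))
  needU <- any(methods %in% c("brain", "both"))
  for (i in seq_len(nPerm)) {
    s <- .svdCross(Xz, Yz[idx[i, ], , drop = FALSE], k)
    if (any(!is.finite(s$d)))
      stop("non-finite singular values at permutation ", i, call. = FALSE)
    vv <- if (needV) .rotatedValues(s$d, crossprod(s$v, V)) else NULL
    vu <- if (needU) .rotatedValues(s$d, crossprod(s$u, U)) else NULL
    for (m in methods) {
      out[[m]][i, ] <- switch(m,
        none = s$d,
        behaviour = vv,
        brain = vu,
        both = (vv + vu) / 2)
    }
  }
  list(ref = ref, values = out)
}

# p-values with a numerical floor: singular values below 1e-12 are
# treated as 0 so floating-point noise cannot create spurious
# exceedances; ties count as exceedances (conservative)
.permPValues <- function(values, observed, addOne) {
  floor <- 1e-12
  obs <- observed
  obs[obs < floor] <- 0
  vals <- values
  vals[vals < floor] <- 0
  counts <- vapply(seq_along(obs),
                   function(j) sum(vals[, j] >= obs[j]), numeric(1))
  if (addOne) (counts + 1) / (nrow(values) + 1) else counts / nrow(values)
}

.newNullDistributions <- function(values, ref, method, seed, addOne) {
  new("NullDistributions", values = values,
      pValues = .permPValues(values, singularValues(ref), addOne),
      observed = singularValues(ref), method = method,
      seed = as.integer(seed), addOne = addOne)
}

#' Run one PLS permutation test
#'
#' Builds per-LV null distributions by re-running the decomposition on
#' row-shuffled data \code{nPerm} times, optionally Procrustes-rotating
#' the permuted singular vectors toward the originals before scoring
#' (see [permutationConfig()] for the four methods), and returns
#' p-values: for LV i, the proportion of null values greater than or
#' equal to the observed singular value.
#'
#' All methods run with the same seed (or a shared
#' \code{shuffleIndices} table) consume identical permutation
#' instances. For the rotated methods the scored null value of the
#' first LV can never exceed the unrotated one on the same instance, so
#' with shared instances the rotated LV1 p-value is always less than or
#' equal to the unrotated LV1 p-value.
#'
#' @param data a [TwoBlockDataset-class].
#' @param config a [PermutationConfig-class]; alternatively leave it
#'   \code{NULL} and pass \code{method}, \code{nPerm}, \code{seed},
#'   \code{addOne} directly.
#' @param method,nPerm,seed,addOne see [permutationConfig()]; ignored
#'   when \code{config} is given.
#' @return A [NullDistributions-class].
#' @examples
#' set.seed(7)
#' d <- TwoBlockDataset(matrix(rnorm(200), 20), matrix(rnorm(60), 20))
#' nd <- runPermutationTest(d, method = "behaviour", nPerm = 200, seed = 3)
#' pValues(nd)
#' @export
runPermutationTest <- function(data, config = NULL,
                               method = c("none", "behaviour", "brain", "both"),
                               nPerm = 10000L, seed = 1L, addOne = FALSE) {
  if (is.null(config)) {
    method <- match.arg(method)
    config <- permutationConfig(method, nPerm, seed, addOne = addOne)
  }
  stopifnot(is(data, "TwoBlockDataset"), is(config, "PermutationConfig"))
  idx <- config@shuffleIndices
  if (is.null(idx))
    idx <- makeShuffleIndices(nObs(data), config@nPerm, config@seed)
  else if (ncol(idx) != nObs(data))
    stop("shuffleIndices were drawn for ", ncol(idx),
         " observations but the dataset has ", nObs(data), call. = FALSE)
  eng <- .permutationEngine(data, idx, config@method)
  .newNullDistributions(eng$values[[config@method]], eng$ref, config@method,
                        config@seed, config@addOne)
}

#' Run all four permutation tests on shared permutation instances
#'
#' Runs the unrotated test and the three rotated variants on identical
#' shuffle indices (one permuted decomposition per instance serves all
#' four), so any differences between the resulting null distributions
#' and p-values are driven by the rotations themselves.
#'
#' @inheritParams runPermutationTest
#' @return Named list of four [NullDistributions-class] objects
#'   (\code{none}, \code{behaviour}, \code{brain}, \code{both}).
#' @export
runAllPermutationTests <- function(data, nPerm = 10000L, seed = 1L,
                                   addOne = FALSE) {
  stopifnot(is(data, "TwoBlockDataset"))
  idx <- makeShuffleIndices(nObs(data), as.integer(nPerm), seed)
  methods <- c("none", "behaviour", "brain", "both")
  eng <- .permutationEngine(data, idx, methods)
  out <- lapply(methods, function(m)
    .newNullDistributions(eng$values[[m]], eng$ref, m, seed, isTRUE(addOne)))
  names(out) <- methods
  out
}

#' @rdname accessors
setMethod("nullValues", "NullDistributions", function(object) object@values)
#' @rdname accessors
setMethod("pValues", "NullDistributions", function(object) object@pValues)
#' @rdname accessors
setMethod("observedValues", "NullDistributions",
          function(object) object@observed)
#' @rdname accessors
setMethod("rotationMethod", "NullDistributions",
          function(object) object@method)

setMethod("show", "NullDistributions", function(object) {
  k <- length(object@pValues)
  cat("NullDistributions (method = ", object@method, "): ",
      nrow(object@values), " permutations, ", k, " LV(s)\n", sep = "")
  show <- min(k, 5L)
  cat("  observed: ",
      paste(signif(object@observed[seq_len(show)], 4), collapse = ", "),
      if (k > show) ", ..." else "", "\n", sep = "")
  cat("  p-values: ",
      paste(signif(object@pValues[seq_len(show)], 3), collapse = ", "),
      if (k > show) ", ..." else "", "\n", sep = "")
})
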