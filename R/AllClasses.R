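#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Paired two-block dataset
#'
#' Container for two numeric matrices measured on the same observations:
#' a "brain" block \code{X} (n observations by p features) and a
#' "behaviour" block \code{Y} (n by q). The block labels follow the
#' convention that the larger block is called brain and the smaller
#' behaviour; nothing in the methods depends on the labels. Columns carry
#' feature names; rows are observations in matched order across blocks.
#'
#' Validity requires at least 3 matched rows and no constant (zero
#' variance) column in either block, since all downstream computation
#' z-scores the columns.
#'
#' @slot X numeric matrix, n x p.
#' @slot Y numeric matrix, n x q.
#'
#' @seealso [TwoBlockDataset()] for the user constructor,
#'   [plsDecompose()] for the decomposition.
#' @exportClass TwoBlockDataset
setClass("TwoBlockDataset",
  representation(X = "matrix", Y = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@X) || !is.numeric(object@Y))
      msg <- c(msg, "X and Y must be numeric matrices")
    if (nrow(object@X) != nrow(object@Y))
      msg <- c(msg, sprintf("X has %d rows but Y has %d; blocks must share observations",
                            nrow(object@X), nrow(object@Y)))
    if (nrow(object@X) < 3L)
      msg <- c(msg, "at least 3 observations are required")
    if (length(msg)) return(msg)
    badx <- .constantColumns(object@X)
    if (length(badx))
      msg <- c(msg, paste0("zero-variance column(s) in X: ",
                           paste(badx, collapse = ", ")))
    bady <- .constantColumns(object@Y)
    if (length(bady))
      msg <- c(msg, paste0("zero-variance column(s) in Y: ",
                           paste(bady, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' PLS correlation decomposition
#'
#' Result of the singular value decomposition of the cross-correlation
#' matrix between two z-scored blocks. Each latent variable (LV) is a
#' matched pair of columns of \code{U} (brain feature weights) and
#' \code{V} (behaviour feature weights) together with its singular value.
#' LVs are ranked by singular value; the number of LVs is
#' \code{min(p, q)}. \code{covExplained} holds the squared singular
#' values normalised by their sum, i.e. the fraction of cross-block
#' covariance each LV captures.
#'
#' @slot U p x k matrix of left singular vectors (orthonormal columns).
#' @slot V q x k matrix of right singular vectors (orthonormal columns).
#' @slot d length-k nonincreasing vector of singular values.
#' @slot covExplained length-k vector of covariance-explained fractions.
#'
#' @seealso [plsDecompose()]
#' @exportClass PLSDecomposition
setClass("PLSDecomposition",
  representation(U = "matrix", V = "matrix", d = "numeric",
                 covExplained = "numeric"),
  validity = function(object) {
    k <- length(object@d)
    msg <- character()
    if (ncol(object@U) != k || ncol(object@V) != k)
      msg <- c(msg, "U, V and d disagree on the number of latent variables")
    if (k > 1 && any(diff(object@d) > 1e-8))
      msg <- c(msg, "singular values must be nonincreasing")
    if (any(object@d < -1e-12))
      msg <- c(msg, "singular values must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' Permutation test configuration
#'
#' Settings for a PLS permutation test: the rotation method, the number
#' of permutations, the seed, and (optionally) a precomputed table of
#' shuffle indices with one row per permutation instance. When several
#' methods are run with the same seed (or the same table) they consume
#' identical permutation instances, so differences between their null
#' distributions are attributable to the rotation alone.
#'
#' @slot method one of "none", "behaviour", "brain", "both".
#' @slot nPerm number of permutation instances.
#' @slot seed integer seed used to draw the shuffle indices.
#' @slot shuffleIndices optional nPerm x n integer matrix; each row a
#'   permutation of 1..n.
#' @slot addOne logical; use the (count + 1)/(nPerm + 1) p-value
#'   estimator instead of the literal proportion.
#'
#' @seealso [permutationConfig()], [runPermutationTest()]
#' @exportClass PermutationConfig
setClass("PermutationConfig",
  representation(method = "character", nPerm = "integer", seed = "integer",
                 shuffleIndices = "matrixOrNULL", addOne = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@method %in% c("none", "behaviour", "brain", "both"))
      msg <- c(msg, "method must be one of none, behaviour, brain, both")
    if (object@nPerm < 1L)
      msg <- c(msg, "nPerm must be a positive integer")
    if (!is.null(object@shuffleIndices)) {
      idx <- object@shuffleIndices
      if (nrow(idx) != object@nPerm)
        msg <- c(msg, "shuffleIndices must have nPerm rows")
      n <- ncol(idx)
      ok <- apply(idx, 1L, function(r) identical(sort(as.integer(r)), seq_len(n)))
      if (!all(ok))
        msg <- c(msg, "each row of shuffleIndices must be a permutation of 1..n")
    }
    if (length(msg)) msg else TRUE
  })

#' Permutation null distributions for one rotation method
#'
#' Per-LV null distributions of permuted singular values (or their
#' Procrustes-rotated surrogates) plus the resulting p-values. The
#' p-value for LV i is the proportion of null values greater than or
#' equal to the observed singular value (optionally with the add-one
#' correction).
#'
#' @slot values nPerm x k matrix; column i is the null for LV i.
#' @slot pValues length-k vector in [0, 1].
#' @slot observed length-k vector of observed singular values.
#' @slot method rotation method tag.
#' @slot seed seed used to draw the shuffle indices (NA if a table was
#'   supplied directly).
#' @slot addOne whether the add-one estimator was used.
#'
#' @exportClass NullDistributions
setClass("NullDistributions",
  representation(values = "matrix", pValues = "numeric", observed = "numeric",
                 method = "character", seed = "integer", addOne = "logical"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@values) != length(object@pValues))
      msg <- c(msg, "values and pValues disagree on the number of LVs")
    if (length(object@pValues) != length(object@observed))
      msg <- c(msg, "pValues and observed must have equal length")
    if (any(object@pValues < 0 | object@pValues > 1))
      msg <- c(msg, "p-values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Population joint correlation model with one latent effect
#'
#' A population correlation matrix for (X, Y) jointly, split into the
#' within-block correlations \code{Cxx}, \code{Cyy} and the cross-block
#' matrix \code{Cxy}. The cross-block structure encodes exactly one
#' latent effect whose first canonical correlation equals \code{r};
#' remaining canonical pairs are unconstrained.
#'
#' @slot Cxx p x p within-X correlation matrix.
#' @slot Cyy q x q within-Y correlation matrix.
#' @slot Cxy p x q cross-correlation matrix.
#' @slot r first-pair canonical correlation of the population model.
#' @slot m number of encoded latent effects (always 1).
#'
#' @seealso [buildJointCorrelation()], [sampleDataset()],
#'   [populationCanonicalCorrelations()]
#' @exportClass JointCorrelationModel
setClass("JointCorrelationModel",
  representation(Cxx = "matrix", Cyy = "matrix", Cxy = "matrix",
                 r = "numeric", m = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@Cxy) != nrow(object@Cxx) ||
        ncol(object@Cxy) != nrow(object@Cyy))
      msg <- c(msg, "Cxy dimensions must match Cxx and Cyy")
    if (max(abs(diag(object@Cxx) - 1)) > 1e-8 ||
        max(abs(diag(object@Cyy) - 1)) > 1e-8)
      msg <- c(msg, "within-block matrices must have unit diagonal")
    if (object@r <= 0 || object@r >= 1)
      msg <- c(msg, "r must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Split-half stability result
#'
#' Absolute Pearson correlations between latent-variable weight vectors
#' estimated independently on two random halves of the sample, per LV
#' and per block, over repeated random splits.
#'
#' @slot perSplitX nSplits x k matrix of |r| between half-sample left
#'   singular vectors.
#' @slot perSplitY nSplits x k matrix for the right singular vectors.
#' @slot seed seed that drew the splits.
#'
#' @seealso [splitHalfStability()]
#' @exportClass StabilityResult
setClass("StabilityResult",
  representation(perSplitX = "matrix", perSplitY = "matrix", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@perSplitX), dim(object@perSplitY)))
      msg <- c(msg, "perSplitX and perSplitY must have identical dimensions")
    rng <- range(object@perSplitX, object@perSplitY)
    if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
      msg <- c(msg, "stability values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Bootstrap feature-weight reliability result
#'
#' Bootstrap ratios for the brain features (mean aligned weight divided
#' by its standard deviation across resamples, a z-score analogue) and
#' behavioural loadings (correlations between each Y variable and the Y
#' latent scores) with percentile 95% confidence intervals across
#' resamples. Resampled decompositions are Procrustes-aligned to the
#' original via the brain component before accumulation.
#'
#' @slot bootstrapRatiosX p x k matrix of bootstrap ratios.
#' @slot sdFlooredX p x k logical matrix flagging cells whose
#'   across-resample SD fell below the numerical floor (the ratio there
#'   is capped).
#' @slot loadingsY q x k matrix of behavioural loadings on the original
#'   sample.
#' @slot loadingCILow,loadingCIHigh q x k percentile 2.5% / 97.5% bounds.
#' @slot nBoot number of bootstrap resamples.
#' @slot nRedrawn number of resamples redrawn because a column was
#'   constant.
#' @slot seed resampling seed.
#'
#' @seealso [bootstrapReliability()]
#' @exportClass BootstrapResult
setClass("BootstrapResult",
  representation(bootstrapRatiosX = "matrix", sdFlooredX = "matrix",
                 loadingsY = "matrix", loadingCILow = "matrix",
                 loadingCIHigh = "matrix", nBoot = "integer",
                 nRedrawn = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    rng <- range(object@loadingsY, object@loadingCILow, object@loadingCIHigh)
    if (rng[1] < -1 - 1e-8 || rng[2] > 1 + 1e-8)
      msg <- c(msg, "loadings and their CI bounds must lie in [-1, 1]")
    if (any(object@loadingCILow > object@loadingCIHigh + 1e-12))
      msg <- c(msg, "CI lower bounds must not exceed upper bounds")
    if (length(msg)) msg else TRUE
  })

# columns with (numerically) zero sample variance; returns printable labels
.constantColumns <- function(M) {
  if (ncol(M) == 0L) return(character())
  v <- apply(M, 2L, stats::var)
  bad <- which(!is.finite(v) | v < .Machine$double.eps)
  if (!length(bad)) return(character())
  nm <- colnames(M)
  if (is.null(nm)) as.character(bad) else nm[bad]
}
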