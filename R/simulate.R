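#' Generate an iid-normal null dataset
#'
#' Draws every entry of X (n x p) and Y (n x q) independently from the
#' standard normal distribution: the null regime with no cross-block
#' structure (the population joint correlation is the identity, so the
#' first canonical correlation is 0).
#'
#' @param n number of observations (>= 3).
#' @param p,q feature counts (study defaults 90 and 10).
#' @param seed integer seed.
#' @return A [TwoBlockDataset-class].
#' @export
generateNullDataset <- function(n, p = 90L, q = 10L, seed = 1L) {
  stopifnot(n >= 3L, p >= 1L, q >= 1L)
  withr::with_seed(as.integer(seed), {
    X <- matrix(stats::rnorm(n * p), n, p)
    Y <- matrix(stats::rnorm(n * q), n, q)
  })
  TwoBlockDataset(X, Y)
}

# symmetric matrix square root (and inverse root) via eigendecomposition
.symSqrt <- function(S, inverse = FALSE) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  half <- if (inverse) 1 / sqrt(vals) else sqrt(vals)
  e$vectors %*% (half * t(e$vectors))
}

#' Build a joint correlation model with one latent effect
#'
#' Constructs a population correlation model (Cxx, Cyy, Cxy) whose
#' cross-block structure encodes exactly one latent effect with first
#' canonical correlation equal to \code{r}. A random unit-vector pair
#' (a, b) is drawn in the whitened spaces and the cross block is set to
#' \eqn{C_{XY} = C_{XX}^{1/2}\, a\, r\, b^\top C_{YY}^{1/2}}, which
#' makes the first population canonical correlation exactly \code{r}
#' and leaves further canonical pairs unconstrained. By default the
#' within-block matrices are identities, which keeps the embedded
#' canonical correlation analytically exact; \code{within = "decay"}
#' gives within-block correlation with power-law eigenvalue decay
#' (random eigenvectors, eigenvalues proportional to
#' \code{i^-decayExponent}, rescaled to unit diagonal).
#'
#' The assembled joint matrix is checked for positive definiteness; a
#' failing draw is rebuilt with fresh vectors up to 10 times before
#' erroring (with identities the whitened cross block has spectral norm
#' r < 1, so the check cannot fail there).
#'
#' @param p,q feature counts.
#' @param r target first canonical correlation, in (0, 1).
#' @param seed integer seed for the random singular vectors.
#' @param within within-block structure, \code{"identity"} (default) or
#'   \code{"decay"}.
#' @param decayExponent eigenvalue decay exponent for
#'   \code{within = "decay"}.
#' @return A [JointCorrelationModel-class].
#' @examples
#' m <- buildJointCorrelation(6, 3, r = 0.5, seed = 1)
#' populationCanonicalCorrelations(m)
#' @export
buildJointCorrelation <- function(p, q, r, seed = 1L,
                                  within = c("identity", "decay"),
                                  decayExponent = 1) {
  within <- match.arg(within)
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    Cxx <- .withinCorrelation(p, within, decayExponent)
    Cyy <- .withinCorrelation(q, within, decayExponent)
    SxxH <- .symSqrt(Cxx)
    SyyH <- .symSqrt(Cyy)
    for (try in seq_len(10L)) {
      a <- stats::rnorm(p); a <- a / sqrt(sum(a^2))
      b <- stats::rnorm(q); b <- b / sqrt(sum(b^2))
      Cxy <- SxxH %*% (a %o% b * r) %*% SyyH
      joint <- rbind(cbind(Cxx, Cxy), cbind(t(Cxy), Cyy))
      if (min(eigen(joint, symmetric = TRUE, only.values = TRUE)$values) > 1e-10)
        return(new("JointCorrelationModel", Cxx = Cxx, Cyy = Cyy, Cxy = Cxy,
                   r = r, m = 1L))
    }
  })
  stop("could not build a positive-definite joint correlation matrix",
       call. = FALSE)
}

.withinCorrelation <- function(d, within, decayExponent) {
  if (within == "identity" || d == 1L) return(diag(d))
  lam <- seq_len(d)^(-decayExponent)
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  S <- Q %*% (lam * t(Q))
  stats::cov2cor(S)
}

#' @rdname accessors
setMethod("canonicalCorrelation", "JointCorrelationModel",
          function(object) object@r)
#' @rdname accessors
setMethod("jointMatrix", "JointCorrelationModel", function(object)
  rbind(cbind(object@Cxx, object@Cxy),
        cbind(t(object@Cxy), object@Cyy)))

setMethod("show", "JointCorrelationModel", function(object) {
  cat("JointCorrelationModel: p =", nrow(object@Cxx),
      ", q =", nrow(object@Cyy), "\n")
  cat("  latent effects:", object@m,
      " first canonical correlation:", object@r, "\n")
})

#' Population canonical correlations of a joint model
#'
#' Singular values of the whitened cross block
#' \eqn{C_{XX}^{-1/2} C_{XY} C_{YY}^{-1/2}}: the population canonical
#' correlations of the model. For a model built by
#' [buildJointCorrelation()] the largest equals the requested \code{r}
#' up to numerical tolerance.
#'
#' @param model a [JointCorrelationModel-class].
#' @return Nonincreasing vector of min(p, q) canonical correlations.
#' @export
populationCanonicalCorrelations <- function(model) {
  stopifnot(is(model, "JointCorrelationModel"))
  K <- .symSqrt(model@Cxx, inverse = TRUE) %*% model@Cxy %*%
    .symSqrt(model@Cyy, inverse = TRUE)
  svd(K, nu = 0, nv = 0)$d
}

#' Sample a dataset from a joint correlation model
#'
#' Draws n observations from the multivariate normal distribution with
#' mean 0 and the model's assembled joint correlation matrix; the first
#' p columns become X and the remaining q become Y.
#'
#' @param model a [JointCorrelationModel-class].
#' @param n number of observations (>= 3).
#' @param seed integer seed.
#' @return A [TwoBlockDataset-class].
#' @export
sampleDataset <- function(model, n, seed = 1L) {
  stopifnot(is(model, "JointCorrelationModel"), n >= 3L)
  joint <- jointMatrix(model)
  p <- nrow(model@Cxx)
  q <- nrow(model@Cyy)
  Z <- withr::with_seed(as.integer(seed),
    MASS::mvrnorm(n, mu = rep(0, p + q), Sigma = joint))
  TwoBlockDataset(Z[, seq_len(p), drop = FALSE],
                  Z[, p + seq_len(q), drop = FALSE])
}

#' Add Gaussian noise to both blocks
#'
#' Adds iid normal(0, noiseSd^2) noise matrices of matching size to X
#' and Y (after simulation, before any z-scoring, which happens inside
#' the PLS itself). \code{noiseSd = 0} returns the input unchanged.
#'
#' @param data a [TwoBlockDataset-class].
#' @param noiseSd noise standard deviation, >= 0.
#' @param seed integer seed.
#' @return A [TwoBlockDataset-class].
#' @export
addNoise <- function(data, noiseSd, seed = 1L) {
  stopifnot(is(data, "TwoBlockDataset"), noiseSd >= 0)
  if (noiseSd == 0) return(data)
  X <- xBlock(data)
  Y <- yBlock(data)
  withr::with_seed(as.integer(seed), {
    X <- X + matrix(stats::rnorm(length(X), sd = noiseSd), nrow(X), ncol(X))
    Y <- Y + matrix(stats::rnorm(length(Y), sd = noiseSd), nrow(Y), ncol(Y))
  })
  TwoBlockDataset(X, Y)
}
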