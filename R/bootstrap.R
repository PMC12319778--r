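#' Bootstrap feature-weight reliability
#'
#' Resamples observations with replacement \code{nBoot} times, re-runs
#' the PLS decomposition on each resample, and Procrustes-aligns each
#' resampled decomposition to the original via the brain component
#' (the rotation from [solveProcrustes()] on U(b) vs U is applied to
#' both U(b) and V(b)). From the aligned resamples it reports:
#' \itemize{
#'   \item bootstrap ratios for the brain features: a feature's mean
#'     aligned weight divided by its standard deviation across
#'     resamples (analogous to a z-score);
#'   \item behavioural loadings: Pearson correlations between each Y
#'     variable and the Y latent scores on the original sample, with
#'     percentile 95% confidence intervals across the resampled
#'     (aligned) loadings.
#' }
#' Resamples in which any column becomes constant are redrawn (the
#' count is recorded). When a feature's across-resample SD falls below
#' the 1e-12 floor its ratio is capped at mean/1e-12 and flagged.
#'
#' @param data a [TwoBlockDataset-class].
#' @param nBoot number of bootstrap resamples (study default 10000; at
#'   least 100 for CI estimation).
#' @param seed integer resampling seed.
#' @return A [BootstrapResult-class].
#' @examples
#' set.seed(3)
#' z <- rnorm(60)
#' d <- TwoBlockDataset(cbind(z + rnorm(60, sd = 0.4), rnorm(60)),
#'                      cbind(z + rnorm(60, sd = 0.4), rnorm(60)))
#' br <- bootstrapReliability(d, nBoot = 200, seed = 1)
#' behaviourLoadings(br)
#' @export
bootstrapReliability <- function(data, nBoot = 10000L, seed = 1L) {
  stopifnot(is(data, "TwoBlockDataset"))
  nBoot <- as.integer(nBoot)
  if (nBoot < 100L)
    stop("nBoot must be at least 100 for CI estimation", call. = FALSE)
  X <- xBlock(data)
  Y <- yBlock(data)
  n <- nrow(X)
  p <- ncol(X)
  q <- ncol(Y)
  ref <- plsDecompose(data)
  k <- numLV(ref)
  U <- leftVectors(ref)
  V <- rightVectors(ref)

  # loadings on the original sample: correlation of each Y variable
  # with the Y latent scores Yz %*% V
  Yz <- zscoreColumns(Y)
  scoresY <- Yz %*% V
  loadingsY <- stats::cor(Y, scoresY)

  sumU <- matrix(0, p, k)
  sumU2 <- matrix(0, p, k)
  bootLoad <- array(NA_real_, dim = c(nBoot, q, k))
  nRedrawn <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(nBoot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        if (!length(.constantColumns(Xb)) && !length(.constantColumns(Yb)))
          break
        nRedrawn <- nRedrawn + 1L
        if (nRedrawn > 100L * nBoot)
          stop("too many degenerate bootstrap resamples", call. = FALSE)
      }
      Xbz <- zscoreColumns(Xb)
      Ybz <- zscoreColumns(Yb)
      s <- .svdCross(Xbz, Ybz, k)
      R <- .procrustesR(crossprod(s$u, U))
      Ub <- s$u %*% R
      Vb <- s$v %*% R
      sumU <- sumU + Ub
      sumU2 <- sumU2 + Ub^2
      bootLoad[b, , ] <- stats::cor(Yb, Ybz %*% Vb)
    }
  })

  meanU <- sumU / nBoot
  varU <- pmax(sumU2 / nBoot - meanU^2, 0) * nBoot / (nBoot - 1L)
  sdU <- sqrt(varU)
  floorMask <- sdU < 1e-12
  sdSafe <- pmax(sdU, 1e-12)
  ratios <- meanU / sdSafe
  ratios[meanU == 0] <- 0

  ciLow <- apply(bootLoad, c(2L, 3L), stats::quantile, probs = 0.025,
                 names = FALSE)
  ciHigh <- apply(bootLoad, c(2L, 3L), stats::quantile, probs = 0.975,
                  names = FALSE)
  dimnames(ratios) <- dimnames(floorMask) <-
    list(colnames(X), paste0("LV", seq_len(k)))
  dimnames(loadingsY) <- dimnames(ciLow) <- dimnames(ciHigh) <-
    list(colnames(Y), paste0("LV", seq_len(k)))
  new("BootstrapResult", bootstrapRatiosX = ratios, sdFlooredX = floorMask,
      loadingsY = loadingsY, loadingCILow = ciLow, loadingCIHigh = ciHigh,
      nBoot = nBoot, nRedrawn = nRedrawn, seed = as.integer(seed))
}

#' @rdname accessors
setMethod("bootstrapRatios", "BootstrapResult",
          function(object) object@bootstrapRatiosX)
#' @rdname accessors
setMethod("behaviourLoadings", "BootstrapResult",
          function(object) object@loadingsY)
#' @rdname accessors
setMethod("loadingCI", "BootstrapResult", function(object)
  list(low = object@loadingCILow, high = object@loadingCIHigh))

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult:", object@nBoot, "resamples",
      sprintf("(%d redrawn)", object@nRedrawn), "\n")
  cat("  brain features:", nrow(object@bootstrapRatiosX),
      " behaviour variables:", nrow(object@loadingsY),
      " LVs:", ncol(object@loadingsY), "\n")
})
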