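#' Split-half stability of the latent variables
#'
#' Repeatedly splits the sample at random into two disjoint halves,
#' runs the PLS decomposition on each half separately, and records for
#' each LV the absolute Pearson correlation between the two halves'
#' singular vectors, separately for the brain (U) and behaviour (V)
#' blocks. The absolute value accounts for arbitrary sign flips; LVs
#' are matched between halves by rank order. With an odd number of
#' observations the extra row goes to the first half.
#'
#' @param data a [TwoBlockDataset-class] with at least 6 observations.
#' @param nSplits number of random splits (study default 100).
#' @param seed integer seed for the splits.
#' @return A [StabilityResult-class].
#' @examples
#' set.seed(2)
#' d <- TwoBlockDataset(matrix(rnorm(600), 60), matrix(rnorm(180), 60))
#' st <- splitHalfStability(d, nSplits = 10, seed = 1)
#' stabilitySummary(st)
#' @export
splitHalfStability <- function(data, nSplits = 100L, seed = 1L) {
  stopifnot(is(data, "TwoBlockDataset"))
  n <- nObs(data)
  if (n < 6L)
    stop("split-half stability needs at least 6 observations", call. = FALSE)
  nSplits <- as.integer(nSplits)
  if (nSplits < 1L) stop("nSplits must be >= 1", call. = FALSE)
  X <- xBlock(data)
  Y <- yBlock(data)
  k <- min(ncol(X), ncol(Y))
  n1 <- ceiling(n / 2)
  perSplitX <- matrix(NA_real_, nSplits, k)
  perSplitY <- matrix(NA_real_, nSplits, k)
  withr::with_seed(as.integer(seed), {
    for (s in seq_len(nSplits)) {
      ord <- sample.int(n)
      h1 <- ord[seq_len(n1)]
      h2 <- ord[-seq_len(n1)]
      d1 <- .plsFromC(crossprod(zscoreColumns(X[h1, , drop = FALSE]),
                                zscoreColumns(Y[h1, , drop = FALSE])) /
                        (length(h1) - 1L))
      d2 <- .plsFromC(crossprod(zscoreColumns(X[h2, , drop = FALSE]),
                                zscoreColumns(Y[h2, , drop = FALSE])) /
                        (length(h2) - 1L))
      for (j in seq_len(k)) {
        perSplitX[s, j] <- abs(stats::cor(d1@U[, j], d2@U[, j]))
        perSplitY[s, j] <- abs(stats::cor(d1@V[, j], d2@V[, j]))
      }
    }
  })
  colnames(perSplitX) <- colnames(perSplitY) <- paste0("LV", seq_len(k))
  new("StabilityResult", perSplitX = perSplitX, perSplitY = perSplitY,
      seed = as.integer(seed))
}

#' @rdname accessors
setMethod("stabilityX", "StabilityResult", function(object) object@perSplitX)
#' @rdname accessors
setMethod("stabilityY", "StabilityResult", function(object) object@perSplitY)
#' @rdname accessors
setMethod("numLV", "StabilityResult",
          function(object) ncol(object@perSplitX))

#' Per-LV stability summary
#'
#' Mean and standard deviation of the per-split absolute correlations,
#' per LV and per block.
#'
#' @param object a [StabilityResult-class].
#' @return data.frame with one row per LV: mean and SD for each block.
#' @export
stabilitySummary <- function(object) {
  stopifnot(is(object, "StabilityResult"))
  data.frame(lv = seq_len(ncol(object@perSplitX)),
             stability_x_mean = colMeans(object@perSplitX),
             stability_x_sd = apply(object@perSplitX, 2L, stats::sd),
             stability_y_mean = colMeans(object@perSplitY),
             stability_y_sd = apply(object@perSplitY, 2L, stats::sd),
             row.names = NULL)
}

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult:", nrow(object@perSplitX), "splits,",
      ncol(object@perSplitX), "LV(s)\n")
  s <- stabilitySummary(object)
  show <- min(nrow(s), 5L)
  cat("  mean |r| X: ",
      paste(signif(s$stability_x_mean[seq_len(show)], 3), collapse = ", "),
      "\n  mean |r| Y: ",
      paste(signif(s$stability_y_mean[seq_len(show)], 3), collapse = ", "),
      "\n", sep = "")
})
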