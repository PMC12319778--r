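#' Run a simulation sweep
#'
#' Orchestrates the four simulated analyses: for each grid value and
#' replicate, a dataset is generated, all four permutation tests are
#' run on shared shuffle indices, and covariance explained plus
#' split-half stability are recorded for every LV. The analyses are
#' \describe{
#'   \item{\code{random}}{iid-normal null data; the grid is sample
#'     size. Pass rates here estimate the empirical type-I error.}
#'   \item{\code{sample_size}}{one latent effect at canonical
#'     correlation \code{r} (default 0.3); the grid is sample size.}
#'   \item{\code{canonical_correlation}}{one latent effect at sample
#'     size \code{n} (default 1000); the grid is the canonical
#'     correlation.}
#'   \item{\code{noise}}{one latent effect (\code{r}, \code{n} fixed);
#'     the grid is the SD of additive Gaussian noise.}
#' }
#' Replicate seeds are derived deterministically from the master seed,
#' so results do not depend on evaluation order. Stability is computed
#' once per dataset (it does not depend on the rotation method).
#' Failed replicates are recorded and skipped; the sweep aborts if more
#' than 1% fail.
#'
#' The study-scale grids are 10 sample sizes log-spaced 10 to 10000, 10
#' canonical correlations linearly spaced 0.1 to 0.9, 10 noise SDs
#' linearly spaced 0 to 1, with 100 replicates, 10000 permutations and
#' 100 splits per dataset; pass smaller grids/counts for desk-scale
#' runs.
#'
#' @param analysis one of \code{"random"}, \code{"sample_size"},
#'   \code{"canonical_correlation"}, \code{"noise"}.
#' @param grid numeric vector of grid values (sample sizes, canonical
#'   correlations, or noise SDs, by analysis).
#' @param nReplicates replicate datasets per grid value.
#' @param nPerm permutations per test.
#' @param nSplits random splits for stability.
#' @param seed master seed.
#' @param n companion sample size for the
#'   \code{canonical_correlation}/\code{noise} analyses.
#' @param r companion canonical correlation for the
#'   \code{sample_size}/\code{noise} analyses.
#' @param p,q feature counts (study defaults 90 and 10).
#' @return A tidy data.frame with one row per
#'   (grid value, replicate, LV): p-values for the four methods,
#'   covariance explained, and mean split-half stability per block.
#'   Sweep settings and per-replicate seeds are attached as the
#'   \code{"metadata"} attribute.
#' @seealso [passRate()]
#' @export
runAnalysis <- function(analysis = c("random", "sample_size",
                                     "canonical_correlation", "noise"),
                        grid, nReplicates = 100L, nPerm = 10000L,
                        nSplits = 100L, seed = 1L,
                        n = 1000L, r = 0.3, p = 90L, q = 10L) {
  analysis <- match.arg(analysis)
  if (!length(grid)) stop("grid must be nonempty", call. = FALSE)
  nReplicates <- as.integer(nReplicates)
  nCell <- length(grid) * nReplicates
  # 5 independent sub-seeds per replicate:
  # model, sample, noise, permutations, splits
  seedTab <- withr::with_seed(as.integer(seed),
    matrix(sample.int(.Machine$integer.max - 1L, nCell * 5L), ncol = 5L))
  rows <- vector("list", nCell)
  failures <- 0L
  cell <- 0L
  for (gi in seq_along(grid)) {
    g <- grid[gi]
    for (rep in seq_len(nReplicates)) {
      cell <- cell + 1L
      sds <- seedTab[cell, ]
      res <- tryCatch(
        .sweepReplicate(analysis, g, sds, nPerm, nSplits, n, r, p, q),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- failures + 1L
        warning("replicate failed (", analysis, ", grid value ", g,
                ", replicate ", rep, "): ", conditionMessage(res),
                call. = FALSE)
        if (failures > max(1L, ceiling(0.01 * nCell)))
          stop("more than 1% of replicates failed; aborting sweep",
               call. = FALSE)
        next
      }
      res$analysis <- analysis
      res$grid_value <- g
      res$replicate <- rep
      rows[[cell]] <- res
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[, c("analysis", "grid_value", "replicate", "lv",
                 "p_none", "p_behaviour", "p_brain", "p_both",
                 "covariance_explained",
                 "stability_x_mean", "stability_y_mean")]
  rownames(out) <- NULL
  attr(out, "metadata") <- list(
    analysis = analysis, grid = grid, n_replicates = nReplicates,
    n_perm = as.integer(nPerm), n_splits = as.integer(nSplits),
    seed = as.integer(seed), companions = list(n = n, r = r, p = p, q = q),
    replicate_seeds = seedTab, n_failures = failures,
    shared_shuffle_indices = TRUE)
  out
}

.sweepReplicate <- function(analysis, g, sds, nPerm, nSplits, n, r, p, q) {
  data <- switch(analysis,
    random = generateNullDataset(n = g, p = p, q = q, seed = sds[2]),
    sample_size = sampleDataset(
      buildJointCorrelation(p, q, r = r, seed = sds[1]), n = g, seed = sds[2]),
    canonical_correlation = sampleDataset(
      buildJointCorrelation(p, q, r = g, seed = sds[1]), n = n, seed = sds[2]),
    noise = addNoise(sampleDataset(
      buildJointCorrelation(p, q, r = r, seed = sds[1]), n = n, seed = sds[2]),
      noiseSd = g, seed = sds[3]))
  tests <- runAllPermutationTests(data, nPerm = nPerm, seed = sds[4])
  stab <- stabilitySummary(splitHalfStability(data, nSplits = nSplits,
                                              seed = sds[5]))
  obs <- observedValues(tests$none)
  k <- length(obs)
  data.frame(lv = seq_len(k),
             p_none = pValues(tests$none),
             p_behaviour = pValues(tests$behaviour),
             p_brain = pValues(tests$brain),
             p_both = pValues(tests$both),
             covariance_explained = obs^2 / sum(obs^2),
             stability_x_mean = stab$stability_x_mean,
             stability_y_mean = stab$stability_y_mean)
}

#' Pass rate of a permutation test across replicates
#'
#' Fraction of replicate datasets whose p-value for a given LV and
#' rotation method falls strictly below \code{alpha}, at each grid
#' value of a sweep. On null data this estimates the empirical type-I
#' error of the test; with a simulated effect it estimates power.
#'
#' @param result a sweep data.frame from [runAnalysis()].
#' @param lv latent variable index (default 1).
#' @param method one of \code{"none"}, \code{"behaviour"},
#'   \code{"brain"}, \code{"both"}.
#' @param alpha significance level (default 0.05, strict inequality).
#' @return data.frame with columns \code{grid_value} and
#'   \code{pass_rate}.
#' @export
passRate <- function(result, lv = 1L, method = "none", alpha = 0.05) {
  if (!method %in% c("none", "behaviour", "brain", "both"))
    stop("unknown method: ", method, call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  col <- paste0("p_", method)
  if (!col %in% names(result)) stop("column ", col, " not found", call. = FALSE)
  sub <- result[result$lv == lv, , drop = FALSE]
  if (!nrow(sub)) stop("lv out of range", call. = FALSE)
  agg <- stats::aggregate(sub[[col]] < alpha,
                          by = list(grid_value = sub$grid_value), FUN = mean)
  names(agg)[2] <- "pass_rate"
  agg[order(agg$grid_value), , drop = FALSE]
}
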