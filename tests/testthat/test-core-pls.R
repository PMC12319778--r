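test_that("z-scoring standardizes columns under the n-1 convention", {
  # two-point symmetry
  expect_equal(zscoreColumns(matrix(c(1, 3), 2))[, 1],
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # frozen hand computation: mean 5, sd sqrt(20/3)
  expect_equal(zscoreColumns(matrix(c(2, 4, 6, 8), 4))[, 1],
               c(-3, -1, 1, 3) / 2.5819888974716112,
               tolerance = 1e-12)
  # idempotence on an already-standardized column
  z <- zscoreColumns(matrix(rnorm(20), 10, 2))
  expect_equal(zscoreColumns(z), z, tolerance = 1e-12)
  # each column mean 0, sample variance 1
  M <- matrix(rnorm(60), 12, 5)
  Z <- zscoreColumns(M)
  expect_equal(unname(colMeans(Z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, var)), rep(1, 5), tolerance = 1e-12)
})

test_that("zero-variance columns are rejected by name", {
  M <- cbind(a = rnorm(5), flat = rep(2, 5))
  expect_error(zscoreColumns(M), "flat")
  expect_error(TwoBlockDataset(M, matrix(rnorm(10), 5)), "flat")
})

test_that("dataset validity enforces matched rows and minimum size", {
  expect_error(TwoBlockDataset(matrix(rnorm(12), 4), matrix(rnorm(15), 5)),
               "rows")
  expect_error(TwoBlockDataset(matrix(rnorm(4), 2), matrix(rnorm(4), 2)),
               "3 observations")
})

test_that("cross-correlation entries are exact Pearson correlations", {
  set.seed(11)
  # a column shared between blocks correlates perfectly with itself
  shared <- rnorm(9)
  d <- TwoBlockDataset(cbind(shared), cbind(shared))
  expect_equal(crossCorrelation(d)[1, 1], 1, tolerance = 1e-12)

  # a Y column orthogonal to X after centring gives zero correlation
  x <- rnorm(8)
  y <- rnorm(8)
  xc <- x - mean(x)
  y <- y - mean(y)
  y <- y - sum(y * xc) / sum(xc^2) * xc
  d <- TwoBlockDataset(cbind(x), cbind(y))
  expect_lt(abs(crossCorrelation(d)[1, 1]), 1e-12)

  # fixed integer toy against the pairwise-correlation oracle
  X <- matrix(c(1, 4, 2, 8, 5, 3, 9, 1, 7, 6), 5, 2)
  Y <- matrix(c(2, 2, 6, 4, 9, 1, 8, 3, 5, 7), 5, 2)
  d <- TwoBlockDataset(X, Y)
  expect_equal(unname(crossCorrelation(d)), unname(cor(X, Y)),
               tolerance = 1e-12)
  expect_true(all(abs(crossCorrelation(d)) <= 1 + 1e-12))
})

test_that("decomposition satisfies reconstruction, energy and orthonormality", {
  set.seed(21)
  for (dims in list(c(30, 7, 3), c(25, 4, 9), c(40, 6, 6))) {
    d <- TwoBlockDataset(matrix(rnorm(dims[1] * dims[2]), dims[1]),
                         matrix(rnorm(dims[1] * dims[3]), dims[1]))
    dec <- plsDecompose(d)
    k <- min(dims[2], dims[3])
    expect_identical(numLV(dec), as.integer(k))
    C <- crossCorrelation(d)
    U <- leftVectors(dec)
    V <- rightVectors(dec)
    s <- singularValues(dec)
    expect_lt(norm(C - U %*% (s * t(V)), "F"), 1e-8)
    expect_lt(abs(sum(s^2) - sum(C^2)), 1e-8)
    expect_lt(max(abs(crossprod(U) - diag(k))), 1e-8)
    expect_lt(max(abs(crossprod(V) - diag(k))), 1e-8)
    expect_true(all(diff(s) <= 1e-12))
    expect_equal(sum(covarianceExplained(dec)), 1, tolerance = 1e-12)
    expect_equal(covarianceExplained(dec), s^2 / sum(s^2), tolerance = 1e-12)
    # sign convention: largest-magnitude V element of each LV is positive
    for (j in seq_len(k)) {
      expect_gt(V[which.max(abs(V[, j])), j], 0)
    }
  }
})

test_that("decomposition is equivariant to joint row permutation", {
  set.seed(31)
  d <- TwoBlockDataset(matrix(rnorm(20 * 5), 20), matrix(rnorm(20 * 3), 20))
  perm <- sample(20)
  d2 <- TwoBlockDataset(xBlock(d)[perm, ], yBlock(d)[perm, ])
  a <- plsDecompose(d)
  b <- plsDecompose(d2)
  expect_equal(singularValues(a), singularValues(b), tolerance = 1e-12)
  expect_equal(leftVectors(a), leftVectors(b), tolerance = 1e-10)
  expect_equal(rightVectors(a), rightVectors(b), tolerance = 1e-10)
})

test_that("singular values match the eigenvalue oracle on a fixed matrix", {
  C <- matrix(c(2, 0, 1, 1, 2, 0), 3, 2)
  dec <- plsperm:::.plsFromC(C)
  oracle <- sqrt(sort(eigen(crossprod(C), symmetric = TRUE)$values,
                      decreasing = TRUE))
  expect_equal(dec@d, oracle, tolerance = 1e-12)
})

test_that("a single shared latent score gives rank-1 covariance structure", {
  d <- latentToyDataset(500, 6, 4, strength = 0.995, seed = 7)
  dec <- plsDecompose(d)
  expect_gt(covarianceExplained(dec)[1], 0.95)
  expect_lt(singularValues(dec)[2] / singularValues(dec)[1], 0.2)
})

test_that("round trip through delimited text preserves the dataset", {
  set.seed(41)
  d <- TwoBlockDataset(matrix(rnorm(30), 10), matrix(rnorm(20), 10))
  xf <- withr::local_tempfile(fileext = ".csv")
  yf <- withr::local_tempfile(fileext = ".csv")
  write.csv(xBlock(d), xf, row.names = FALSE)
  write.csv(yBlock(d), yf, row.names = FALSE)
  d2 <- readTwoBlockDataset(xf, yf)
  expect_equal(xBlock(d2), xBlock(d), tolerance = 1e-12)
  expect_equal(featureNamesY(d2), featureNamesY(d))
})
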