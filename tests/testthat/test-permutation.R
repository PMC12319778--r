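test_that("identity permutation reproduces the original decomposition", {
  set.seed(1)
  d <- TwoBlockDataset(matrix(rnorm(60), 12), matrix(rnorm(36), 12))
  ref <- plsDecompose(d)
  for (side in c("y", "x")) {
    pd <- permutedDecomposition(d, seq_len(12), side = side)
    expect_equal(singularValues(pd), singularValues(ref), tolerance = 1e-14)
    expect_equal(leftVectors(pd), leftVectors(ref), tolerance = 1e-14)
  }
})

test_that("invalid permutation vectors are rejected", {
  set.seed(2)
  d <- TwoBlockDataset(matrix(rnorm(30), 6), matrix(rnorm(12), 6))
  expect_error(permutedDecomposition(d, c(1, 1, 2, 3, 4, 5)), "permutation")
  expect_error(permutedDecomposition(d, 1:5), "permutation")
  expect_error(permutedDecomposition(d, c(1:5, 7)), "permutation")
})

test_that("permuted decomposition matches direct recomputation on a fixed toy", {
  X <- matrix(c(3, 1, 4, 1, 5, 9,
                2, 6, 5, 3, 5, 8,
                9, 7, 9, 3, 2, 3), 6, 3)
  Y <- matrix(c(2, 7, 1, 8, 2, 8,
                1, 4, 1, 4, 2, 1), 6, 2)
  d <- TwoBlockDataset(X, Y)
  perm <- c(4, 1, 6, 2, 5, 3)
  pd <- permutedDecomposition(d, perm, side = "y")
  oracle <- svd(cor(X, Y[perm, ]))$d
  expect_equal(singularValues(pd), oracle, tolerance = 1e-12)
  # x-side shuffling with the inverse index yields the same pairing
  pdx <- permutedDecomposition(d, order(perm), side = "x")
  expect_equal(singularValues(pdx), singularValues(pd), tolerance = 1e-12)
})

test_that("a two-row swap only flips the correlation sign", {
  # at n = 2 the z-scored columns are +-1/sqrt(2), so swapping the rows
  # of one block negates every correlation and preserves singular values
  withr::with_seed(3, {
    X <- matrix(rnorm(4), 2, 2)
    Y <- matrix(rnorm(2), 2, 1)
  })
  Xz <- zscoreColumns(X)
  Yz <- zscoreColumns(Y)
  s0 <- plsperm:::.svdCross(Xz, Yz, 1)
  s1 <- plsperm:::.svdCross(Xz, Yz[2:1, , drop = FALSE], 1)
  expect_equal(s1$d, s0$d, tolerance = 1e-12)
})

test_that("Procrustes solution handles identity and relabeling exactly", {
  set.seed(4)
  V <- qr.Q(qr(matrix(rnorm(12), 4, 3)))
  expect_equal(solveProcrustes(V, V), diag(3), tolerance = 1e-12)
  swap <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
  expect_equal(solveProcrustes(V[, c(2, 1, 3)], V), swap, tolerance = 1e-12)
  expect_error(solveProcrustes(V, V[, 1:2]), "shape")
})

test_that("Procrustes solution is optimal against a random/grid search", {
  set.seed(5)
  thetaGrid <- seq(0, 2 * pi, length.out = 721)
  for (i in 1:5) {
    Wp <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
    Wr <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
    R <- solveProcrustes(Wp, Wr)
    expect_lt(max(abs(crossprod(R) - diag(2))), 1e-8)
    best <- procrustesObjective(Wp, R, Wr)
    # fine grid over all 2x2 rotations and reflections
    gridBest <- min(vapply(thetaGrid, function(theta) {
      min(procrustesObjective(Wp, randomOrthogonal2(theta, FALSE), Wr),
          procrustesObjective(Wp, randomOrthogonal2(theta, TRUE), Wr))
    }, numeric(1)))
    expect_lte(best, gridBest + 1e-10)
  }
})

test_that("rotated null values collapse correctly in degenerate cases", {
  set.seed(6)
  # k = 1: the rotation is +-1 and the value is the permuted singular value
  d1 <- TwoBlockDataset(matrix(rnorm(60), 12), matrix(rnorm(12), 12))
  ref1 <- plsDecompose(d1)
  pd1 <- permutedDecomposition(d1, sample(12), side = "y")
  expect_equal(rotatedNullValues(pd1, ref1, "v"), singularValues(pd1),
               tolerance = 1e-12)
  # self-alignment: R = I and the values are the singular values
  d <- TwoBlockDataset(matrix(rnorm(60), 12), matrix(rnorm(48), 12))
  ref <- plsDecompose(d)
  expect_equal(rotatedNullValues(ref, ref, "v"), singularValues(ref),
               tolerance = 1e-10)
  expect_equal(rotatedNullValues(ref, ref, "u"), singularValues(ref),
               tolerance = 1e-10)
})

test_that("rotation conserves total covariance and cannot exceed the top value", {
  set.seed(7)
  d <- generateNullDataset(40, 15, 6, seed = 8)
  ref <- plsDecompose(d)
  for (i in 1:10) {
    pd <- permutedDecomposition(d, sample(40), side = "y")
    sp <- singularValues(pd)
    for (comp in c("v", "u")) {
      vals <- rotatedNullValues(pd, ref, comp)
      expect_lt(abs(sum(vals^2) - sum(sp^2)), 1e-8)
      expect_lte(max(vals), sp[1] + 1e-10)
    }
  }
})

test_that("p-values hit the boundary conventions", {
  # overwhelming effect: no permuted value reaches the observed LV1
  d <- latentToyDataset(80, 5, 3, strength = 0.98, seed = 9)
  nd <- runPermutationTest(d, method = "none", nPerm = 50, seed = 10)
  expect_identical(pValues(nd)[1], 0)
  ndAdd <- runPermutationTest(d, method = "none", nPerm = 50, seed = 10,
                              addOne = TRUE)
  expect_equal(pValues(ndAdd)[1], 1 / 51, tolerance = 1e-12)
  # add-one shifts every p-value monotonically
  expect_true(all(pValues(ndAdd) >= pValues(nd)))
})

test_that("all four methods agree exactly when Y has a single column", {
  set.seed(11)
  d <- TwoBlockDataset(matrix(rnorm(25 * 6), 25), matrix(rnorm(25), 25))
  tests <- runAllPermutationTests(d, nPerm = 300, seed = 12)
  for (m in c("behaviour", "brain", "both")) {
    expect_identical(nullValues(tests[[m]]), nullValues(tests$none))
    expect_identical(pValues(tests[[m]]), pValues(tests$none))
  }
})

test_that("equal seeds give bit-identical null distributions", {
  set.seed(13)
  d <- TwoBlockDataset(matrix(rnorm(20 * 8), 20), matrix(rnorm(20 * 4), 20))
  a <- runPermutationTest(d, method = "behaviour", nPerm = 100, seed = 14)
  b <- runPermutationTest(d, method = "behaviour", nPerm = 100, seed = 14)
  expect_identical(nullValues(a), nullValues(b))
  # a standalone run matches the shared-instance run at the same seed
  all4 <- runAllPermutationTests(d, nPerm = 100, seed = 14)
  expect_identical(nullValues(all4$behaviour), nullValues(a))
  # and a precomputed index table reproduces the seeded run
  idx <- makeShuffleIndices(20, 100, 14)
  cfg <- permutationConfig("behaviour", 100, seed = 14, shuffleIndices = idx)
  expect_identical(nullValues(runPermutationTest(d, cfg)), nullValues(a))
})

test_that("rotated LV1 p-values never exceed the unrotated one per dataset", {
  for (s in 1:8) {
    d <- generateNullDataset(30, 12, 5, seed = 100 + s)
    tests <- runAllPermutationTests(d, nPerm = 150, seed = 200 + s)
    p1 <- vapply(tests, function(t) pValues(t)[1], numeric(1))
    expect_lte(p1[["behaviour"]], p1[["none"]])
    expect_lte(p1[["brain"]], p1[["none"]])
    expect_lte(p1[["both"]], p1[["none"]])
  }
})

test_that("configuration validation catches malformed inputs", {
  expect_error(permutationConfig("none", nPerm = 0), "positive")
  badIdx <- matrix(c(1L, 1L, 2L, 3L), 1)
  expect_error(permutationConfig("none", nPerm = 1, shuffleIndices = badIdx),
               "permutation")
  set.seed(15)
  d <- TwoBlockDataset(matrix(rnorm(30), 6), matrix(rnorm(12), 6))
  cfg <- permutationConfig("none", nPerm = 10, seed = 1,
                           shuffleIndices = makeShuffleIndices(5, 10, 1))
  expect_error(runPermutationTest(d, cfg), "observations")
})
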