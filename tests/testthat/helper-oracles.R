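# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# population canonical correlations from the generalized eigenproblem
# Cxy Cyy^-1 Cyx a = rho^2 Cxx a, solved with base eigen()/solve()
geigCanonicalCorrelations <- function(Cxx, Cyy, Cxy) {
  M <- solve(Cxx, Cxy %*% solve(Cyy, t(Cxy)))
  ev <- eigen(M, only.values = TRUE)$values
  sort(sqrt(pmax(Re(ev), 0)), decreasing = TRUE)
}

# Frobenius objective of the orthogonal Procrustes problem
procrustesObjective <- function(Wperm, R, Wref) {
  sum((Wperm %*% R - Wref)^2)
}

# every 2x2 orthogonal matrix is a rotation or a reflection by an angle
randomOrthogonal2 <- function(theta, reflect) {
  ct <- cos(theta); st <- sin(theta)
  if (reflect) matrix(c(ct, st, st, -ct), 2, 2)
  else matrix(c(ct, st, -st, ct), 2, 2)
}

# a small dataset with one strong shared latent score
latentToyDataset <- function(n, p, q, strength = 0.9, seed = 1) {
  withr::with_seed(seed, {
    s <- rnorm(n)
    X <- outer(s, rnorm(p)) * strength +
      matrix(rnorm(n * p, sd = sqrt(1 - strength^2)), n, p)
    Y <- outer(s, rnorm(q)) * strength +
      matrix(rnorm(n * q, sd = sqrt(1 - strength^2)), n, q)
  })
  TwoBlockDataset(X, Y)
}
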