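# full-conditional updates for the marker layer: sweeps, inclusion
# probabilities, variance components

sweep1 <- nnbayes:::update_marker_effects_independent

test_that("an all-zero inclusion prior leaves effects and residual unchanged", {
  set.seed(1)
  X <- matrix(rbinom(40, 2, 0.4), 10, 4)
  r <- rnorm(10)
  out <- sweep1(r, X, b = numeric(4), d = rep(0L, 4), marker_vars = 0.1,
                sigma2_node = 1, pi = 0, family = "BayesCpi")
  expect_equal(out$b, numeric(4))
  expect_equal(out$d, rep(0L, 4))
  expect_equal(out$resid, r)
})

test_that("RR-BLUP chain average matches the closed-form ridge solution", {
  set.seed(2)
  n <- 12; p <- 3
  X <- matrix(rbinom(n * p, 2, 0.5), n, p)
  y <- rnorm(n)
  s2e <- 0.8; s2b <- 0.5
  # oracle: posterior mean = (X'X + I s2e/s2b)^-1 X'y
  ridge <- solve(crossprod(X) + diag(s2e / s2b, p), crossprod(X, y))
  niter <- 6000
  b <- numeric(p); d <- rep(1L, p); r <- drop(y - X %*% b)
  draws <- matrix(0, niter, p)
  for (it in seq_len(niter)) {
    out <- sweep1(r, X, b, d, marker_vars = s2b, sigma2_node = s2e,
                  pi = 1, family = "RR-BLUP")
    b <- out$b; d <- out$d; r <- out$resid
    draws[it, ] <- b
  }
  draws <- draws[-(1:500), ]
  for (j in seq_len(p))
    expect_lt(abs(mean(draws[, j]) - ridge[j]), 3 * mcse(draws[, j]))
  # invariant: residual bookkeeping stays consistent with the state
  expect_equal(r, drop(y - X %*% b), tolerance = 1e-10)
})

test_that("BayesCpi ranks truly causal markers highest", {
  set.seed(3)
  n <- 300; p <- 50
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  causal <- c(7L, 23L)
  y <- drop(X[, causal] %*% c(1.5, -1.5)) + rnorm(n, 0, 0.5)
  y <- y - mean(y)
  b <- numeric(p); d <- rep(0L, p); r <- y
  pi <- 0.1
  incl <- numeric(p)
  niter <- 600
  for (it in seq_len(niter)) {
    out <- sweep1(r, X, b, d, marker_vars = 0.5, sigma2_node = 0.5,
                  pi = pi, family = "BayesCpi")
    b <- out$b; d <- out$d; r <- out$resid
    if (it > 100) incl <- incl + d
  }
  expect_setequal(order(incl, decreasing = TRUE)[1:2], causal)
})

test_that("inclusion-probability update follows its Beta/Dirichlet posterior", {
  set.seed(4)
  d <- c(rep(1L, 60), rep(0L, 40))
  draws <- replicate(4000, nnbayes:::update_inclusion_probability(d))
  # oracle: Beta(61, 41) mean
  expect_lt(abs(mean(draws) - 61 / 102), 4 * sd(draws) / sqrt(4000))
  expect_true(all(draws >= 0 & draws <= 1))

  dall <- rep(1L, 200)
  expect_gt(mean(replicate(500, nnbayes:::update_inclusion_probability(dall))),
            0.98)
  expect_error(nnbayes:::update_inclusion_probability(integer(0)), "no markers")

  cfg <- nnbayes:::inclusion_configs(2L)
  D <- rbind(matrix(c(1L, 1L), 30, 2, byrow = TRUE),
             matrix(c(0L, 0L), 10, 2, byrow = TRUE))
  Pi <- replicate(4000, nnbayes:::update_inclusion_probability(
    D, "multi_trait", cfg))
  expect_equal(dim(Pi), c(4L, 4000L))
  # Dirichlet(11, 1, 1, 31) means
  alpha <- c(11, 1, 1, 31)
  for (k in 1:4)
    expect_lt(abs(mean(Pi[k, ]) - alpha[k] / sum(alpha)),
              4 * sd(Pi[k, ]) / sqrt(4000))
})

test_that("multi-trait configuration posterior matches numerical integration", {
  set.seed(5)
  n <- 6; l1 <- 2
  x <- as.numeric(rbinom(n, 2, 0.4))
  X <- matrix(x, n, 1)
  Rmat <- matrix(rnorm(n * l1, 0, 1), n, l1)
  Rmat[, 1] <- Rmat[, 1] + 0.8 * x
  G <- matrix(c(0.6, 0.1, 0.1, 0.4), 2)
  Sigma <- matrix(c(1, 0.3, 0.3, 0.8), 2)
  Sigmainv <- solve(Sigma)
  Pi <- c(0.25, 0.25, 0.25, 0.25)
  cfg <- nnbayes:::inclusion_configs(2L)

  # oracle: p(config | R) by 2-D grid integration of the Gaussian likelihood
  # over beta ~ N(0, G), independent of the sampler's algebra
  grid <- seq(-4, 4, length.out = 241)
  hstep <- grid[2] - grid[1]
  loglik <- function(w) {
    E <- Rmat - x %*% t(w)
    -0.5 * sum((E %*% Sigmainv) * E)
  }
  margs <- numeric(4)
  for (k in 1:4) {
    dk <- cfg[k, ]
    acc <- 0
    for (b1 in grid) for (b2 in grid) {
      bb <- c(b1, b2)
      pri <- exp(-0.5 * drop(bb %*% solve(G, bb)))
      acc <- acc + pri * exp(loglik(dk * bb))
    }
    margs[k] <- acc * hstep^2
  }
  oracle <- margs * Pi / sum(margs * Pi)

  niter <- 20000
  B <- matrix(0, 1, 2); D <- matrix(0L, 1, 2)
  counts <- numeric(4)
  Rcur <- Rmat
  for (it in seq_len(niter)) {
    out <- nnbayes:::update_marker_effects_multitrait(
      Rcur, X, B, D, solve(G), Sigmainv, Pi, cfg)
    B <- out$B; D <- out$D; Rcur <- out$resid
    k <- sum(D[1, ] * c(1, 2)) + 1
    counts[k] <- counts[k] + 1
  }
  freq <- counts / niter
  for (k in 1:4)
    expect_lt(abs(freq[k] - oracle[k]),
              0.02 + 4 * sqrt(oracle[k] * (1 - oracle[k]) / niter))
})

test_that("a point-mass prior on the empty configuration zeroes all effects", {
  set.seed(6)
  n <- 8; p <- 3
  X <- matrix(rbinom(n * p, 2, 0.5), n, p)
  Rmat <- matrix(rnorm(n * 2), n, 2)
  cfg <- nnbayes:::inclusion_configs(2L)
  out <- nnbayes:::update_marker_effects_multitrait(
    Rmat, X, matrix(0, p, 2), matrix(0L, p, 2), diag(2), diag(2),
    c(1, 0, 0, 0), cfg)
  expect_equal(out$D, matrix(0L, p, 2))
  expect_equal(out$resid, Rmat)  # all effects zero, residual untouched
})

test_that("hidden residual covariance updates match their conjugate laws", {
  set.seed(7)
  # n = 0: draws come from the prior; scaled-inv-chi2 mean nu*S/(nu-2)
  E0 <- matrix(numeric(0), 0, 1)
  pri <- replicate(10000, nnbayes:::update_hidden_residual_cov(
    E0, nu_eps = 6, S_eps = 2, mode = "independent"))
  expect_equal(mean(pri), 3, tolerance = 0.1)  # nu*S/(nu-2) = 12/4

  # l1 = 1 inverse Wishart equals scaled-inv-chi2 in distribution
  iw <- replicate(10000, nnbayes:::update_hidden_residual_cov(
    matrix(numeric(0), 0, 1), nu_eps = 8, S_eps = matrix(3), mode = "multi_trait"))
  sc <- nnbayes:::rscinvchisq(10000, 8, 3 / 8)
  expect_equal(mean(iw), mean(sc), tolerance = 0.05)
  expect_equal(var(iw), var(sc), tolerance = 0.3 * var(sc))

  # consistency: with plenty of data the posterior mean approaches the truth
  Sig <- matrix(c(1, 0.5, 0.5, 2), 2)
  ch <- chol(Sig)
  E <- matrix(rnorm(5000 * 2), 5000, 2) %*% ch
  draws <- replicate(200, nnbayes:::update_hidden_residual_cov(
    E, nu_eps = 6, S_eps = diag(2), mode = "multi_trait"))
  post_mean <- apply(draws, c(1, 2), mean)
  expect_true(all(abs(post_mean - Sig) / Sig < 0.1))
})

test_that("per-family variance updates keep positivity and conjugate means", {
  set.seed(8)
  pr <- list(nu_marker = 4, S_marker = 0.5, lasso_shape = 0.1, lasso_rate = 0.1)
  b <- rnorm(20, 0, 0.7); d <- rep(1L, 20)
  for (fam in c("RR-BLUP", "BayesA", "BayesB", "BayesCpi")) {
    v <- nnbayes:::update_marker_variances(b, d, fam, pr)
    expect_true(all(v$varm > 0))
  }
  vL <- nnbayes:::update_marker_variances(b, d, "BayesL", pr, lambda2 = 2)
  expect_true(all(vL$varm > 0))
  expect_gt(vL$lambda2, 0)
  # BayesCpi scale: mean of (nu S + sum b^2)/chisq(nu + p) over draws
  reps <- replicate(4000, nnbayes:::update_marker_variances(
    b, d, "BayesCpi", pr)$common)
  nu_post <- 4 + 20
  expect_equal(mean(reps), (4 * 0.5 + sum(b^2)) / (nu_post - 2),
               tolerance = 0.05)
})
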