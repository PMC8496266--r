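# Hamiltonian Monte Carlo for the hidden-node full conditional

rand_cfg <- function(l1, act_name) {
  Sig <- crossprod(matrix(rnorm(l1 * l1, 0, 0.7), l1)) + diag(0.3, l1)
  list(z = rnorm(l1), y = rnorm(1), mu0 = rnorm(l1), xb = rnorm(l1),
       Sigma = Sig, mu1 = rnorm(1), w1 = rnorm(l1),
       s2e = runif(1, 0.2, 2), act = nnbayes:::make_activation(act_name))
}

test_that("gradient matches central finite differences on random configs", {
  set.seed(1)
  worst <- 0
  for (rep in 1:100) {
    l1 <- sample(1:3, 1)
    cc <- rand_cfg(l1, sample(c("tanh", "identity"), 1))
    gr <- nnbayes:::grad_log_cond_z(cc$z, cc$y, cc$mu0, cc$xb, cc$Sigma,
                                    cc$mu1, cc$w1, cc$s2e, cc$act)
    h <- 1e-5
    fd <- vapply(seq_len(l1), function(j) {
      zp <- cc$z; zm <- cc$z
      zp[j] <- zp[j] + h; zm[j] <- zm[j] - h
      (nnbayes:::log_cond_z(zp, cc$y, cc$mu0, cc$xb, cc$Sigma, cc$mu1,
                            cc$w1, cc$s2e, cc$act) -
       nnbayes:::log_cond_z(zm, cc$y, cc$mu0, cc$xb, cc$Sigma, cc$mu1,
                            cc$w1, cc$s2e, cc$act)) / (2 * h)
    }, numeric(1))
    rel <- sqrt(sum((gr - fd)^2)) / max(sqrt(sum(fd^2)), 1e-8)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("hand-worked gradient value is reproduced", {
  # identity activation, Sigma = I, s2e = 1, means 0, w1 = 1, y = 2, z = 0:
  # prior term 0, likelihood term (2 - 0) * 1 * 1 = 2
  g <- nnbayes:::grad_log_cond_z(0, 2, 0, 0, matrix(1), 0, 1, 1,
                                 nnbayes:::make_activation("identity"))
  expect_equal(g, 2)
})

test_that("log conditional obeys tanh odd symmetry and prior-only limits", {
  set.seed(2)
  act <- nnbayes:::make_activation("tanh")
  for (rep in 1:20) {
    cc <- rand_cfg(2, "tanh")
    v1 <- nnbayes:::log_cond_z(cc$z, cc$y, cc$mu0, cc$xb, cc$Sigma, cc$mu1,
                               cc$w1, cc$s2e, act)
    v2 <- nnbayes:::log_cond_z(-cc$z, cc$y, -cc$mu0, -cc$xb, cc$Sigma,
                               cc$mu1, -cc$w1, cc$s2e, act)
    expect_equal(v1, v2, tolerance = 1e-12)
  }
  # w1 = 0: pure MVN kernel, maximised (gradient zero) at z = mu0 + xb
  cc <- rand_cfg(3, "tanh")
  g0 <- nnbayes:::grad_log_cond_z(cc$mu0 + cc$xb, cc$y, cc$mu0, cc$xb,
                                  cc$Sigma, cc$mu1, rep(0, 3), cc$s2e, cc$act)
  expect_equal(g0, rep(0, 3), tolerance = 1e-12)
  zs <- replicate(20, {
    dz <- rnorm(3, 0, 0.5)
    nnbayes:::log_cond_z(cc$mu0 + cc$xb + dz, cc$y, cc$mu0, cc$xb, cc$Sigma,
                         cc$mu1, rep(0, 3), cc$s2e, cc$act)
  })
  vmax <- nnbayes:::log_cond_z(cc$mu0 + cc$xb, cc$y, cc$mu0, cc$xb, cc$Sigma,
                               cc$mu1, rep(0, 3), cc$s2e, cc$act)
  expect_true(all(zs <= vmax))
})

test_that("identity activation at l1 = 1 matches conjugate-normal algebra", {
  set.seed(3)
  cc <- rand_cfg(1, "identity")
  # oracle: product of two Gaussian kernels in z
  prec <- 1 / cc$Sigma[1, 1] + cc$w1^2 / cc$s2e
  mean_z <- ((cc$mu0 + cc$xb) / cc$Sigma[1, 1] +
               cc$w1 * (cc$y - cc$mu1) / cc$s2e) / prec
  zgrid <- seq(-3, 3, length.out = 7)
  vals <- vapply(zgrid, function(z)
    nnbayes:::log_cond_z(z, cc$y, cc$mu0, cc$xb, cc$Sigma, cc$mu1, cc$w1,
                         cc$s2e, cc$act), numeric(1))
  oracle <- -0.5 * prec * (zgrid - mean_z)^2
  expect_equal(vals - vals[1], oracle - oracle[1], tolerance = 1e-8)
})

test_that("a zero step size is always accepted with ratio one", {
  set.seed(4)
  cc <- rand_cfg(2, "tanh")
  out <- nnbayes:::hmc_update(cc$z, cc$y, cc$mu0, cc$xb, cc$Sigma, cc$mu1,
                              cc$w1, cc$s2e, cfg = hmc_control(L = 10, epsilon = 0))
  expect_equal(out$z, cc$z)
  expect_equal(out$r, 1)
  expect_true(out$accepted)
})

test_that("leapfrog is time-reversible to 1e-8", {
  set.seed(5)
  n <- 5; l1 <- 2
  Z <- matrix(rnorm(n * l1), n, l1)
  P <- matrix(rnorm(n * l1), n, l1)
  y <- rnorm(n); Mu <- matrix(rnorm(n * l1), n, l1)
  Sigi <- solve(crossprod(matrix(rnorm(4), 2)) + diag(0.5, 2))
  act <- nnbayes:::make_activation("tanh")
  gradfun <- function(Zc) nnbayes:::grad_log_cond_zmat(Zc, y, Mu, Sigi, 0.2,
                                                       c(1, -1), 0.7, act)
  fwd <- nnbayes:::leapfrog(Z, P, L = 10, eps = 0.1, Minv = diag(2), gradfun)
  back <- nnbayes:::leapfrog(fwd$Z, -fwd$P, L = 10, eps = 0.1, Minv = diag(2),
                             gradfun)
  expect_lt(max(abs(back$Z - Z)), 1e-8)
  expect_lt(max(abs(-back$P - P)), 1e-8)
})

test_that("energy error shrinks as the step size is refined", {
  set.seed(6)
  cc <- rand_cfg(2, "tanh")
  mean_abs_logr <- vapply(c(0.2, 0.1, 0.05), function(eps) {
    L <- round(2 / eps)  # fixed trajectory length L * eps = 2
    mean(replicate(300, {
      out <- nnbayes:::hmc_update(cc$z, cc$y, cc$mu0, cc$xb, cc$Sigma,
                                  cc$mu1, cc$w1, cc$s2e,
                                  cfg = hmc_control(L = L, epsilon = eps))
      abs(log(out$r))
    }))
  }, numeric(1))
  expect_true(all(diff(mean_abs_logr) < 0))
  expect_true(all(is.finite(mean_abs_logr)))
})

test_that("HMC reproduces the analytic Gaussian conditional (identity)", {
  set.seed(7)
  act <- nnbayes:::make_activation("identity")
  Sigma <- matrix(0.6); mu0 <- 0.4; xb <- 0.3; mu1 <- -0.2; w1 <- 1.3
  s2e <- 0.5; yobs <- 1.1
  prec <- 1 / Sigma[1, 1] + w1^2 / s2e
  m_true <- ((mu0 + xb) / Sigma[1, 1] + w1 * (yobs - mu1) / s2e) / prec
  v_true <- 1 / prec
  # 10 replicate chains of 2,000 updates; the across-chain spread of the
  # estimates is the Monte-Carlo SE
  nrep <- 10; nit <- 2000
  ms <- vs <- numeric(nrep); acc <- 0
  for (rep in seq_len(nrep)) {
    z <- 0; zs <- numeric(nit)
    for (it in seq_len(nit)) {
      out <- nnbayes:::hmc_update(z, yobs, mu0, xb, Sigma, mu1, w1, s2e,
                                  cfg = hmc_control(), act = act)
      z <- out$z; acc <- acc + out$accepted
      zs[it] <- z
    }
    ms[rep] <- mean(zs); vs[rep] <- var(zs)
  }
  expect_gt(acc / (nrep * nit), 0.8)
  expect_lt(abs(mean(ms) - m_true), 3 * sd(ms) / sqrt(nrep))
  expect_lt(abs(mean(vs) - v_true), 3 * sd(vs) / sqrt(nrep))
})

test_that("batched sweep updates rows independently and counts acceptance", {
  set.seed(8)
  n <- 30; l1 <- 2
  Z <- matrix(rnorm(n * l1), n, l1)
  y <- rnorm(n)
  Mu <- matrix(0, n, l1)
  act <- nnbayes:::make_activation("tanh")
  cfg <- nnbayes:::resolve_hmc(hmc_control(), l1)
  out <- nnbayes:::hmc_sweep(Z, y, Mu, diag(l1), 0, c(1, 1), 1, act, cfg)
  expect_equal(dim(out$Z), c(n, l1))
  expect_length(out$accept, n)
  # rejected rows keep their previous value
  rej <- which(!out$accept)
  if (length(rej)) expect_equal(out$Z[rej, ], Z[rej, ])
  expect_true(all(is.finite(out$logr) | out$logr == -Inf))
})

test_that("non-finite inputs are rejected up front", {
  expect_error(nnbayes:::log_cond_z(NaN, 1, 0, 0, matrix(1), 0, 1, 1),
               "non-finite")
  expect_error(nnbayes:::grad_log_cond_z(0, Inf, 0, 0, matrix(1), 0, 1, 1),
               "non-finite")
})
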