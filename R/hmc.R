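# Hamiltonian Monte Carlo update of the hidden-node vectors z_i.
# All individuals are updated in one batched sweep: given the rest of the
# state the z_i are conditionally independent, so matrix operations across
# rows reproduce the per-individual sampler with a shared random stream
# (momentum matrix filled column-wise, then one uniform per individual).

make_activation <- function(name) {
  switch(name,
    tanh = list(name = "tanh", g = tanh,
                gprime = function(z) 1 - tanh(z)^2),
    identity = list(name = "identity", g = identity,
                    gprime = function(z) array(1, dim(z) %||% length(z))),
    stop("unknown activation: ", name))
}

# log full conditional of each row of Z, up to a constant:
# -1/2 (z - mu)' Sigmainv (z - mu) - (y - mu1 - w1'g(z))^2 / (2 sigma_e2)
log_cond_zmat <- function(Z, y, Mu, Sigmainv, mu1, w1, sigma_e2, act) {
  D <- Z - Mu
  q <- rowSums((D %*% Sigmainv) * D)
  f <- y - mu1 - drop(act$g(Z) %*% w1)
  -0.5 * q - f^2 / (2 * sigma_e2)
}

# gradient of the above wrt each row of Z:
# -Sigmainv (z - mu) + [(y - mu1 - w1'g(z)) / sigma_e2] * (w1 o g'(z))
grad_log_cond_zmat <- function(Z, y, Mu, Sigmainv, mu1, w1, sigma_e2, act) {
  f <- (y - mu1 - drop(act$g(Z) %*% w1)) / sigma_e2
  -(Z - Mu) %*% Sigmainv + f * sweep(act$gprime(Z), 2L, w1, `*`)
}

# single-individual views of the two functions above
log_cond_z <- function(z, y_i, mu0, xb, Sigma, mu1, w1, sigma_e2,
                       act = make_activation("tanh")) {
  if (!all(is.finite(c(z, y_i, mu0, xb, Sigma, mu1, w1, sigma_e2))))
    stop("non-finite input to log_cond_z")
  Sigma <- as.matrix(Sigma)
  Sigmainv <- chol2inv(chol(Sigma))
  drop(log_cond_zmat(matrix(z, 1L), y_i, matrix(mu0 + xb, 1L), Sigmainv,
                     mu1, w1, sigma_e2, act))
}

grad_log_cond_z <- function(z, y_i, mu0, xb, Sigma, mu1, w1, sigma_e2,
                            act = make_activation("tanh")) {
  if (!all(is.finite(c(z, y_i, mu0, xb, Sigma, mu1, w1, sigma_e2))))
    stop("non-finite input to grad_log_cond_z")
  Sigma <- as.matrix(Sigma)
  Sigmainv <- chol2inv(chol(Sigma))
  drop(grad_log_cond_zmat(matrix(z, 1L), y_i, matrix(mu0 + xb, 1L), Sigmainv,
                          mu1, w1, sigma_e2, act))
}

# resolve an hmc_control into concrete matrices for l1 nodes
resolve_hmc <- function(cfg, l1) {
  M <- cfg$mass
  if (is.null(M)) M <- diag(1, l1)
  else if (is.vector(M) && !is.matrix(M)) {
    if (length(M) == 1L) M <- diag(M, l1) else M <- diag(M)
  }
  M <- as.matrix(M)
  if (nrow(M) != l1 || !isTRUE(all.equal(M, t(M))))
    stop("mass matrix must be symmetric ", l1, "x", l1)
  cholM <- chol(M)  # upper; M = t(cholM) %*% cholM
  list(L = cfg$L, epsilon = cfg$epsilon, M = M,
       Minv = chol2inv(cholM), cholM = cholM)
}

# L leapfrog steps for all rows at once; time-reversible by construction
leapfrog <- function(Z, P, L, eps, Minv, gradfun) {
  P <- P + 0.5 * eps * gradfun(Z)
  for (l in seq_len(L)) {
    Z <- Z + eps * P %*% Minv
    P <- P + (if (l < L) eps else 0.5 * eps) * gradfun(Z)
  }
  list(Z = Z, P = P)
}

# one HMC update of every row of Z; returns new Z, per-row acceptance and
# log acceptance ratios. Non-finite trajectories count as rejections.
hmc_sweep <- function(Z, y, Mu, Sigmainv, mu1, w1, sigma_e2, act, cfg) {
  n <- nrow(Z); l1 <- ncol(Z)
  Phi <- matrix(rnorm(n * l1), n, l1) %*% cfg$cholM
  gradfun <- function(Zc) grad_log_cond_zmat(Zc, y, Mu, Sigmainv, mu1, w1,
                                             sigma_e2, act)
  lp0 <- log_cond_zmat(Z, y, Mu, Sigmainv, mu1, w1, sigma_e2, act)
  k0 <- 0.5 * rowSums((Phi %*% cfg$Minv) * Phi)
  prop <- leapfrog(Z, Phi, cfg$L, cfg$epsilon, cfg$Minv, gradfun)
  lp1 <- log_cond_zmat(prop$Z, y, Mu, Sigmainv, mu1, w1, sigma_e2, act)
  k1 <- 0.5 * rowSums((prop$P %*% cfg$Minv) * prop$P)
  logr <- (lp1 - k1) - (lp0 - k0)
  bad <- !is.finite(logr)
  logr[bad] <- -Inf
  accept <- log(runif(n)) < logr   # min(1, r) via log u < log r
  Znew <- Z
  if (any(accept)) Znew[accept, ] <- prop$Z[accept, ]
  list(Z = Znew, accept = accept, logr = logr, n_nonfinite = sum(bad))
}

# single-individual HMC update (momentum refresh + L leapfrog steps +
# Metropolis accept); r is the acceptance ratio before capping at 1
hmc_update <- function(z, y_i, mu0, xb, Sigma, mu1, w1, sigma_e2,
                       cfg = hmc_control(), act = make_activation("tanh")) {
  l1 <- length(z)
  rc <- resolve_hmc(cfg, l1)
  Sigma <- as.matrix(Sigma)
  Sigmainv <- chol2inv(chol(Sigma))
  res <- hmc_sweep(matrix(z, 1L), y_i, matrix(mu0 + xb, 1L), Sigmainv,
                   mu1, w1, sigma_e2, act, rc)
  list(z = drop(res$Z), accepted = res$accept[1L], r = exp(res$logr[1L]))
}
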