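# Gibbs updates for the hidden -> output layer: intercept mu1 and weights w1
# under flat (or optionally proper normal) priors, and the residual variance
# under its scaled inverse chi-squared prior.

# (mu1, w1) ~ MVN(theta_hat, sigma_e2 (C'C)^-1) with C = [1, g(Z)], the
# standard flat-prior Gaussian linear-model conditional. A finite prior_var
# adds the corresponding normal prior (used where a proper joint is needed).
# Rank deficiency falls back to a 1e-8 ridge jitter with a warning.
sample_output_coeffs <- function(gZ, y, sigma_e2, prior_var = Inf) {
  C <- cbind(1, gZ)
  k <- ncol(C)
  CtC <- crossprod(C)
  if (is.finite(prior_var)) CtC <- CtC + diag(sigma_e2 / prior_var, k)
  Cty <- crossprod(C, y)
  ch <- tryCatch(chol(CtC), error = function(e) NULL)
  if (is.null(ch)) {
    warning("rank-deficient output design; adding ridge jitter")
    CtC <- CtC + diag(1e-8, k)
    ch <- chol(CtC)
  }
  theta_hat <- backsolve(ch, forwardsolve(t(ch), Cty))
  theta <- drop(theta_hat) + sqrt(sigma_e2) * drop(backsolve(ch, rnorm(k)))
  list(mu1 = theta[1L], w1 = theta[-1L])
}

# sigma_e2 | residuals ~ scaled-inv-chi2(nu_e + n, (nu_e S_e2 + e'e)/(nu_e + n))
sample_sigma_e <- function(residuals, nu_e, S_e2) {
  n <- length(residuals)
  (nu_e * S_e2 + sum(residuals^2)) / stats::rchisq(1L, nu_e + n)
}

# mu0 | rest, multi-trait: flat prior gives MVN(colMeans(Z - XW0), Sigma/n);
# a finite prior_var shrinks towards zero
sample_mu0_multitrait <- function(Rmu, Sigmainv, prior_var = Inf) {
  n <- nrow(Rmu); l1 <- ncol(Rmu)
  prec <- n * Sigmainv + diag(if (is.finite(prior_var)) 1 / prior_var else 0, l1)
  rhs <- Sigmainv %*% colSums(Rmu)
  ch <- chol(prec)
  m <- backsolve(ch, forwardsolve(t(ch), rhs))
  drop(m) + drop(backsolve(ch, rnorm(l1)))
}

# independent-node version with per-node residual variances
sample_mu0_independent <- function(Rmu, sigma_z2, prior_var = Inf) {
  n <- nrow(Rmu)
  pv <- if (is.finite(prior_var)) 1 / prior_var else 0
  vapply(seq_len(ncol(Rmu)), function(j) {
    prec <- n / sigma_z2[j] + pv
    m <- sum(Rmu[, j]) / sigma_z2[j] / prec
    m + rnorm(1L) / sqrt(prec)
  }, numeric(1L))
}
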