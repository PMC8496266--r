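# Bayesian Alphabet full-conditional updates for the input -> hidden layer.
# The O(n*p) marker sweeps live in src/sweeps.cpp; this file provides the R
# surface plus the variance / inclusion-probability updates.

family_code <- c("RR-BLUP" = 0L, "BayesA" = 1L, "BayesB" = 2L,
                 "BayesCpi" = 3L, "BayesL" = 4L)

# One Gibbs sweep over markers for a single node (or the linear model).
# resid must be the current residual with all marker effects subtracted;
# sweep order is marker index ascending with incremental residual updates.
update_marker_effects_independent <- function(resid, X, b, d, marker_vars,
                                              sigma2_node, pi, family) {
  fam <- family_code[[family]]
  p <- ncol(X)
  varm <- if (length(marker_vars) == 1L) rep(marker_vars, p) else marker_vars
  if (any(varm <= 0)) stop("marker-effect variances must be positive")
  if (any(colSums(X^2) == 0))
    stop("zero-variance marker column; drop monomorphic markers at load")
  out <- cpp_sweep_node(resid, X, b, as.integer(d), varm, sigma2_node, pi, fam)
  list(b = drop(out$b), d = as.integer(out$d), resid = drop(out$resid))
}

# Multi-trait sweep: configuration + effect-vector update per marker.
update_marker_effects_multitrait <- function(Resid, X, B, D, Ginv, Sigmainv,
                                             Pi, configs) {
  logPi <- log(Pi)
  logPi[Pi == 0] <- -Inf
  cpp_sweep_multitrait(Resid, X, B, storage.mode_int(D), Ginv, Sigmainv,
                       logPi, storage.mode_int(configs))
}

storage.mode_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

# pi ~ Beta(1 + #included, 1 + #excluded); multi-trait: Dirichlet over the
# 2^l1 inclusion configurations with counts from D's rows.
update_inclusion_probability <- function(D, mode = c("independent", "multi_trait"),
                                         configs = NULL) {
  mode <- match.arg(mode)
  if (mode == "independent") {
    d <- as.integer(D)
    if (!length(d)) stop("no markers: cannot update the inclusion probability")
    rbeta(1L, 1 + sum(d), 1 + sum(1L - d))
  } else {
    if (is.null(dim(D)) || !nrow(D)) stop("no markers: cannot update Pi")
    l1 <- ncol(D)
    idx <- as.integer(D %*% 2^(seq_len(l1) - 1)) + 1L
    counts <- tabulate(idx, nbins = nrow(configs))
    rdirichlet(1 + counts)
  }
}

# Sigma | residuals: inverse Wishart (multi-trait) or per-node scaled
# inverse chi-squared. Non-PD numerical draws are retried with jitter.
update_hidden_residual_cov <- function(E, nu_eps, S_eps,
                                       mode = c("multi_trait", "independent"),
                                       jitter = 1e-8) {
  mode <- match.arg(mode)
  n <- nrow(E)
  if (mode == "independent") {
    vapply(seq_len(ncol(E)), function(j) {
      Sj <- if (length(S_eps) == 1L) S_eps else S_eps[j]
      ss <- nu_eps * Sj + sum(E[, j]^2)
      rscinvchisq(1L, nu_eps + n, ss / (nu_eps + n))
    }, numeric(1L))
  } else {
    S <- S_eps + crossprod(E)
    nu <- nu_eps + n
    draw <- tryCatch(rinvwishart(nu, S), error = function(e) NULL)
    ok <- !is.null(draw) && all(is.finite(draw)) &&
      !inherits(tryCatch(chol(draw), error = function(e) e, warning = function(w) w),
                c("error", "warning"))
    if (!ok) {
      warning("non-positive-definite covariance draw; retrying with jitter")
      S <- S + diag(jitter * mean(diag(S)), nrow(S))
      draw <- rinvwishart(nu, S)
    }
    draw
  }
}

# per-family marker-effect variance updates after a sweep (single node)
update_marker_variances <- function(b, d, family, pr, lambda2 = NULL) {
  p <- length(b)
  switch(family,
    "RR-BLUP" = {
      v <- (pr$nu_marker * pr$S_marker + sum(b^2)) /
        stats::rchisq(1L, pr$nu_marker + p)
      list(varm = rep(v, p), common = v)
    },
    "BayesA" = {
      v <- (pr$nu_marker * pr$S_marker + b^2) /
        stats::rchisq(p, pr$nu_marker + 1)
      list(varm = v)
    },
    "BayesB" = {
      # excluded markers: conditional is the prior
      v <- (pr$nu_marker * pr$S_marker + b^2 * d) /
        stats::rchisq(p, pr$nu_marker + d)
      list(varm = v)
    },
    "BayesCpi" = {
      k <- sum(d)
      v <- (pr$nu_marker * pr$S_marker + sum(b[d == 1L]^2)) /
        stats::rchisq(1L, pr$nu_marker + k)
      list(varm = rep(v, p), common = v)
    },
    "BayesL" = {
      mu_ig <- sqrt(lambda2 / pmax(b^2, 1e-12))
      invtau2 <- rinvgauss(p, pmin(mu_ig, 1e8), lambda2)
      varm <- 1 / pmax(invtau2, 1e-12)
      lambda2 <- stats::rgamma(1L, shape = pr$lasso_shape + p,
                               rate = pr$lasso_rate + sum(varm) / 2)
      list(varm = varm, lambda2 = lambda2)
    },
    stop("unknown family: ", family))
}
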