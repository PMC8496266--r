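#' Bayesian Alphabet prior specification
#'
#' Collects the prior family for the marker effects and the variance
#' hyperparameters of the hidden-node regression. `pi` is, throughout this
#' package, the prior probability that a marker effect is NONZERO (the
#' inclusion probability); summaries report both `pi` and `1 - pi`.
#'
#' Scale hyperparameters left `NULL` are resolved at fit time from the
#' phenotypic (or hidden-node) variance assuming an a-priori 50/50 split
#' between genetic and residual variance, the common Bayesian Alphabet
#' practice.
#'
#' @param family one of `"BayesCpi"`, `"RR-BLUP"`, `"BayesA"`, `"BayesB"`,
#'   `"BayesL"`.
#' @param mode `"auto"` (multi-trait for RR-BLUP/BayesCpi with few nodes,
#'   otherwise per-node), `"multi_trait"`, or `"independent_nodes"`.
#' @param nu_e,S_e2 residual-variance scaled-inverse-chi-squared df and scale.
#' @param nu_marker,S_marker marker-effect-variance df and scale
#'   (per-node families).
#' @param nu_eps,S_eps hidden-node residual df and scale: inverse-Wishart
#'   (matrix scale) in multi-trait mode, per-node scaled-inverse-chi-squared
#'   otherwise.
#' @param nu_beta,S_beta inverse-Wishart df and scale matrix for the
#'   multi-trait marker-effect covariance.
#' @param pi_treatment `"sampled"` (Beta/Dirichlet update) or `"fixed"`.
#' @param pi_init initial (or fixed) inclusion probability.
#' @param lasso_shape,lasso_rate Gamma hyperprior on the Bayesian-LASSO rate
#'   parameter lambda^2; a `NULL` rate is resolved so the prior mean matches
#'   the marker-variance target.
#' @param max_multitrait_nodes hard cap on hidden nodes in multi-trait mode
#'   (the configuration sampler enumerates `2^l1` patterns).
#' @return An object of class `bayes_prior`.
#' @export
bayes_prior <- function(family = c("BayesCpi", "RR-BLUP", "BayesA", "BayesB",
                                   "BayesL"),
                        mode = c("auto", "multi_trait", "independent_nodes"),
                        nu_e = 4, S_e2 = NULL,
                        nu_marker = 4, S_marker = NULL,
                        nu_eps = NULL, S_eps = NULL,
                        nu_beta = NULL, S_beta = NULL,
                        pi_treatment = c("sampled", "fixed"), pi_init = 0.5,
                        lasso_shape = 0.1, lasso_rate = NULL,
                        max_multitrait_nodes = 10) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  pi_treatment <- match.arg(pi_treatment)
  if (nu_e <= 0 || nu_marker <= 0) stop("prior degrees of freedom must be > 0")
  if (pi_init < 0 || pi_init > 1) stop("pi_init must be in [0, 1]")
  if (mode == "multi_trait" && !family %in% c("RR-BLUP", "BayesCpi"))
    stop("multi-trait mode supports RR-BLUP and BayesCpi only; ",
         family, " runs per node in independent_nodes mode")
  structure(list(family = family, mode = mode,
                 nu_e = nu_e, S_e2 = S_e2,
                 nu_marker = nu_marker, S_marker = S_marker,
                 nu_eps = nu_eps, S_eps = S_eps,
                 nu_beta = nu_beta, S_beta = S_beta,
                 pi_treatment = pi_treatment, pi_init = pi_init,
                 lasso_shape = lasso_shape, lasso_rate = lasso_rate,
                 max_multitrait_nodes = max_multitrait_nodes),
            class = "bayes_prior")
}

#' Hamiltonian Monte Carlo settings for the hidden-node update
#'
#' @param L number of leapfrog steps (default 10).
#' @param epsilon leapfrog step size (default 0.1).
#' @param mass mass matrix: `NULL` for the identity, a vector for a diagonal
#'   mass, or a symmetric positive-definite matrix.
#' @return An object of class `hmc_control`.
#' @export
hmc_control <- function(L = 10, epsilon = 0.1, mass = NULL) {
  if (L < 1 || L != round(L)) stop("L must be a positive integer")
  if (epsilon < 0) stop("epsilon must be non-negative")
  structure(list(L = as.integer(L), epsilon = epsilon, mass = mass),
            class = "hmc_control")
}

#' Fitting-process controls
#'
#' @param fixed_output optional numeric `c(mu1, w1...)` freezing the output
#'   layer (used for structural checks such as collapsing the network onto a
#'   linear model).
#' @param fixed_sigma optional value freezing the hidden-node residual
#'   variance (per node; multi-trait mode uses `diag(fixed_sigma, l1)`).
#' @param mu_prior_var prior variance of the hidden-node means `mu0` (and the
#'   linear-model intercept). The default `NULL` resolves to 1 for the
#'   hidden-node means — weakly informative on the standardized latent
#'   scale, keeping the node locations inside the activation's dynamic range
#'   (beyond it the location is unidentified: a node drifting into tanh
#'   saturation costs the likelihood nothing but corrupts the window
#'   statistics of [wppa()]) — and to `Inf` (flat) for the linear-model
#'   intercept, which is fully identified. `Inf` restores flat priors
#'   everywhere.
#' @param coef_prior_var prior variance of the output-layer coefficients.
#'   The default `NULL` resolves to `25 * var(y)` at fit time — a
#'   weakly-informative prior that is essentially flat over the identified
#'   region but pins down the scale ridge that a saturating activation leaves
#'   unidentified (near-collinear hidden nodes otherwise let `|w1|` diverge).
#'   `Inf` gives the exact flat prior.
#' @param z_init_sd standard deviation of the symmetry-breaking noise added
#'   to the standardized phenotype when initialising the hidden nodes
#'   (default 1, so nodes start decorrelated).
#' @param store_data keep the training dosage matrix in the fit object
#'   (needed as the default reference set for [wppa()]).
#' @return An object of class `nnbayes_control`.
#' @export
nnbayes_control <- function(fixed_output = NULL, fixed_sigma = NULL,
                            mu_prior_var = NULL, coef_prior_var = NULL,
                            z_init_sd = 1, store_data = TRUE) {
  structure(list(fixed_output = fixed_output, fixed_sigma = fixed_sigma,
                 mu_prior_var = mu_prior_var, coef_prior_var = coef_prior_var,
                 z_init_sd = z_init_sd, store_data = store_data),
            class = "nnbayes_control")
}

# ---- distribution utilities ------------------------------------------------

# scaled inverse chi-squared: density of nu*scale/chisq_nu
rscinvchisq <- function(n, df, scale) df * scale / stats::rchisq(n, df)

# inverse Wishart with density |S|^{nu/2} |X|^{-(nu+d+1)/2} exp(-tr(S X^-1)/2);
# mean S / (nu - d - 1)
rinvwishart <- function(nu, S) {
  d <- nrow(S)
  if (nu <= d - 1) stop("inverse-Wishart df too small")
  W <- stats::rWishart(1L, df = nu, Sigma = solve(S))[, , 1L]
  solve(W)
}

# inverse Gaussian (Michael, Schucany & Haas)
rinvgauss <- function(n, mean, shape) {
  y <- stats::rnorm(n)^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

# all 2^l1 inclusion patterns, binary counting (row k: bits of k-1)
inclusion_configs <- function(l1) {
  K <- 2L^l1
  cfg <- matrix(0L, K, l1)
  for (j in seq_len(l1)) cfg[, j] <- (seq_len(K) - 1L) %/% 2L^(j - 1L) %% 2L
  cfg
}

# resolve NULL scale hyperparameters from the data at fit time
resolve_prior <- function(prior, l1, var_y, var_z, sum_var_x, linear = FALSE) {
  pr <- unclass(prior)
  pr$l1 <- l1
  mixture <- pr$family %in% c("BayesB", "BayesCpi")
  pi_expect <- if (mixture) max(pr$pi_init, 0.01) else 1
  base_var <- if (linear) var_y else var_z
  # per-included-marker effect-variance target: half the response variance
  vtar <- 0.5 * base_var / (pi_expect * sum_var_x)
  pr$vtar <- vtar
  if (is.null(pr$S_e2)) pr$S_e2 <- 0.5 * var_y * (pr$nu_e - 2) / pr$nu_e
  if (is.null(pr$S_marker))
    pr$S_marker <- vtar * (pr$nu_marker - 2) / pr$nu_marker
  if (!linear) {
    if (pr$mode == "multi_trait") {
      if (is.null(pr$nu_beta)) pr$nu_beta <- l1 + 4
      if (is.null(pr$S_beta))
        pr$S_beta <- diag(vtar * (pr$nu_beta - l1 - 1), l1)
      if (is.null(pr$nu_eps)) pr$nu_eps <- l1 + 4
      if (is.null(pr$S_eps))
        pr$S_eps <- diag(0.5 * var_z * (pr$nu_eps - l1 - 1), l1)
      if (is.matrix(pr$S_eps) && !isTRUE(all.equal(pr$S_eps, t(pr$S_eps))))
        stop("S_eps must be symmetric")
    } else {
      if (is.null(pr$nu_eps)) pr$nu_eps <- 4
      if (is.null(pr$S_eps))
        pr$S_eps <- 0.5 * var_z * (pr$nu_eps - 2) / pr$nu_eps
    }
  }
  if (pr$family == "BayesL") {
    pr$lambda2_init <- 2 / vtar
    if (is.null(pr$lasso_rate)) pr$lasso_rate <- pr$lasso_shape / pr$lambda2_init
  }
  pr
}
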