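# The outer Gibbs loop assembling the samplers into the full model, plus the
# linear Bayesian Alphabet baseline (n_hidden = 0). Update order per
# iteration: layer-1 unknowns given Z (which do not depend on the observed
# trait), then Z by HMC, then the output layer and residual variance.

# ---- state initialisation --------------------------------------------------

nn_init_state <- function(X, y, l1, family, prior, activation, hmc, control) {
  n <- nrow(X); p <- ncol(X)
  act <- make_activation(activation)
  var_y <- stats::var(y)
  if (var_y == 0) stop("phenotype has zero variance")
  mode <- prior$mode
  if (mode == "auto")
    mode <- if (family %in% c("RR-BLUP", "BayesCpi") && l1 <= 5)
      "multi_trait" else "independent_nodes"
  if (mode == "multi_trait" && l1 > prior$max_multitrait_nodes)
    stop("multi-trait mode enumerates 2^l1 configurations; use ",
         "independent_nodes mode for more than ",
         prior$max_multitrait_nodes, " hidden nodes")
  if (mode == "multi_trait" && !family %in% c("RR-BLUP", "BayesCpi"))
    stop(family, " runs per node; use independent_nodes mode")

  if (is.null(control$coef_prior_var))
    control$coef_prior_var <- 25 * var_y
  if (is.null(control$mu_prior_var))
    control$mu_prior_var <- 1    # hidden nodes live on the standardized scale
  zsd <- control$z_init_sd
  Z <- matrix(as.vector(scale(y)), n, l1) + matrix(rnorm(n * l1, 0, zsd), n, l1)
  svx <- sum(apply(X, 2L, stats::var))
  prior$mode <- mode
  pr <- resolve_prior(prior, l1, var_y, var_z = 1 + zsd^2, sum_var_x = svx)

  mixture <- family %in% c("BayesB", "BayesCpi")
  st <- list(X = X, y = y, n = n, p = p, l1 = l1, family = family,
             mode = mode, act = act, prior = pr, control = control,
             hmc = resolve_hmc(hmc, l1), xtx = colSums(X^2))
  st$mu0 <- colMeans(Z)
  st$Z <- Z
  st$B <- matrix(0, p, l1)
  st$D <- matrix(if (mixture) 0L else 1L, p, l1)
  st$W0 <- matrix(0, p, l1)
  if (mode == "multi_trait") {
    st$configs <- if (family == "RR-BLUP") matrix(1L, 1L, l1)
                  else inclusion_configs(l1)
    st$Pi <- if (family == "RR-BLUP") 1 else {
      pi1 <- pr$pi_init
      apply(st$configs, 1L, function(d) prod(ifelse(d == 1L, pi1, 1 - pi1)))
    }
    st$G <- diag(pr$vtar, l1)
    st$Ginv <- diag(1 / pr$vtar, l1)
  } else {
    st$Vm <- matrix(pr$vtar, p, l1)
    st$pi <- rep(pr$pi_init, l1)
    if (family == "BayesL") st$lambda2 <- rep(pr$lambda2_init, l1)
  }
  fixed_sigma <- control$fixed_sigma
  if (mode == "multi_trait") {
    st$Sigma <- if (!is.null(fixed_sigma)) diag(fixed_sigma, l1)
                else diag(0.5 * (1 + zsd^2), l1)
    st$Sigmainv <- chol2inv(chol(st$Sigma))
  } else {
    st$sigma_z2 <- rep(if (!is.null(fixed_sigma)) fixed_sigma
                       else 0.5 * (1 + zsd^2), l1)
    st$Sigmainv <- diag(1 / st$sigma_z2, l1)
  }
  if (!is.null(control$fixed_output)) {
    fo <- control$fixed_output
    if (length(fo) != l1 + 1L)
      stop("fixed_output must be c(mu1, w1) of length n_hidden + 1")
    st$mu1 <- fo[1L]; st$w1 <- fo[-1L]
  } else {
    st$mu1 <- mean(y); st$w1 <- rep(0.5, l1)
  }
  st$sigma_e2 <- var_y / 2
  st$accept <- NA_real_
  st
}

# ---- one full Gibbs scan ---------------------------------------------------

nn_gibbs_iter <- function(st) {
  pr <- st$prior
  ctl <- st$control
  n <- st$n; l1 <- st$l1
  # layer 1 given Z ------------------------------------------------------
  Rmu <- st$Z - st$X %*% st$W0
  st$mu0 <- if (st$mode == "multi_trait")
    sample_mu0_multitrait(Rmu, st$Sigmainv, ctl$mu_prior_var)
  else
    sample_mu0_independent(Rmu, st$sigma_z2, ctl$mu_prior_var)
  R <- Rmu - matrix(st$mu0, n, l1, byrow = TRUE)

  if (st$mode == "multi_trait") {
    out <- update_marker_effects_multitrait(R, st$X, st$B, st$D, st$Ginv,
                                            st$Sigmainv, st$Pi, st$configs)
    st$B <- out$B; st$D <- out$D; R <- out$resid
    st$W0 <- st$B * st$D
    st$G <- rinvwishart(pr$nu_beta + st$p, pr$S_beta + crossprod(st$B))
    st$Ginv <- chol2inv(chol(st$G))
    if (st$family == "BayesCpi" && pr$pi_treatment == "sampled")
      st$Pi <- update_inclusion_probability(st$D, "multi_trait", st$configs)
    if (is.null(ctl$fixed_sigma)) {
      st$Sigma <- update_hidden_residual_cov(R, pr$nu_eps, pr$S_eps,
                                             "multi_trait")
      st$Sigmainv <- chol2inv(chol(st$Sigma))
    }
  } else {
    for (j in seq_len(l1)) {
      out <- update_marker_effects_independent(R[, j], st$X, st$B[, j],
                                               st$D[, j], st$Vm[, j],
                                               st$sigma_z2[j], st$pi[j],
                                               st$family)
      st$B[, j] <- out$b; st$D[, j] <- out$d; R[, j] <- out$resid
      vu <- update_marker_variances(st$B[, j], st$D[, j], st$family, pr,
                                    lambda2 = st$lambda2[j])
      st$Vm[, j] <- vu$varm
      if (!is.null(vu$lambda2)) st$lambda2[j] <- vu$lambda2
      if (st$family %in% c("BayesB", "BayesCpi") &&
          pr$pi_treatment == "sampled")
        st$pi[j] <- update_inclusion_probability(st$D[, j], "independent")
    }
    st$W0 <- st$B * st$D
    if (is.null(ctl$fixed_sigma))
      st$sigma_z2 <- update_hidden_residual_cov(R, pr$nu_eps, pr$S_eps,
                                                "independent")
    st$Sigmainv <- diag(1 / st$sigma_z2, l1)
  }

  # hidden nodes by HMC --------------------------------------------------
  Mu <- matrix(st$mu0, n, l1, byrow = TRUE) + st$X %*% st$W0
  hz <- hmc_sweep(st$Z, st$y, Mu, st$Sigmainv, st$mu1, st$w1, st$sigma_e2,
                  st$act, st$hmc)
  st$Z <- hz$Z
  st$accept <- mean(hz$accept)

  # output layer ---------------------------------------------------------
  gZ <- st$act$g(st$Z)
  if (is.null(ctl$fixed_output)) {
    oc <- sample_output_coeffs(gZ, st$y, st$sigma_e2, ctl$coef_prior_var)
    st$mu1 <- oc$mu1; st$w1 <- oc$w1
  }
  e <- st$y - st$mu1 - drop(gZ %*% st$w1)
  st$sigma_e2 <- sample_sigma_e(e, pr$nu_e, pr$S_e2)
  st
}

# draw y from the model given the current state (Geweke-style checks)
nn_sim_y <- function(st) {
  st$mu1 + drop(st$act$g(st$Z) %*% st$w1) + rnorm(st$n, 0, sqrt(st$sigma_e2))
}

# ---- linear Bayesian Alphabet baseline ------------------------------------

lm_init_state <- function(X, y, family, prior, control) {
  n <- nrow(X); p <- ncol(X)
  var_y <- stats::var(y)
  if (var_y == 0) stop("phenotype has zero variance")
  svx <- sum(apply(X, 2L, stats::var))
  pr <- resolve_prior(prior, 1L, var_y, var_z = var_y, sum_var_x = svx,
                      linear = TRUE)
  mixture <- family %in% c("BayesB", "BayesCpi")
  st <- list(X = X, y = y, n = n, p = p, family = family, prior = pr,
             control = control)
  st$mu <- mean(y)
  st$b <- numeric(p)
  st$d <- rep(if (mixture) 0L else 1L, p)
  st$varm <- rep(pr$vtar, p)
  st$pi <- pr$pi_init
  if (family == "BayesL") st$lambda2 <- pr$lambda2_init
  st$sigma_e2 <- var_y / 2
  st$resid <- y - st$mu
  st
}

lm_gibbs_iter <- function(st) {
  pr <- st$prior
  rmu <- st$resid + st$mu
  pv <- st$control$mu_prior_var %||% Inf  # linear intercept: flat by default
  prec <- st$n / st$sigma_e2 + (if (is.finite(pv)) 1 / pv else 0)
  st$mu <- sum(rmu) / st$sigma_e2 / prec + rnorm(1L) / sqrt(prec)
  r <- rmu - st$mu
  out <- update_marker_effects_independent(r, st$X, st$b, st$d, st$varm,
                                           st$sigma_e2, st$pi, st$family)
  st$b <- out$b; st$d <- out$d; st$resid <- out$resid
  vu <- update_marker_variances(st$b, st$d, st$family, pr,
                                lambda2 = st$lambda2)
  st$varm <- vu$varm
  if (!is.null(vu$lambda2)) st$lambda2 <- vu$lambda2
  if (st$family %in% c("BayesB", "BayesCpi") && pr$pi_treatment == "sampled")
    st$pi <- update_inclusion_probability(st$d, "independent")
  st$sigma_e2 <- sample_sigma_e(st$resid, pr$nu_e, pr$S_e2)
  st
}

# ---- user-facing fit -------------------------------------------------------

#' Fit a Bayesian neural network (or linear Bayesian Alphabet) genomic model
#'
#' Markers are linearly connected to `n_hidden` latent intermediate traits
#' through a (multi-trait) Bayesian Alphabet regression, and the latent nodes
#' are non-linearly connected to the phenotype through an activation function
#' and a flat-prior output layer. Layer-1 unknowns are Gibbs-sampled from
#' their full conditionals, hidden nodes by Hamiltonian Monte Carlo, and the
#' output layer by its conjugate normal/scaled-inverse-chi-squared updates.
#' `n_hidden = 0` fits the plain single-trait Bayesian Alphabet linear model
#' with the same prior family.
#'
#' Genotype dosages are used raw (0/1/2) without centering or scaling.
#'
#' @param geno a [genotype_data] object or a plain dosage matrix.
#' @param y phenotypes: a numeric vector aligned with the rows of `geno`, or
#'   a data frame whose first two columns are individual id and value.
#' @param n_hidden number of hidden nodes `l1` (0 = linear model).
#' @param family marker-effect prior family, see [bayes_prior()].
#' @param prior a [bayes_prior()] specification.
#' @param activation `"tanh"` (default) or `"identity"`.
#' @param hmc an [hmc_control()] specification.
#' @param n_iter,burn_in,thin chain length, burn-in (default half the chain)
#'   and thinning interval; `floor((n_iter - burn_in)/thin)` records are kept.
#' @param seed optional integer seed; fixing it makes the chain fully
#'   reproducible.
#' @param verbose print progress (HMC acceptance, residual variance) every
#'   100 iterations.
#' @param control an [nnbayes_control()] specification.
#' @return An object of class `nnbayes` with elements `samples` (thinned
#'   post-burn-in records of `W0`, `D`, `mu0`, `w1`, `mu1`, `sigma_e2`, and
#'   `Sigma`/`sigma_z2`, `pi`), `accept_rate` (per-iteration mean HMC
#'   acceptance), chain metadata, and the training data (unless
#'   `store_data = FALSE`).
#' @seealso [predict.nnbayes()], [pip()], [wppa()], [prediction_accuracy()]
#' @export
nnbayes <- function(geno, y, n_hidden = 2, family = "BayesCpi",
                    prior = bayes_prior(family),
                    activation = c("tanh", "identity"),
                    hmc = hmc_control(), n_iter = 4000, burn_in = NULL,
                    thin = 1, seed = NULL, verbose = FALSE,
                    control = nnbayes_control()) {
  activation <- match.arg(activation)
  X <- as_dosage_matrix(geno)
  yv <- if (inherits(geno, "genotype_data")) align_trait(geno, y)
        else {
          yv0 <- as.numeric(if (is.data.frame(y)) y[[2L]] else y)
          if (length(yv0) != nrow(X)) stop("length of y does not match geno")
          if (any(!is.finite(yv0))) stop("phenotypes must be finite")
          yv0
        }
  family <- match.arg(family, names(family_code))
  if (missing(family) && !missing(prior)) family <- prior$family
  if (family != prior$family) {
    if (!missing(family) && !missing(prior))
      stop("family disagrees with prior$family")
    prior$family <- family
  }
  if (is.null(burn_in)) burn_in <- floor(n_iter / 2)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  if (any(apply(X, 2L, stats::var) == 0))
    stop("monomorphic marker(s) present; load genotypes with ",
         "drop_monomorphic = TRUE")
  if (!is.null(seed)) set.seed(seed)
  nsave <- floor((n_iter - burn_in) / thin)
  if (nsave < 1) stop("no samples would be saved; check n_iter/burn_in/thin")

  if (n_hidden == 0) {
    st <- lm_init_state(X, yv, family, prior, control)
    S <- list(W0 = array(0, c(st$p, 1L, nsave)),
              D = array(0L, c(st$p, 1L, nsave)),
              mu0 = matrix(0, nsave, 1L), w1 = matrix(1, nsave, 1L),
              mu1 = numeric(nsave), sigma_e2 = numeric(nsave),
              pi = matrix(NA_real_, nsave, 1L))
    k <- 0L
    for (it in seq_len(n_iter)) {
      st <- lm_gibbs_iter(st)
      if (!all(is.finite(c(st$sigma_e2, st$mu))))
        stop("divergent chain at iteration ", it)
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        k <- k + 1L
        S$W0[, 1L, k] <- st$b * st$d
        S$D[, 1L, k] <- st$d
        S$mu0[k, 1L] <- st$mu
        S$mu1[k] <- 0
        S$sigma_e2[k] <- st$sigma_e2
        S$pi[k, 1L] <- st$pi
      }
      if (verbose && it %% 100L == 0L)
        message(sprintf("iter %d  sigma_e2 %.4f", it, st$sigma_e2))
    }
    fit <- list(samples = S, n_saved = nsave, n_hidden = 0L,
                activation = "identity", family = family, mode = "linear",
                prior = st$prior, hmc = NULL,
                chain = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                             seed = seed),
                accept_rate = NULL,
                marker_ids = colnames(X), ids = rownames(X),
                call = match.call())
    if (control$store_data) { fit$X <- X; fit$y <- yv }
    class(fit) <- "nnbayes"
    return(fit)
  }

  l1 <- as.integer(n_hidden)
  st <- nn_init_state(X, yv, l1, family, prior, activation, hmc, control)
  npi <- if (st$mode == "multi_trait") length(st$Pi) else l1
  S <- list(W0 = array(0, c(st$p, l1, nsave)),
            D = array(0L, c(st$p, l1, nsave)),
            mu0 = matrix(0, nsave, l1), w1 = matrix(0, nsave, l1),
            mu1 = numeric(nsave), sigma_e2 = numeric(nsave),
            Sigma = array(0, c(l1, l1, nsave)),
            pi = matrix(NA_real_, nsave, npi))
  accept_rate <- numeric(n_iter)
  k <- 0L
  for (it in seq_len(n_iter)) {
    st <- nn_gibbs_iter(st)
    accept_rate[it] <- st$accept
    if (!all(is.finite(c(st$sigma_e2, st$mu1, st$w1, st$mu0))))
      stop("divergent chain at iteration ", it,
           " (sigma_e2 = ", format(st$sigma_e2), ")")
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      k <- k + 1L
      S$W0[, , k] <- st$W0
      S$D[, , k] <- st$D
      S$mu0[k, ] <- st$mu0
      S$w1[k, ] <- st$w1
      S$mu1[k] <- st$mu1
      S$sigma_e2[k] <- st$sigma_e2
      S$Sigma[, , k] <- if (st$mode == "multi_trait") st$Sigma
                        else diag(st$sigma_z2, l1)
      S$pi[k, ] <- if (st$mode == "multi_trait") st$Pi else st$pi
    }
    if (verbose && it %% 100L == 0L)
      message(sprintf("iter %d  accept %.2f  sigma_e2 %.4f", it,
                      mean(accept_rate[(it - 99L):it]), st$sigma_e2))
  }
  fit <- list(samples = S, n_saved = nsave, n_hidden = l1,
              activation = activation, family = family, mode = st$mode,
              prior = st$prior, hmc = st$hmc,
              chain = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                           seed = seed),
              accept_rate = accept_rate,
              marker_ids = colnames(X), ids = rownames(X),
              call = match.call())
  if (control$store_data) { fit$X <- X; fit$y <- yv }
  class(fit) <- "nnbayes"
  fit
}

# ---- methods ---------------------------------------------------------------

#' @export
print.nnbayes <- function(x, ...) {
  if (x$n_hidden == 0L) {
    cat("Linear Bayesian Alphabet model (", x$family, ")\n", sep = "")
  } else {
    cat("NN-Bayes: ", x$n_hidden, " hidden node(s), ", x$family,
        " prior (", x$mode, "), ", x$activation, " activation\n", sep = "")
  }
  cat("chain: ", x$chain$n_iter, " iterations, burn-in ", x$chain$burn_in,
      ", thin ", x$chain$thin, " (", x$n_saved, " records)\n", sep = "")
  if (!is.null(x$accept_rate))
    cat(sprintf("mean HMC acceptance: %.3f\n", mean(x$accept_rate)))
  cat(sprintf("posterior mean sigma_e2: %.4f\n", mean(x$samples$sigma_e2)))
  invisible(x)
}

#' Effective sample size of a scalar chain
#'
#' `n / (1 + 2 * sum(rho_k))` with the empirical autocorrelations summed up
#' to the first negative lag. A constant chain reports its full length.
#'
#' @param x numeric chain.
#' @return estimated effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 3L || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 1000L), plot = FALSE)$acf[-1L]
  neg <- which(ac < 0)[1L]
  if (!is.na(neg)) ac <- ac[seq_len(neg - 1L)]
  min(n, max(1, n / (1 + 2 * sum(ac))))
}

#' @export
summary.nnbayes <- function(object, ...) {
  S <- object$samples
  scalar_tab <- function(m) {
    data.frame(mean = colMeans(m), sd = apply(m, 2L, stats::sd),
               ess = apply(m, 2L, ess))
  }
  out <- list(
    model = list(family = object$family, n_hidden = object$n_hidden,
                 mode = object$mode, activation = object$activation),
    sigma_e2 = scalar_tab(cbind(sigma_e2 = S$sigma_e2)),
    output_layer = if (object$n_hidden > 0L)
      scalar_tab(cbind(mu1 = S$mu1,
                       structure(S$w1, dimnames = list(NULL,
                         paste0("w1_", seq_len(ncol(S$w1)))))))
      else NULL,
    pi = if (!anyNA(S$pi)) colMeans(S$pi) else NULL,
    accept_rate = if (!is.null(object$accept_rate))
      mean(object$accept_rate) else NULL,
    n_saved = object$n_saved)
  class(out) <- "summary.nnbayes"
  out
}

#' @export
print.summary.nnbayes <- function(x, ...) {
  cat("Model:", if (x$model$n_hidden == 0L) "linear" else
    paste0("NN (", x$model$n_hidden, " nodes, ", x$model$mode, ")"),
    "with", x$model$family, "prior\n")
  cat("Residual variance:\n"); print(x$sigma_e2)
  if (!is.null(x$output_layer)) { cat("Output layer:\n"); print(x$output_layer) }
  if (!is.null(x$pi)) {
    cat("Posterior mean inclusion probability (pi):",
        format(round(x$pi, 4)), "\n")
    cat("  (exclusion 1 - pi:", format(round(1 - x$pi, 4)), ")\n")
  }
  if (!is.null(x$accept_rate))
    cat(sprintf("Mean HMC acceptance: %.3f over %d records\n",
                x$accept_rate, x$n_saved))
  invisible(x)
}

#' @export
coef.nnbayes <- function(object, ...) {
  W <- apply(object$samples$W0, c(1L, 2L), mean)
  rownames(W) <- object$marker_ids
  colnames(W) <- paste0("node", seq_len(ncol(W)))
  W
}

#' @export
fitted.nnbayes <- function(object, ...) {
  if (is.null(object$X)) stop("fit was run with store_data = FALSE")
  drop(predict(object, object$X)) + mean(object$samples$mu1)
}

#' @export
residuals.nnbayes <- function(object, ...) {
  if (is.null(object$y)) stop("fit was run with store_data = FALSE")
  object$y - fitted(object)
}
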