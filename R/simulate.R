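#' Simulate SNP dosages on one synthetic chromosome
#'
#' Per marker, allele frequencies are drawn from `U(maf_low, maf_high)` and
#' dosages are the sum of two haplotypes. Linkage disequilibrium between
#' adjacent markers is induced by a first-order copying chain: each haplotype
#' allele is copied from the previous marker with probability `ld_rho`,
#' otherwise drawn fresh from its own frequency, so the adjacent-marker
#' correlation is approximately `ld_rho`. Markers are placed at regular
#' spacing so physical windows are well defined. Monomorphic columns are
#' redrawn so every marker is polymorphic.
#'
#' @param n,p number of individuals and markers.
#' @param maf_low,maf_high allele-frequency bounds, `0 < maf_low <= maf_high
#'   <= 0.5`.
#' @param ld_rho copying probability in `[0, 1)`; 0 gives independent markers.
#' @param bp_spacing distance between consecutive markers in base pairs
#'   (default 50 kb, about 20 markers per 1-Mb window).
#' @param chrom chromosome label.
#' @param seed optional integer seed.
#' @return A [genotype_data] object.
#' @export
sim_genotypes <- function(n, p, maf_low = 0.05, maf_high = 0.5, ld_rho = 0.6,
                          bp_spacing = 50000, chrom = "1", seed = NULL) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (n < 1 || p < 1) stop("n and p must be positive")
  if (!is.null(seed)) set.seed(seed)
  f <- runif(p, maf_low, maf_high)
  haplo <- function() {
    H <- matrix(0L, n, p)
    H[, 1L] <- rbinom(n, 1L, f[1L])
    if (p > 1L) for (m in 2:p) {
      copy <- runif(n) < ld_rho
      fresh <- rbinom(n, 1L, f[m])
      H[, m] <- ifelse(copy, H[, m - 1L], fresh)
    }
    H
  }
  X <- haplo() + haplo()
  for (j in which(apply(X, 2L, stats::var) == 0)) {
    repeat {
      xj <- rbinom(n, 2L, f[j])
      if (stats::var(xj) > 0) break
    }
    X[, j] <- xj
  }
  map <- data.frame(marker_id = sprintf("m%05d", seq_len(p)),
                    chrom = chrom,
                    pos_bp = (seq_len(p) - 1) * bp_spacing,
                    stringsAsFactors = FALSE)
  genotype_data(X, map, sprintf("ind%04d", seq_len(n)))
}

#' Simulate a trait with dominance and complementary epistasis
#'
#' A random `round(qtl_fraction * p)` of the markers are selected as QTL.
#' Additive effects are `a ~ N(0, 1)`; dominance factors `delta ~ N(dom_mean,
#' dom_sd^2)` give dominance effects `d = delta * |a|`, expressed at
#' heterozygotes. Epistatic factors `gamma ~ N(0, 1)` for every unordered QTL
#' pair give pairwise effects `gamma * |a_i a_j|`, expressed under
#' complementary gene action: only when both loci carry at least one
#' alternative allele (dosage >= 1). Genetic values and an orthogonalised
#' Gaussian residual are rescaled so that, in sample, the phenotypic variance
#' is exactly 1 and the broad-sense heritability is exactly `h2`.
#'
#' @param geno a [genotype_data] object.
#' @param qtl_fraction fraction of markers that are QTL (default 0.05).
#' @param h2 target broad-sense heritability in `(0, 1]` (default 0.5).
#' @param dom_mean,dom_sd dominance-factor distribution (defaults 1.2, 0.3).
#' @param epistasis `"complementary"` (default) or `"none"`.
#' @param seed optional integer seed.
#' @return list with `trait` (data frame `id`, `y`) and `truth`, an object of
#'   class `sim_truth` holding QTL indices, effects (`a`, `delta`, `d`, the
#'   pairwise epistatic effect matrix), the common scale factor applied to all
#'   genetic components, the scaled per-individual components `g_additive`,
#'   `g_dominance`, `g_epistatic`, `g_total`, and `realized_H2`.
#' @export
sim_trait <- function(geno, qtl_fraction = 0.05, h2 = 0.5,
                      dom_mean = 1.2, dom_sd = 0.3,
                      epistasis = c("complementary", "none"), seed = NULL) {
  epistasis <- match.arg(epistasis)
  X <- geno$X
  n <- nrow(X); p <- ncol(X)
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must be in (0, 1]")
  k <- round(qtl_fraction * p)
  if (k < 2) stop("qtl_fraction * p must give at least 2 QTL")
  if (n < 3) stop("need at least 3 individuals")
  if (!is.null(seed)) set.seed(seed)
  qtl <- sort(sample.int(p, k))
  a <- rnorm(k)
  delta <- rnorm(k, dom_mean, dom_sd)
  d <- delta * abs(a)
  gam <- matrix(0, k, k)
  Eps <- matrix(0, k, k)
  if (epistasis == "complementary") {
    ut <- upper.tri(gam)
    gam[ut] <- rnorm(sum(ut))
    A <- abs(outer(a, a))
    Eps[ut] <- gam[ut] * A[ut]
    Eps <- Eps + t(Eps)
  }
  Xq <- X[, qtl, drop = FALSE]
  Hq <- (Xq == 1) + 0
  Uq <- (Xq >= 1) + 0
  g_a <- unname(drop(Xq %*% a))
  g_d <- unname(drop(Hq %*% d))
  g_e <- unname(0.5 * rowSums((Uq %*% Eps) * Uq))
  g <- g_a + g_d + g_e
  vg <- stats::var(g)
  if (vg == 0) stop("degenerate genetic values; increase n or the QTL count")
  s <- sqrt(h2 / vg)
  g_a <- g_a * s; g_d <- g_d * s; g_e <- g_e * s; g <- g * s
  if (h2 < 1) {
    # residual orthogonalised against g in sample, so var(y) = 1 and
    # var(g)/var(y) = h2 hold exactly for every seed
    e0 <- rnorm(n)
    gc <- g - mean(g)
    e1 <- e0 - mean(e0) - (sum((e0 - mean(e0)) * gc) / sum(gc^2)) * gc
    e <- e1 * sqrt((1 - h2) / stats::var(e1))
  } else {
    e <- numeric(n)
  }
  y <- g + e
  truth <- structure(list(qtl_indices = qtl, a = a, delta = delta, d = d,
                          gamma = gam, epistatic = Eps, scale = s,
                          g_additive = g_a, g_dominance = g_d,
                          g_epistatic = g_e, g_total = g,
                          realized_H2 = stats::var(g) / stats::var(y),
                          h2 = h2),
                     class = "sim_truth")
  list(trait = data.frame(id = geno$ids, y = y, stringsAsFactors = FALSE),
       truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$qtl_indices), "QTL, realized H2 =",
      format(x$realized_H2, digits = 4), "\n")
  invisible(x)
}

#' True per-window variance-share labels
#'
#' For each genomic window, the true genetic contribution sums the additive
#' and dominance terms of the QTL inside the window plus the epistatic terms,
#' attributed half to each interacting QTL's window. A window is labelled
#' causal when the variance of its contribution exceeds a fraction `T` of the
#' total genetic variance.
#'
#' @param truth a `sim_truth` from [sim_trait()].
#' @param windows a `window_set` built from the same genotypes.
#' @param geno the [genotype_data] the trait was simulated from.
#' @param T variance-share threshold (default 0.01).
#' @return data frame: `window_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_markers`, `share`, `causal`.
#' @export
truth_window_labels <- function(truth, windows, geno, T = 0.01) {
  p <- ncol(geno$X)
  covered <- sort(unlist(windows$markers))
  if (!identical(covered, seq_len(p)) || max(truth$qtl_indices) > p)
    stop("windows were not derived from the same genotypes as the trait")
  Xq <- geno$X[, truth$qtl_indices, drop = FALSE]
  Hq <- (Xq == 1) + 0
  Uq <- (Xq >= 1) + 0
  s <- truth$scale
  UE <- Uq %*% truth$epistatic  # column i: sum_j eps_ij u_j
  vtot <- stats::var(truth$g_total)
  share <- vapply(windows$markers, function(idx) {
    qin <- which(truth$qtl_indices %in% idx)
    if (!length(qin)) return(0)
    cw <- drop(Xq[, qin, drop = FALSE] %*% (truth$a[qin] * s)) +
      drop(Hq[, qin, drop = FALSE] %*% (truth$d[qin] * s)) +
      0.5 * s * rowSums(Uq[, qin, drop = FALSE] * UE[, qin, drop = FALSE])
    stats::var(cw) / vtot
  }, numeric(1L))
  out <- windows$windows[, c("window_id", "chrom", "start_bp", "end_bp", "n_markers")]
  out$share <- share
  out$causal <- share > T
  out
}

#' Simulate a trait from the network's own generative model
#'
#' Draws a phenotype from the hidden-layer model itself: sparse marker effects
#' on `n_hidden` latent nodes confined to a few causal windows, Gaussian node
#' residuals, and a tanh output layer. Used for calibration studies where the
#' fitted model is correctly specified and the causal windows are known.
#'
#' @param geno a [genotype_data] object.
#' @param windows a `window_set` over `geno`.
#' @param n_hidden number of hidden nodes.
#' @param n_causal_windows number of windows carrying nonzero effects.
#' @param markers_per_window causal markers per causal window.
#' @param effect_sd standard deviation of the per-node marker effects.
#' @param sigma_z hidden-node residual standard deviation.
#' @param w1 output weights (default all 1).
#' @param mu0,mu1 hidden-node and output intercepts (default 0).
#' @param sigma_e output residual standard deviation.
#' @param seed optional integer seed.
#' @return list with `y`, `Z`, `W0`, `causal_windows` (window indices),
#'   `shares` (true per-window genetic-variance shares computed from the true
#'   parameters), and the parameters used.
#' @export
sim_nn_trait <- function(geno, windows, n_hidden = 2, n_causal_windows = 3,
                         markers_per_window = 5, effect_sd = 0.4,
                         sigma_z = 0.5, w1 = NULL, mu0 = NULL, mu1 = 0,
                         sigma_e = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- geno$X
  n <- nrow(X); p <- ncol(X); l1 <- n_hidden
  if (is.null(w1)) w1 <- rep(1, l1)
  if (is.null(mu0)) mu0 <- rep(0, l1)
  nw <- nrow(windows$windows)
  if (n_causal_windows > nw) stop("more causal windows than windows")
  cw <- sort(sample.int(nw, n_causal_windows))
  W0 <- matrix(0, p, l1)
  for (w in cw) {
    idx <- windows$markers[[w]]
    pick <- if (length(idx) <= markers_per_window) idx
            else sort(sample(idx, markers_per_window))
    W0[pick, ] <- matrix(rnorm(length(pick) * l1, 0, effect_sd),
                         length(pick), l1)
  }
  M0 <- matrix(mu0, n, l1, byrow = TRUE)
  Z <- M0 + X %*% W0 + matrix(rnorm(n * l1, 0, sigma_z), n, l1)
  y <- mu1 + drop(tanh(Z) %*% w1) + rnorm(n, 0, sigma_e)
  gfull <- drop(tanh(M0 + X %*% W0) %*% w1)
  shares <- vapply(windows$markers, function(idx) {
    gt <- drop(tanh(X[, idx, drop = FALSE] %*% W0[idx, , drop = FALSE]) %*% w1)
    stats::var(gt) / stats::var(gfull)
  }, numeric(1L))
  list(y = y, Z = Z, W0 = W0, causal_windows = cw, shares = shares,
       w1 = w1, mu0 = mu0, mu1 = mu1, sigma_z = sigma_z, sigma_e = sigma_e)
}
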