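# shared fixtures and small utilities for the test suite

toy_geno <- function(n = 60, p = 30, seed = 1, ...) {
  sim_genotypes(n, p, seed = seed, ...)
}

# Monte-Carlo standard error with autocorrelation-adjusted sample size
mcse <- function(x) stats::sd(x) / sqrt(ess(x))

# write a small csv genotype fixture + map; returns the two paths
write_csv_fixture <- function(dir, X, map, ids = paste0("i", seq_len(nrow(X)))) {
  gpath <- file.path(dir, "geno.csv")
  mpath <- file.path(dir, "map.csv")
  colnames(X) <- map$marker_id
  df <- data.frame(id = ids, X, check.names = FALSE)
  utils::write.csv(df, gpath, row.names = FALSE, quote = FALSE)
  utils::write.csv(map, mpath, row.names = FALSE, quote = FALSE)
  list(geno = gpath, map = mpath)
}

small_map <- function(p, chrom = "1", spacing = 1e5) {
  data.frame(marker_id = paste0("m", seq_len(p)), chrom = chrom,
             pos_bp = (seq_len(p) - 1) * spacing, stringsAsFactors = FALSE)
}

# minimal hand-built nnbayes object for testing the inference layer
fake_fit <- function(W0, mu0, w1, mu1, sigma_e2 = NULL, D = NULL,
                     activation = "tanh", family = "BayesCpi",
                     marker_ids = NULL, X = NULL) {
  nsave <- dim(W0)[3L]
  p <- dim(W0)[1L]; l1 <- dim(W0)[2L]
  if (is.null(D)) D <- array(as.integer(W0 != 0), dim(W0))
  if (is.null(sigma_e2)) sigma_e2 <- rep(1, nsave)
  structure(list(
    samples = list(W0 = W0, D = D, mu0 = mu0, w1 = w1, mu1 = mu1,
                   sigma_e2 = sigma_e2,
                   Sigma = array(diag(l1), c(l1, l1, nsave)),
                   pi = matrix(NA_real_, nsave, l1)),
    n_saved = nsave, n_hidden = l1, activation = activation,
    family = family, mode = "multi_trait",
    marker_ids = marker_ids, ids = NULL, X = X,
    chain = list(n_iter = nsave, burn_in = 0L, thin = 1L, seed = NULL)),
    class = "nnbayes")
}
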