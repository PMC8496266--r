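# Genomic prediction from posterior samples of genotypic values, and
# window-based GWAS statistics (per-marker PIP, per-window q_t and WPPA).

record_W0 <- function(fit, r) {
  matrix(fit$samples$W0[, , r], ncol = fit$n_hidden %||% 1L)
}

#' Predict genotypic values
#'
#' For each saved posterior record the genotypic value of individual `i` is
#' `g(mu0' + x_i' W0) w1` with the fit's activation — marker effects and
#' hidden-node means only, excluding the output intercept. The posterior mean
#' over records is the point prediction.
#'
#' @param object an [nnbayes] fit.
#' @param newdata a [genotype_data] or dosage matrix with the same markers
#'   (in the same order) as the training data.
#' @param type `"mean"` (posterior-mean vector) or `"samples"` (matrix,
#'   individuals x saved records).
#' @param ... unused.
#' @return numeric vector, or matrix for `type = "samples"`.
#' @export
predict.nnbayes <- function(object, newdata, type = c("mean", "samples"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) {
    if (is.null(object$X)) stop("no newdata and fit stored no training data")
    newdata <- object$X
  }
  X <- as_dosage_matrix(newdata)
  p <- dim(object$samples$W0)[1L]
  if (ncol(X) != p)
    stop("newdata has ", ncol(X), " markers but the fit used ", p)
  if (inherits(newdata, "genotype_data") && !is.null(object$marker_ids) &&
      !identical(newdata$map$marker_id, object$marker_ids))
    stop("marker ids of newdata do not match the fit")
  act <- make_activation(object$activation)
  S <- object$samples
  l1 <- max(object$n_hidden, 1L)
  m <- nrow(X)
  G <- matrix(0, m, object$n_saved)
  for (r in seq_len(object$n_saved)) {
    W0 <- matrix(S$W0[, , r], p, l1)
    H <- act$g(matrix(S$mu0[r, ], m, l1, byrow = TRUE) + X %*% W0)
    G[, r] <- H %*% S$w1[r, ]
  }
  rownames(G) <- rownames(X)
  if (type == "mean") rowMeans(G) else G
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted genotypic values and observed
#' phenotypes in a validation set.
#'
#' @param g_hat posterior-mean genotypic values.
#' @param y_val validation phenotypes.
#' @return correlation coefficient.
#' @export
prediction_accuracy <- function(g_hat, y_val) {
  if (length(g_hat) != length(y_val)) stop("length mismatch")
  if (length(g_hat) < 3L) stop("need at least 3 validation observations")
  if (any(!is.finite(g_hat)) || any(!is.finite(y_val)))
    stop("non-finite values")
  if (stats::var(g_hat) == 0 || stats::var(y_val) == 0)
    stop("zero variance: accuracy undefined")
  stats::cor(g_hat, y_val)
}

#' Per-marker posterior inclusion probabilities
#'
#' Fraction of saved records in which a marker's effect is nonzero on at
#' least one hidden node. Families without inclusion indicators (RR-BLUP,
#' BayesA, BayesL) include every marker in every record, so the PIP is 1 for
#' all markers and a caveat is issued.
#'
#' @param fit an [nnbayes] fit.
#' @return named numeric vector of PIPs in `[0, 1]`.
#' @export
pip <- function(fit) {
  p <- dim(fit$samples$D)[1L]
  if (!fit$family %in% c("BayesB", "BayesCpi")) {
    warning("family ", fit$family, " has no inclusion indicators; ",
            "PIP is 1 for all markers")
    out <- rep(1, p)
  } else {
    any_node <- apply(fit$samples$D, c(1L, 3L), max)  # p x nsave
    out <- rowMeans(any_node)
  }
  names(out) <- fit$marker_ids
  out
}

#' Window posterior probabilities of association
#'
#' For each saved record, the genotypic values attributed to window `t` are
#' `g(X_t W0_t) w1` — the window's markers only, without the hidden-node
#' means — and `q_t` is the ratio of their sample variance to that of the
#' full genotypic values over the reference individuals. `WPPA_t` is the
#' fraction of records with `q_t > T`; a window is flagged significant when
#' `WPPA_t > 0.95`. Records whose full genotypic values have zero variance
#' are skipped (count in attribute `"skipped_records"`). `q_t` can exceed 1
#' under nonlinearity and is not clamped.
#'
#' @param fit an [nnbayes] fit.
#' @param windows a `window_set` over the fit's markers.
#' @param X_ref reference dosage matrix for the variances (default: the
#'   training genotypes stored in the fit).
#' @param T genetic-variance-share threshold (default 0.01).
#' @return data frame: `window_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_markers`, `wppa`, `mean_qt`, `significant`; attribute
#'   `"skipped_records"`.
#' @export
wppa <- function(fit, windows, X_ref = NULL, T = 0.01) {
  if (T <= 0 || T >= 1) stop("T must be in (0, 1)")
  if (is.null(X_ref)) {
    if (is.null(fit$X)) stop("no X_ref and fit stored no training data")
    X_ref <- fit$X
  }
  X <- as_dosage_matrix(X_ref)
  p <- dim(fit$samples$W0)[1L]
  if (ncol(X) != p) stop("X_ref marker count does not match the fit")
  covered <- sort(unlist(windows$markers))
  if (!identical(covered, seq_len(p)))
    stop("windows do not partition the fit's markers")
  act <- make_activation(fit$activation)
  S <- fit$samples
  l1 <- max(fit$n_hidden, 1L)
  nw <- length(windows$markers)
  nsave <- fit$n_saved
  m <- nrow(X)
  qt <- matrix(NA_real_, nw, nsave)
  skipped <- 0L
  for (r in seq_len(nsave)) {
    W0 <- matrix(S$W0[, , r], p, l1)
    w1 <- S$w1[r, ]
    gfull <- drop(act$g(matrix(S$mu0[r, ], m, l1, byrow = TRUE) +
                          X %*% W0) %*% w1)
    vfull <- stats::var(gfull)
    if (vfull == 0) { skipped <- skipped + 1L; next }
    for (t in seq_len(nw)) {
      idx <- windows$markers[[t]]
      gt <- drop(act$g(X[, idx, drop = FALSE] %*%
                         W0[idx, , drop = FALSE]) %*% w1)
      qt[t, r] <- stats::var(gt) / vfull
    }
  }
  if (skipped == nsave) stop("all records had zero genetic variance")
  keep <- !is.na(qt[1L, ])
  out <- windows$windows[, c("window_id", "chrom", "start_bp", "end_bp",
                             "n_markers")]
  out$wppa <- rowMeans(qt[, keep, drop = FALSE] > T)
  out$mean_qt <- rowMeans(qt[, keep, drop = FALSE])
  out$significant <- out$wppa > 0.95
  attr(out, "skipped_records") <- skipped
  attr(out, "T") <- T
  out
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counted one half.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param truth logical (or 0/1) labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0L || nn == 0L)
    stop("need at least one positive and one negative label")
  r <- rank(scores)  # average ranks give ties weight 1/2
  (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
}
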