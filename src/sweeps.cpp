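// Gibbs sweeps over marker effects.  These are the O(n*p) inner loops of the
// sampler; everything else lives in R.  R's RNG is used throughout so chains
// are reproducible from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// family codes: 0 RR-BLUP, 1 BayesA, 2 BayesB, 3 BayesCpi, 4 BayesL
// Mixture families (BayesB/BayesCpi) sample the inclusion indicator with the
// effect integrated out, then the effect from its conditional normal; excluded
// markers carry effect 0.  Non-mixture families always include.

// [[Rcpp::export]]
List cpp_sweep_node(const arma::vec& resid0, const arma::mat& X,
                    const arma::vec& b0, const arma::ivec& d0,
                    const arma::vec& varm, double sigma2_node,
                    double pi, int family) {
  arma::vec r = resid0;
  arma::vec b = b0;
  arma::ivec d = d0;
  const arma::uword p = X.n_cols;
  const bool mixture = (family == 2 || family == 3);
  const double logpi = std::log(pi), log1mpi = std::log1p(-pi);

  for (arma::uword m = 0; m < p; ++m) {
    const arma::vec& x = X.unsafe_col(m);
    const double xtx = arma::dot(x, x);
    const double wold = mixture ? (d[m] ? b[m] : 0.0) : b[m];
    const double rhs = arma::dot(x, r) + xtx * wold;
    const double v = varm[m];
    const double prec = xtx / sigma2_node + 1.0 / v;
    const double mean = rhs / sigma2_node / prec;
    double wnew;
    if (mixture) {
      // log posterior odds of inclusion, effect integrated out
      const double logodds =
          logpi - log1mpi - 0.5 * std::log(v * prec) + 0.5 * mean * mean * prec;
      double pincl;
      if (logodds > 35.0) pincl = 1.0;
      else if (logodds < -35.0) pincl = 0.0;
      else pincl = 1.0 / (1.0 + std::exp(-logodds));
      if (unif_rand() < pincl) {
        d[m] = 1;
        b[m] = mean + norm_rand() / std::sqrt(prec);
        wnew = b[m];
      } else {
        d[m] = 0;
        b[m] = 0.0;
        wnew = 0.0;
      }
    } else {
      d[m] = 1;
      b[m] = mean + norm_rand() / std::sqrt(prec);
      wnew = b[m];
    }
    const double delta = wnew - wold;
    if (delta != 0.0) r -= delta * x;
  }
  return List::create(_["b"] = b, _["d"] = d, _["resid"] = r);
}

// Multi-trait sweep: per marker, sample the inclusion configuration (rows of
// `configs`, entries 0/1) from its categorical full conditional with beta_m
// integrated out, then the full beta_m vector from its MVN full conditional.
// R is the n x l1 residual matrix Z - mu0 - X W0 (current effects removed).
// Small-matrix algebra (l1 <= 10) is hand-rolled on preallocated buffers.

// lower-triangular Cholesky of A (d x d) into L; returns false if not PD
static bool chol_lower(const double* A, double* L, int d) {
  for (int j = 0; j < d; ++j) {
    double s = A[j + j * d];
    for (int k = 0; k < j; ++k) s -= L[j + k * d] * L[j + k * d];
    if (s <= 0.0) return false;
    const double ljj = std::sqrt(s);
    L[j + j * d] = ljj;
    for (int i = j + 1; i < d; ++i) {
      double t = A[i + j * d];
      for (int k = 0; k < j; ++k) t -= L[i + k * d] * L[j + k * d];
      L[i + j * d] = t / ljj;
    }
    for (int i = 0; i < j; ++i) L[i + j * d] = 0.0;
  }
  return true;
}

static void fwd_solve(const double* L, const double* b, double* u, int d) {
  for (int i = 0; i < d; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i + k * d] * u[k];
    u[i] = s / L[i + i * d];
  }
}

static void bwd_solve(const double* L, const double* b, double* u, int d) {
  for (int i = d - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < d; ++k) s -= L[k + i * d] * u[k];
    u[i] = s / L[i + i * d];
  }
}

// [[Rcpp::export]]
List cpp_sweep_multitrait(const arma::mat& R0, const arma::mat& X,
                          const arma::mat& B0, const arma::imat& D0,
                          const arma::mat& Ginv, const arma::mat& Sigmainv,
                          const arma::vec& logPi, const arma::imat& configs) {
  arma::mat R = R0;
  arma::mat B = B0;
  arma::imat D = D0;
  const int n = R.n_rows;
  const arma::uword p = X.n_cols;
  const int l1 = R.n_cols;
  const arma::uword K = configs.n_rows;
  const int d2 = l1 * l1;

  // per-config masked Sigmainv (Sigmainv with excluded rows/cols zeroed)
  std::vector<std::vector<double> > SigK(K, std::vector<double>(d2));
  for (arma::uword k = 0; k < K; ++k)
    for (int j = 0; j < l1; ++j)
      for (int i = 0; i < l1; ++i)
        SigK[k][i + j * l1] =
            (configs(k, i) && configs(k, j)) ? Sigmainv(i, j) : 0.0;

  std::vector<double> P(d2), L(d2), bv(l1), u(l1), mu(l1), zv(l1),
      beta(l1), wold(l1), v(l1), sv(l1), logpost(K), pr(K);

  for (arma::uword m = 0; m < p; ++m) {
    const double* x = X.colptr(m);
    double xtx = 0.0;
    for (int i = 0; i < n; ++i) xtx += x[i] * x[i];
    for (int j = 0; j < l1; ++j)
      wold[j] = D(m, j) ? B(m, j) : 0.0;
    // v = R' x + xtx * wold, column by column (no transpose copy)
    for (int j = 0; j < l1; ++j) {
      const double* rc = R.colptr(j);
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += rc[i] * x[i];
      v[j] = s + xtx * wold[j];
    }
    for (int i = 0; i < l1; ++i) {
      double s = 0.0;
      for (int j = 0; j < l1; ++j) s += Sigmainv(i, j) * v[j];
      sv[i] = s;
    }
    double mx = -INFINITY;
    for (arma::uword k = 0; k < K; ++k) {
      const double* Sk = SigK[k].data();
      for (int t = 0; t < d2; ++t) P[t] = Ginv[t] + xtx * Sk[t];
      if (!chol_lower(P.data(), L.data(), l1)) { logpost[k] = -INFINITY; continue; }
      double ldet = 0.0, quad = 0.0;
      for (int j = 0; j < l1; ++j) {
        ldet += std::log(L[j + j * l1]);
        bv[j] = configs(k, j) ? sv[j] : 0.0;
      }
      fwd_solve(L.data(), bv.data(), u.data(), l1);
      for (int j = 0; j < l1; ++j) quad += u[j] * u[j];
      logpost[k] = logPi[k] - ldet + 0.5 * quad;
      if (logpost[k] > mx) mx = logpost[k];
    }
    double tot = 0.0;
    for (arma::uword k = 0; k < K; ++k) {
      pr[k] = std::exp(logpost[k] - mx);
      tot += pr[k];
    }
    const double u01 = unif_rand() * tot;
    arma::uword k = 0;
    double csum = pr[0];
    while (u01 > csum && k + 1 < K) { ++k; csum += pr[k]; }

    // beta | config ~ N(P^-1 bv, P^-1), P = Ginv + xtx * SigK[k]
    {
      const double* Sk = SigK[k].data();
      for (int t = 0; t < d2; ++t) P[t] = Ginv[t] + xtx * Sk[t];
      chol_lower(P.data(), L.data(), l1);
      for (int j = 0; j < l1; ++j) bv[j] = configs(k, j) ? sv[j] : 0.0;
      fwd_solve(L.data(), bv.data(), u.data(), l1);
      bwd_solve(L.data(), u.data(), mu.data(), l1);
      for (int j = 0; j < l1; ++j) zv[j] = norm_rand();
      bwd_solve(L.data(), zv.data(), beta.data(), l1);
      for (int j = 0; j < l1; ++j) beta[j] += mu[j];
    }
    bool changed = false;
    for (int j = 0; j < l1; ++j) {
      B(m, j) = beta[j];
      D(m, j) = configs(k, j);
      const double wnew = configs(k, j) ? beta[j] : 0.0;
      const double dw = wnew - wold[j];
      if (dw != 0.0) {
        changed = true;
        double* rc = R.colptr(j);
        for (int i = 0; i < n; ++i) rc[i] -= dw * x[i];
      }
    }
    (void)changed;
  }
  return List::create(_["B"] = B, _["D"] = D, _["resid"] = R);
}
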