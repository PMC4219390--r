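// Likelihood kernels for the joint longitudinal-survival model.
//
// The joint log-likelihood integrates the shared random effects out of
//   prod_j N(y_ij; W_i(t_ij), sigma_e^2) * h_i(T_i)^d_i * exp(-H_i(T_i)) * MVN(b; 0, Sigma)
// by (adaptive) Gauss-Hermite quadrature. Under the intercept association the
// cumulative hazard is available in closed form (H_i = H_0(T) e^{phi'v +
// alpha(beta_0 + b_0)}); under the current-value association the inner
// integral over [0, T] uses fixed Gauss-Legendre nodes whose design rows are
// precomputed in R. The node loop is the hot path (subjects x nodes x
// optimiser evaluations), so it is written allocation-free.

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);
static const double INVALID_LL = -1e10;

static inline double guarded_exp(double x) {
  return std::exp(std::min(x, 700.0));
}

// profiled (GLS) marginal log-likelihood of the linear mixed model
// [[Rcpp::export]]
Rcpp::List cpp_lmm_profile(const arma::vec& y, const arma::mat& X,
                           const arma::mat& Z, const arma::ivec& starts,
                           const arma::ivec& lens, double sigma_e,
                           const arma::mat& L) {
  const uword n = starts.n_elem, p = X.n_cols;
  const double sig2 = sigma_e * sigma_e;
  mat Sigma = symmatl(L * L.t());
  mat A(p, p, fill::zeros);
  vec c(p, fill::zeros);
  double logdet_sum = 0.0;
  std::vector<mat> Vinv_store(n);
  for (uword i = 0; i < n; ++i) {
    uword s = starts(i), k = lens(i);
    mat Zi = Z.rows(s, s + k - 1);
    mat Vi = Zi * Sigma * Zi.t();
    Vi.diag() += sig2;
    mat Vinv;
    if (!inv_sympd(Vinv, Vi)) Rcpp::stop("subject covariance not positive definite");
    double ld, sign;
    log_det(ld, sign, Vi);
    logdet_sum += ld;
    mat Xi = X.rows(s, s + k - 1);
    vec yi = y.subvec(s, s + k - 1);
    A += Xi.t() * Vinv * Xi;
    c += Xi.t() * Vinv * yi;
    Vinv_store[i] = std::move(Vinv);
  }
  vec beta = solve(A, c, solve_opts::likely_sympd);
  double quad = 0.0;
  for (uword i = 0; i < n; ++i) {
    uword s = starts(i), k = lens(i);
    vec r = y.subvec(s, s + k - 1) - X.rows(s, s + k - 1) * beta;
    quad += as_scalar(r.t() * Vinv_store[i] * r);
  }
  double ll = -0.5 * (static_cast<double>(y.n_elem) * LOG2PI + logdet_sum + quad);
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("vcov_beta") = inv_sympd(symmatl(A)));
}

// small-dimension positive-definite solve: analytic for q = 1, 2
static inline bool solve_small(const mat& A, const vec& rhs, vec& out) {
  const uword q = A.n_rows;
  if (q == 1) {
    if (A(0, 0) <= 0) return false;
    out(0) = rhs(0) / A(0, 0);
    return true;
  }
  if (q == 2) {
    double det = A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0);
    if (det <= 0 || A(0, 0) <= 0) return false;
    out(0) = (A(1, 1) * rhs(0) - A(0, 1) * rhs(1)) / det;
    out(1) = (A(0, 0) * rhs(1) - A(1, 0) * rhs(0)) / det;
    return true;
  }
  return solve(out, A, rhs, solve_opts::likely_sympd);
}

// lower Cholesky factor of the inverse of a small PD matrix
static inline bool chol_inv_small(const mat& A, mat& C) {
  const uword q = A.n_rows;
  if (q == 1) {
    if (A(0, 0) <= 0) return false;
    C(0, 0) = 1.0 / std::sqrt(A(0, 0));
    return true;
  }
  if (q == 2) {
    double det = A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0);
    if (det <= 0 || A(1, 1) <= 0) return false;
    // inv(A) = [a11 -a01; -a01 a00]/det; Cholesky of that analytically
    double i00 = A(1, 1) / det, i01 = -A(0, 1) / det, i11 = A(0, 0) / det;
    double c00 = std::sqrt(i00);
    double c10 = i01 / c00;
    double arg = i11 - c10 * c10;
    if (arg <= 0) return false;
    C(0, 0) = c00; C(0, 1) = 0.0; C(1, 0) = c10; C(1, 1) = std::sqrt(arg);
    return true;
  }
  mat P;
  if (!inv_sympd(P, symmatl(A))) return false;
  return chol(C, symmatl(P), "lower");
}

// expand a one-dimensional Gauss-Hermite rule to a q-dimensional product grid
static void gh_grid(const vec& ghx, const vec& ghw, uword q, mat& nodes, vec& lw) {
  const uword G = ghx.n_elem;
  uword total = 1;
  for (uword j = 0; j < q; ++j) total *= G;
  nodes.set_size(q, total);
  lw.set_size(total);
  for (uword k = 0; k < total; ++k) {
    uword rem = k;
    double l = 0.0;
    for (uword j = 0; j < q; ++j) {
      uword idx = rem % G;
      rem /= G;
      nodes(j, k) = ghx(idx);
      l += std::log(ghw(idx)) + ghx(idx) * ghx(idx);
    }
    lw(k) = l;
  }
}

// [[Rcpp::export]]
double cpp_joint_loglik(const arma::vec& y, const arma::mat& X,
                        const arma::mat& Z, const arma::ivec& starts,
                        const arma::ivec& lens, const arma::vec& Tobs,
                        const arma::vec& d, const arma::mat& Vc,
                        const arma::mat& BT, const arma::mat& BpT,
                        int assoc, const arma::mat& XT, const arma::mat& ZT,
                        const arma::mat& XG, const arma::mat& ZG,
                        const arma::mat& BG, const arma::mat& BpG,
                        const arma::vec& glx, const arma::vec& glw,
                        const arma::vec& beta, double log_sigma_e,
                        const arma::mat& L, const arma::vec& gamma,
                        const arma::vec& phi, double alpha,
                        const arma::vec& ghx, const arma::vec& ghw,
                        bool adaptive) {
  const uword n = starts.n_elem;
  const uword q = Z.n_cols;
  if (q > 16) Rcpp::stop("random-effect dimension above 16 is not supported");
  const double sig2 = std::exp(2.0 * log_sigma_e);
  const uword m = (assoc == 1) ? glx.n_elem : 0;

  if (sig2 < 1e-16 || !std::isfinite(sig2)) return INVALID_LL;
  if (L.diag().min() < 1e-8 || L.diag().max() > 1e8) return INVALID_LL;
  mat Sigma = symmatl(L * L.t());
  mat Sinv;
  if (!inv_sympd(Sinv, Sigma)) return INVALID_LL;
  Sinv = symmatl(Sinv);
  double logdetSigma = 2.0 * sum(log(L.diag()));
  const double prior_const = -0.5 * logdetSigma - 0.5 * q * LOG2PI;

  mat nodes;
  vec lw;
  gh_grid(ghx, ghw, q, nodes, lw);
  const uword nnode = lw.n_elem;

  vec resid = y - X * beta;
  vec vphi = (Vc.n_cols > 0) ? vec(Vc * phi) : vec(n, fill::zeros);
  vec sT = BT * gamma;    // log H0(T)
  vec spT = BpT * gamma;  // d log H0 / d log t at T
  vec sG, spG, xgb;
  if (assoc == 1) {
    sG = BG * gamma;
    spG = BpG * gamma;
    xgb = XG * beta;
  }

  // workspace reused across subjects
  vec lvec(q), b(q), bn(q), grad(q), mu(q), work(q);
  mat Q(q, q), negH(q, q), Cq(q, q), P(q, q);
  vec wnode(std::max<uword>(m, 1));
  vec terms(nnode);
  const double sqrt2 = std::sqrt(2.0);

  double total = 0.0;

  for (uword i = 0; i < n; ++i) {
    const uword s = starts(i), k = lens(i);
    const double di = d(i);
    double* rp = resid.memptr() + s;

    // longitudinal sufficient statistics
    double rr = 0.0;
    for (uword j = 0; j < k; ++j) rr += rp[j] * rp[j];
    lvec.zeros();
    Q = Sinv;
    for (uword j = 0; j < k; ++j) {
      const uword row = s + j;
      for (uword a = 0; a < q; ++a) {
        lvec(a) += Z(row, a) * rp[j];
        for (uword c2 = a; c2 < q; ++c2) Q(a, c2) += Z(row, a) * Z(row, c2) / sig2;
      }
    }
    for (uword a = 0; a < q; ++a)
      for (uword c2 = 0; c2 < a; ++c2) Q(a, c2) = Q(c2, a);
    lvec /= sig2;

    // survival pieces not involving b
    double c0 = -0.5 * k * std::log(2.0 * M_PI * sig2) - 0.5 * rr / sig2 +
      prior_const;
    double cH = 0.0;
    const double logT = std::log(Tobs(i));
    if (assoc == 0) {
      if (di > 0 && spT(i) <= 0) return INVALID_LL;
      double lin = sT(i) + vphi(i) + alpha * beta(0);
      cH = guarded_exp(lin);
      if (di > 0) {
        c0 += sT(i) + std::log(spT(i)) - logT + vphi(i) + alpha * beta(0);
        lvec(0) += alpha;
      }
    } else {
      for (uword j = 0; j < m; ++j) {
        double sp = spG(i * m + j);
        if (sp <= 0) return INVALID_LL;
        double t_ij = Tobs(i) * glx(j);
        double logh0 = sG(i * m + j) + std::log(sp) - std::log(t_ij);
        wnode(j) = Tobs(i) * glw(j) *
          guarded_exp(logh0 + vphi(i) + alpha * xgb(i * m + j));
      }
      if (di > 0) {
        if (spT(i) <= 0) return INVALID_LL;
        double xtb = 0.0;
        for (uword a = 0; a < X.n_cols; ++a) xtb += XT(i, a) * beta(a);
        c0 += sT(i) + std::log(spT(i)) - logT + vphi(i) + alpha * xtb;
        for (uword a = 0; a < q; ++a) lvec(a) += alpha * ZT(i, a);
      }
    }

    // log integrand: g(b) = c0 + l'b - 0.5 b'Qb - hazard terms
    auto gfun = [&](const double* bb) -> double {
      double lin = 0.0, qf = 0.0;
      for (uword a = 0; a < q; ++a) {
        lin += lvec(a) * bb[a];
        qf += Q(a, a) * bb[a] * bb[a];
        for (uword c2 = a + 1; c2 < q; ++c2) qf += 2.0 * Q(a, c2) * bb[a] * bb[c2];
      }
      double g = c0 + lin - 0.5 * qf;
      if (assoc == 0) {
        g -= cH * guarded_exp(alpha * bb[0]);
      } else {
        for (uword j = 0; j < m; ++j) {
          double zb = 0.0;
          for (uword a = 0; a < q; ++a) zb += ZG(i * m + j, a) * bb[a];
          g -= wnode(j) * guarded_exp(alpha * zb);
        }
      }
      return g;
    };

    mu.zeros();
    if (adaptive) {
      // Newton to the mode of the log-concave integrand, warm-started at the
      // longitudinal-only empirical-Bayes mean
      if (!solve_small(Q, lvec, b)) return INVALID_LL;
      double gb = gfun(b.memptr());
      for (int iter = 0; iter < 50; ++iter) {
        grad = lvec - Q * b;
        negH = Q;
        if (assoc == 0) {
          double He = cH * guarded_exp(alpha * b(0));
          grad(0) -= alpha * He;
          negH(0, 0) += alpha * alpha * He;
        } else {
          for (uword j = 0; j < m; ++j) {
            double zb = 0.0;
            for (uword a = 0; a < q; ++a) zb += ZG(i * m + j, a) * b(a);
            double He = wnode(j) * guarded_exp(alpha * zb);
            for (uword a = 0; a < q; ++a) {
              grad(a) -= alpha * He * ZG(i * m + j, a);
              for (uword c2 = a; c2 < q; ++c2)
                negH(a, c2) += alpha * alpha * He * ZG(i * m + j, a) * ZG(i * m + j, c2);
            }
          }
          for (uword a = 0; a < q; ++a)
            for (uword c2 = 0; c2 < a; ++c2) negH(a, c2) = negH(c2, a);
        }
        if (norm(grad, 2) < 1e-8) break;
        if (!solve_small(negH, grad, work)) return INVALID_LL;
        double t = 1.0;
        int halved = 0;
        double gnew;
        for (;;) {
          bn = b + t * work;
          gnew = gfun(bn.memptr());
          if (gnew >= gb || halved >= 30) break;
          t *= 0.5;
          ++halved;
        }
        if (gnew < gb) break; // no ascent possible: accept current point
        b = bn;
        gb = gnew;
      }
      mu = b;
      if (!chol_inv_small(negH, Cq)) return INVALID_LL;
    } else {
      Cq = L; // prior-scaled rule centred at zero
    }

    // log-sum-exp over the rescaled product rule
    double mx = -datum::inf;
    for (uword kk = 0; kk < nnode; ++kk) {
      double bb[16];
      for (uword a = 0; a < q; ++a) {
        double acc = mu(a);
        for (uword c2 = 0; c2 <= a; ++c2) acc += sqrt2 * Cq(a, c2) * nodes(c2, kk);
        bb[a] = acc;
      }
      terms(kk) = lw(kk) + gfun(bb);
      if (terms(kk) > mx) mx = terms(kk);
    }
    if (!std::isfinite(mx)) return INVALID_LL;
    double sumex = 0.0;
    for (uword kk = 0; kk < nnode; ++kk) sumex += std::exp(terms(kk) - mx);
    double ldet = 0.0;
    for (uword a = 0; a < q; ++a) ldet += std::log(Cq(a, a));
    total += 0.5 * q * std::log(2.0) + ldet + mx + std::log(sumex);
  }
  if (!std::isfinite(total)) return INVALID_LL;
  return total;
}
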