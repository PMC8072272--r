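// GY94 pruning likelihood on the fixed unrooted 4-taxon tree
// ((A,B),(C,D)). The 61-state generator is reversible, so P(t) comes from
// the spectral decomposition of the pi-symmetrized matrix. Decomposition
// and per-branch likelihood are split so the optimizer can cache
// decompositions across evaluations that only move branch lengths.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat build_q(const imat& ptype, const vec& pi, double kappa,
                   double omega, bool scale) {
  const uword n = 61;
  mat Q(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < n; ++j) {
      switch (ptype(i, j)) {
        case 1: Q(i, j) = pi(j); break;                  // syn transversion
        case 2: Q(i, j) = kappa * pi(j); break;          // syn transition
        case 3: Q(i, j) = omega * pi(j); break;          // nonsyn transversion
        case 4: Q(i, j) = kappa * omega * pi(j); break;  // nonsyn transition
        default: break;
      }
    }
    Q(i, i) = -accu(Q.row(i));
  }
  if (scale) {
    double mu = -dot(pi, Q.diag());
    if (mu > 0) Q /= mu;
  }
  return Q;
}

// Spectral decomposition of the scaled GY94 generator: eigenvalues and
// eigenvectors of diag(sqrt(pi)) Q diag(1/sqrt(pi)) (symmetric).
// [[Rcpp::export]]
Rcpp::List gy94_decompose_cpp(const arma::vec& pi, const arma::imat& ptype,
                              double kappa, double omega) {
  vec sqpi = sqrt(pi);
  mat Q = build_q(ptype, pi, kappa, omega, true);
  mat B = Q;
  for (uword i = 0; i < 61; ++i)
    for (uword j = 0; j < 61; ++j)
      B(i, j) *= sqpi(i) / sqpi(j);
  B = 0.5 * (B + B.t());
  vec vals; mat U;
  eig_sym(vals, U, B);
  return Rcpp::List::create(Rcpp::Named("vals") = vals,
                            Rcpp::Named("U") = U);
}

static mat prob_matrix(const vec& vals, const mat& U, const vec& sqpi,
                       double t) {
  mat P = U * diagmat(exp(vals * t)) * U.t();
  for (uword i = 0; i < 61; ++i)
    for (uword j = 0; j < 61; ++j) {
      P(i, j) *= sqpi(j) / sqpi(i);
      if (P(i, j) < 0) P(i, j) = 0;
    }
  return P;
}

// Pruning log-likelihood from per-branch decompositions.
// patterns: 4 x npat, 0-based codon states (rows: tips A,B,C,D);
// decomps: list of 5 decompositions (branch order A,B,C,D,internal);
// len: 5 branch lengths.
// [[Rcpp::export]]
double gy94_loglik_decomp_cpp(const arma::imat& patterns,
                              const arma::vec& weights,
                              const arma::vec& pi,
                              Rcpp::List decomps,
                              const arma::vec& len) {
  const uword npat = patterns.n_cols;
  vec sqpi = sqrt(pi);
  std::vector<mat> P(5);
  for (uword b = 0; b < 5; ++b) {
    Rcpp::List d = decomps[b];
    P[b] = prob_matrix(Rcpp::as<vec>(d["vals"]), Rcpp::as<mat>(d["U"]),
                       sqpi, len(b));
  }
  mat MU(61, npat), MV(61, npat);
  for (uword k = 0; k < npat; ++k) {
    MU.col(k) = P[0].col(patterns(0, k)) % P[1].col(patterns(1, k));
    MV.col(k) = P[2].col(patterns(2, k)) % P[3].col(patterns(3, k));
  }
  mat W = P[4] * MV;  // propagate node V across the internal branch
  double ll = 0.0;
  for (uword k = 0; k < npat; ++k) {
    double lik = dot(pi % MU.col(k), W.col(k));
    if (!(lik > 0) || !std::isfinite(lik))
      return -std::numeric_limits<double>::infinity();
    ll += weights(k) * std::log(lik);
  }
  return ll;
}

// Log-likelihood together with its analytic gradient in the five branch
// lengths (dP/dt = U diag(lambda exp(lambda t)) U' under the same
// similarity transform). kappa/omega derivatives are left to finite
// differences in the caller.
// [[Rcpp::export]]
Rcpp::List gy94_loglik_grad_cpp(const arma::imat& patterns,
                                const arma::vec& weights,
                                const arma::vec& pi,
                                Rcpp::List decomps,
                                const arma::vec& len) {
  const uword npat = patterns.n_cols;
  vec sqpi = sqrt(pi);
  std::vector<mat> P(5), dP(5);
  for (uword b = 0; b < 5; ++b) {
    Rcpp::List d = decomps[b];
    vec vals = Rcpp::as<vec>(d["vals"]);
    mat U = Rcpp::as<mat>(d["U"]);
    mat E = U * diagmat(exp(vals * len(b))) * U.t();
    mat dE = U * diagmat(vals % exp(vals * len(b))) * U.t();
    for (uword i = 0; i < 61; ++i)
      for (uword j = 0; j < 61; ++j) {
        double s = sqpi(j) / sqpi(i);
        dE(i, j) *= s;
        E(i, j) *= s;
        if (E(i, j) < 0) E(i, j) = 0;
      }
    P[b] = E; dP[b] = dE;
  }
  mat MU(61, npat), MV(61, npat);
  for (uword k = 0; k < npat; ++k) {
    MU.col(k) = P[0].col(patterns(0, k)) % P[1].col(patterns(1, k));
    MV.col(k) = P[2].col(patterns(2, k)) % P[3].col(patterns(3, k));
  }
  // derivative conditionals per tip, batched over patterns
  mat DMA(61, npat), DMB(61, npat), DMC(61, npat), DMD(61, npat);
  for (uword k = 0; k < npat; ++k) {
    DMA.col(k) = dP[0].col(patterns(0, k)) % P[1].col(patterns(1, k));
    DMB.col(k) = P[0].col(patterns(0, k)) % dP[1].col(patterns(1, k));
    DMC.col(k) = dP[2].col(patterns(2, k)) % P[3].col(patterns(3, k));
    DMD.col(k) = P[2].col(patterns(2, k)) % dP[3].col(patterns(3, k));
  }
  mat W = P[4] * MV;
  mat PMU = MU.each_col() % pi;
  vec f = sum(PMU % W, 0).t();
  for (uword k = 0; k < npat; ++k)
    if (!(f(k) > 0) || !std::isfinite(f(k)))
      return Rcpp::List::create(
        Rcpp::Named("ll") = -std::numeric_limits<double>::infinity(),
        Rcpp::Named("grad") = Rcpp::NumericVector(5));
  double ll = dot(weights, log(f));
  vec wf = weights / f;
  vec grad(5);
  grad(0) = dot(wf, sum((DMA.each_col() % pi) % W, 0).t());
  grad(1) = dot(wf, sum((DMB.each_col() % pi) % W, 0).t());
  grad(2) = dot(wf, sum(PMU % (P[4] * DMC), 0).t());
  grad(3) = dot(wf, sum(PMU % (P[4] * DMD), 0).t());
  grad(4) = dot(wf, sum(PMU % (dP[4] * MV), 0).t());
  return Rcpp::List::create(Rcpp::Named("ll") = ll,
                            Rcpp::Named("grad") = Rcpp::wrap(grad));
}

// Convenience one-shot evaluation (decompose + prune), one omega per branch.
// [[Rcpp::export]]
double gy94_loglik_cpp(const arma::imat& patterns,
                       const arma::vec& weights,
                       const arma::vec& pi,
                       const arma::imat& ptype,
                       double kappa,
                       const arma::vec& omega_branch,
                       const arma::vec& len) {
  Rcpp::List decomps(5);
  std::vector<double> seen;
  std::vector<Rcpp::List> cached;
  for (uword b = 0; b < 5; ++b) {
    double w = omega_branch(b);
    int hit = -1;
    for (size_t k = 0; k < seen.size(); ++k)
      if (seen[k] == w) { hit = (int)k; break; }
    if (hit < 0) {
      seen.push_back(w);
      cached.push_back(gy94_decompose_cpp(pi, ptype, kappa, w));
      hit = (int)seen.size() - 1;
    }
    decomps[b] = cached[hit];
  }
  return gy94_loglik_decomp_cpp(patterns, weights, pi, decomps, len);
}
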