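#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <utility>
using namespace Rcpp;

namespace {

struct Problem {
  NumericMatrix X, rho, R;
  NumericVector ss, d, w;
  double lambda;
  int n, p;

  Problem(NumericMatrix X_, NumericVector ss_, NumericMatrix rho_,
          NumericMatrix R_, NumericVector d_, NumericVector w_,
          double lambda_)
    : X(X_), rho(rho_), R(R_), ss(ss_), d(d_), w(w_), lambda(lambda_),
      n(X_.nrow()), p(X_.ncol()) {}

  // Soft-threshold update of the (i, j) pair; returns |change|.
  double update(int i, int j) {
    const double r_old = rho(i, j);
    const double sij = std::sqrt(d[j] / d[i]);
    const double sji = std::sqrt(d[i] / d[j]);
    if (r_old != 0.0) {
      for (int k = 0; k < n; ++k) {
        R(k, i) += r_old * sij * X(k, j);
        R(k, j) += r_old * sji * X(k, i);
      }
    }
    double ci = 0.0, cj = 0.0;
    for (int k = 0; k < n; ++k) {
      ci += R(k, i) * X(k, j);
      cj += R(k, j) * X(k, i);
    }
    const double cc = w[i] * sij * ci + w[j] * sji * cj;
    const double aa = w[i] * sij * sij * ss[j] + w[j] * sji * sji * ss[i];
    double r_new = 0.0;
    const double soft = std::fabs(cc) - lambda;
    if (soft > 0.0) r_new = (cc > 0.0 ? soft : -soft) / aa;
    if (r_new != 0.0) {
      for (int k = 0; k < n; ++k) {
        R(k, i) -= r_new * sij * X(k, j);
        R(k, j) -= r_new * sji * X(k, i);
      }
    }
    rho(i, j) = r_new;
    rho(j, i) = r_new;
    return std::fabs(r_new - r_old);
  }
};

}  // namespace

// Cyclic coordinate descent for the joint symmetric lasso regression
// behind the sparse partial-correlation estimator, with active-set
// refinement: full sweeps over all pairs alternate with cheap sweeps over
// the currently nonzero pairs until a full sweep changes nothing beyond
// tol. `rho` (p x p, symmetric, zero diagonal) and the residual matrix
// `R` (n x p) are updated in place; the caller owns copies.
//
// Objective: (1/2) sum_i w_i || x_i - sum_{j!=i} rho_ij sqrt(d_j/d_i) x_j ||^2
//            + lambda * sum_{i<j} |rho_ij|
// [[Rcpp::export(name = ".space_cd_sweeps")]]
List space_cd_sweeps(NumericMatrix X, NumericVector ss, NumericMatrix rho,
                     NumericMatrix R, NumericVector d, NumericVector w,
                     double lambda, int max_iter, double tol) {
  Problem pb(X, ss, rho, R, d, w, lambda);
  const int p = pb.p;
  int sweeps = 0;
  double max_delta = R_PosInf;
  std::vector<std::pair<int, int> > active;
  while (sweeps < max_iter) {
    // full sweep: global optimality check + active-set harvest
    ++sweeps;
    max_delta = 0.0;
    active.clear();
    for (int i = 0; i < p - 1; ++i) {
      for (int j = i + 1; j < p; ++j) {
        const double delta = pb.update(i, j);
        if (delta > max_delta) max_delta = delta;
        if (rho(i, j) != 0.0) active.push_back(std::make_pair(i, j));
      }
    }
    if (max_delta < tol) break;
    // refine the active set to convergence before the next full sweep
    while (sweeps < max_iter && !active.empty()) {
      ++sweeps;
      double md = 0.0;
      for (std::size_t a = 0; a < active.size(); ++a) {
        const double delta = pb.update(active[a].first, active[a].second);
        if (delta > md) md = delta;
      }
      if (md < tol) break;
    }
  }
  return List::create(_["sweeps"] = sweeps, _["max_delta"] = max_delta);
}
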