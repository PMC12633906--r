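// Penalized log-determinant solver with an elementwise penalty matrix:
//
//   minimize_{Theta > 0}  tr(Theta S) - log det Theta + sum_ij rho_ij |theta_ij|
//
// Block coordinate descent on W = Theta^{-1} (glasso family): each column of W
// is updated by solving a lasso subproblem with per-entry penalties by cyclic
// coordinate descent. The diagonal of W is fixed at S_ii + rho_ii by the KKT
// conditions (the diagonal is penalized).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Soft-thresholding operator
static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Recover Theta from (W, B): theta_jj = 1 / (w_jj - w12' beta_j),
// theta_{.j} = -beta_j * theta_jj. Returns symmetrized Theta.
static arma::mat recover_theta(const arma::mat& W, const arma::mat& B) {
  const arma::uword p = W.n_rows;
  arma::mat Theta(p, p, arma::fill::zeros);
  for (arma::uword j = 0; j < p; ++j) {
    double quad = 0.0;
    for (arma::uword i = 0; i < p; ++i)
      if (i != j) quad += W(i, j) * B(i, j);
    double tjj = 1.0 / (W(j, j) - quad);
    Theta(j, j) = tjj;
    for (arma::uword i = 0; i < p; ++i)
      if (i != j) Theta(i, j) = -B(i, j) * tjj;
  }
  return 0.5 * (Theta + Theta.t());
}

static double primal_objective(const arma::mat& Theta, const arma::mat& S,
                               const arma::mat& Rho, bool& ok) {
  double ld, sign;
  arma::log_det(ld, sign, Theta);
  if (sign <= 0.0 || !std::isfinite(ld)) { ok = false; return NA_REAL; }
  ok = true;
  return arma::trace(Theta * S) - ld + arma::accu(Rho % arma::abs(Theta));
}

// [[Rcpp::export(name = ".glasso_core")]]
List glasso_core(const arma::mat& S, const arma::mat& Rho,
                 double tol, int max_iter,
                 Nullable<NumericMatrix> W_init = R_NilValue,
                 Nullable<NumericMatrix> B_init = R_NilValue,
                 bool trace_objective = true) {
  const arma::uword p = S.n_rows;

  arma::mat W = S;
  W.diag() = S.diag() + Rho.diag();
  arma::mat B(p, p, arma::fill::zeros);
  if (W_init.isNotNull()) {
    W = as<arma::mat>(W_init.get());
    W.diag() = S.diag() + Rho.diag();   // diagonal is fixed by KKT
  }
  if (B_init.isNotNull()) B = as<arma::mat>(B_init.get());

  // Convergence scale: mean |S_ij|, i != j (fallback to mean diag for
  // diagonal S so the threshold stays positive)
  double off_sum = 0.0;
  for (arma::uword j = 0; j < p; ++j)
    for (arma::uword i = 0; i < p; ++i)
      if (i != j) off_sum += std::abs(S(i, j));
  double scale = (p > 1) ? off_sum / (double)(p * (p - 1)) : 0.0;
  if (scale <= 0.0) scale = arma::mean(arma::abs(S.diag()));
  if (scale <= 0.0) scale = 1.0;
  const double thr = tol * scale;
  const double inner_thr = thr / 10.0;

  std::vector<double> obj_trace;
  bool converged = false;
  int iter = 0;

  if (p == 1) {
    arma::mat Theta(1, 1);
    Theta(0, 0) = 1.0 / W(0, 0);
    bool ok;
    double obj = primal_objective(Theta, S, Rho, ok);
    return List::create(_["theta"] = Theta, _["w"] = W, _["iterations"] = 0,
                        _["converged"] = true, _["objective"] = obj,
                        _["objective_trace"] = NumericVector::create(obj),
                        _["B"] = B);
  }

  arma::vec beta(p - 1), s12(p - 1), rho12(p - 1);
  arma::mat W11(p - 1, p - 1);
  arma::uvec idx(p - 1);

  for (iter = 1; iter <= max_iter; ++iter) {
    double mean_change = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      arma::uword m = 0;
      for (arma::uword i = 0; i < p; ++i)
        if (i != j) idx(m++) = i;
      W11 = W.submat(idx, idx);
      for (arma::uword k = 0; k < p - 1; ++k) {
        s12(k) = S(idx(k), j);
        rho12(k) = Rho(idx(k), j);
        beta(k) = B(idx(k), j);
      }
      // lasso CD: min 0.5 b'W11 b - s12'b + sum rho_k |b_k|
      for (int inner = 0; inner < 1000; ++inner) {
        double max_d = 0.0;
        for (arma::uword k = 0; k < p - 1; ++k) {
          double old = beta(k);
          double x = s12(k) - arma::dot(W11.col(k), beta) + W11(k, k) * old;
          double nb = soft(x, rho12(k)) / W11(k, k);
          if (nb != old) {
            beta(k) = nb;
            double d = std::abs(nb - old);
            if (d > max_d) max_d = d;
          }
        }
        if (max_d < inner_thr) break;
      }
      arma::vec w12 = W11 * beta;
      for (arma::uword k = 0; k < p - 1; ++k) {
        mean_change += std::abs(W(idx(k), j) - w12(k));
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    mean_change /= (double)(p * (p - 1));

    if (trace_objective) {
      bool ok;
      double obj = primal_objective(recover_theta(W, B), S, Rho, ok);
      obj_trace.push_back(ok ? obj : NA_REAL);
    }
    if (mean_change < thr) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  arma::mat Theta = recover_theta(W, B);
  bool ok;
  double obj = primal_objective(Theta, S, Rho, ok);

  return List::create(_["theta"] = Theta, _["w"] = W, _["iterations"] = iter,
                      _["converged"] = converged, _["objective"] = obj,
                      _["objective_trace"] = wrap(obj_trace), _["B"] = B);
}
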