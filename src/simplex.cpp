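// Bounded-variable two-phase primal simplex, compiled core.
//
// Mirrors the reference implementation in R/simplex.R (solve_lp_ref): each
// ranged row  rl_i <= a_i' x <= ru_i  becomes an equality with a boxed slack,
// phase 1 drives per-row artificials to zero, phase 2 minimizes the true
// objective. Dantzig pricing with a Bland fallback; explicit basis inverse
// with product-form updates and periodic refactorization.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct PhaseResult {
  bool ok;
  double obj;
};

// One simplex phase on the augmented system. Mutates xval, vstat, basis,
// Binv in place. vstat: 0 nonbasic-at-lb, 1 nonbasic-at-ub, 2 basic.
PhaseResult run_phase(const mat& Afull, const vec& cphase, const vec& lbf,
                      const vec& ubf, const uvec& enterable, vec& xval,
                      ivec& vstat, uvec& basis, mat& Binv, double tol,
                      int max_iter) {
  const uword m = Afull.n_rows;
  const uword nf = Afull.n_cols;
  int iter = 0, stall = 0;
  double last_obj = datum::inf;

  for (;;) {
    if (++iter > max_iter) Rcpp::stop("simplex iteration limit reached");
    if (iter % 60 == 0) {  // periodic refactorization
      mat B = Afull.cols(basis);
      if (!inv(Binv, B)) Rcpp::stop("singular basis");
      vec xn = xval;
      xn.elem(basis).zeros();
      xval.elem(basis) = Binv * (-(Afull * xn));
    }
    vec y = Binv.t() * cphase.elem(basis);
    vec d = cphase - Afull.t() * y;

    double best_viol = 0.0;
    uword e = nf;  // entering variable
    double obj_now = dot(cphase, xval);
    if (obj_now < last_obj - tol) { stall = 0; last_obj = obj_now; }
    else ++stall;
    bool bland = stall > 80;

    for (uword j = 0; j < nf; ++j) {
      if (!enterable[j] || vstat[j] == 2) continue;
      double viol = (vstat[j] == 0) ? -d[j] : d[j];
      if (viol <= tol) continue;
      if (bland) { e = j; break; }
      if (viol > best_viol) { best_viol = viol; e = j; }
    }
    if (e == nf) {  // optimal for this phase
      return PhaseResult{true, dot(cphase, xval)};
    }

    double dir = (vstat[e] == 0) ? 1.0 : -1.0;
    vec w = dir * (Binv * Afull.col(e));  // basic change per unit is -w

    double t_best = ubf[e] - lbf[e];  // own-bound flip distance
    sword leave_pos = -1;
    for (uword i = 0; i < m; ++i) {
      uword bi = basis[i];
      double ti;
      if (w[i] > tol)       ti = (xval[bi] - lbf[bi]) / w[i];
      else if (w[i] < -tol) ti = (ubf[bi] - xval[bi]) / (-w[i]);
      else continue;
      if (!std::isfinite(ti)) continue;
      if (ti < 0) ti = 0;
      if (ti < t_best - tol ||
          (ti < t_best + tol && leave_pos >= 0 && bi < basis[(uword)leave_pos])) {
        t_best = ti;
        leave_pos = (sword)i;
      }
    }
    if (!std::isfinite(t_best)) Rcpp::stop("LP unbounded");

    xval[e] += dir * t_best;
    for (uword i = 0; i < m; ++i) xval[basis[i]] -= t_best * w[i];

    if (leave_pos < 0) {  // bound flip
      vstat[e] = (vstat[e] == 0) ? 1 : 0;
      xval[e] = (vstat[e] == 0) ? lbf[e] : ubf[e];
    } else {
      uword lp = (uword)leave_pos;
      uword lv = basis[lp];
      bool hit_upper = w[lp] < 0;
      vstat[lv] = hit_upper ? 1 : 0;
      xval[lv] = hit_upper ? ubf[lv] : lbf[lv];
      vstat[e] = 2;
      basis[lp] = e;
      vec eta = Binv * Afull.col(e);
      double piv = eta[lp];
      if (std::abs(piv) < 1e-11) {
        mat B = Afull.cols(basis);
        if (!inv(Binv, B)) Rcpp::stop("singular basis");
      } else {
        Binv.row(lp) /= piv;
        for (uword i = 0; i < m; ++i) {
          if (i != lp && std::abs(eta[i]) > 1e-13) {
            Binv.row(i) -= eta[i] * Binv.row(lp);
          }
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".solve_lp_cpp")]]
Rcpp::List solve_lp_cpp(const arma::vec& cost, const arma::mat& A,
                        const arma::vec& rl, const arma::vec& ru,
                        const arma::vec& lb, const arma::vec& ub,
                        double tol = 1e-9, double feas_tol = 1e-7,
                        int max_iter = 10000) {
  const uword m = A.n_rows, n = A.n_cols;
  if (any(lb > ub + tol) || any(rl > ru + tol)) {
    return Rcpp::List::create(Rcpp::Named("status") = "infeasible",
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("obj") = NA_REAL);
  }
  vec ubx = max(ub, lb);

  const uword nf = n + 2 * m;
  mat Afull(m, nf, fill::zeros);
  Afull.cols(0, n - 1) = A;
  for (uword i = 0; i < m; ++i) Afull(i, n + i) = -1.0;

  vec lbf(nf), ubf(nf);
  lbf.subvec(0, n - 1) = lb;            ubf.subvec(0, n - 1) = ubx;
  lbf.subvec(n, n + m - 1) = rl;        ubf.subvec(n, n + m - 1) = ru;
  lbf.subvec(n + m, nf - 1).zeros();
  ubf.subvec(n + m, nf - 1).fill(datum::inf);

  vec v = A * lb;
  vec s0 = min(max(v, rl), ru);
  s0.elem(find_nonfinite(s0)).zeros();
  vec resid = v - s0;

  vec xval(nf, fill::zeros);
  xval.subvec(0, n - 1) = lb;
  xval.subvec(n, n + m - 1) = s0;
  ivec vstat(nf, fill::zeros);
  uvec basis(m);
  for (uword i = 0; i < m; ++i) {
    double sgn = (resid[i] > 0) ? -1.0 : 1.0;
    Afull(i, n + m + i) = sgn;
    if (std::abs(resid[i]) > tol) {     // artificial basic, slack at a bound
      basis[i] = n + m + i;
      xval[n + m + i] = std::abs(resid[i]);
      bool at_upper = v[i] > ru[i];
      vstat[n + i] = at_upper ? 1 : 0;
      xval[n + i] = at_upper ? ru[i] : rl[i];
    } else {                            // slack basic, artificial pinned
      basis[i] = n + i;
      ubf[n + m + i] = 0.0;
    }
  }
  for (uword i = 0; i < m; ++i) vstat[basis[i]] = 2;
  uvec enterable(nf, fill::ones);
  enterable.subvec(n + m, nf - 1).zeros();  // artificials never enter

  mat Binv;
  if (!inv(Binv, Afull.cols(basis))) Rcpp::stop("singular basis");

  // phase 1
  double art_mass = accu(xval.subvec(n + m, nf - 1));
  if (art_mass > tol) {
    vec c1(nf, fill::zeros);
    c1.subvec(n + m, nf - 1).ones();
    PhaseResult ph1 = run_phase(Afull, c1, lbf, ubf, enterable, xval, vstat,
                                basis, Binv, tol, max_iter);
    if (ph1.obj > feas_tol) {
      return Rcpp::List::create(Rcpp::Named("status") = "infeasible",
                                Rcpp::Named("x") = R_NilValue,
                                Rcpp::Named("obj") = NA_REAL);
    }
  }
  // pin artificials to zero for phase 2
  ubf.subvec(n + m, nf - 1).zeros();
  xval.subvec(n + m, nf - 1).zeros();

  vec c2(nf, fill::zeros);
  c2.subvec(0, n - 1) = cost;
  run_phase(Afull, c2, lbf, ubf, enterable, xval, vstat, basis, Binv, tol,
            max_iter);

  vec x = xval.subvec(0, n - 1);
  return Rcpp::List::create(Rcpp::Named("status") = "optimal",
                            Rcpp::Named("x") = Rcpp::NumericVector(x.begin(), x.end()),
                            Rcpp::Named("obj") = dot(cost, x));
}
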