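// Bounded-variable two-phase primal simplex for dense LPs:
//   maximize c'x  subject to  A x = b,  l <= x <= u
// Bounds may be +-Inf. Dense refactorization each iteration (problems here
// have at most a few hundred rows, so an O(m^3) solve per pivot is cheap and
// numerically uneventful). Dantzig pricing with a Bland fallback after
// 3*(n+m) iterations guards against cycling on degenerate fermentation
// networks (which are highly degenerate by construction).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double FEAS_TOL = 1e-7;  // entering threshold: above solve() noise
static const double PIVOT_TOL = 1e-9;

namespace {

struct SimplexState {
  mat A;          // m x N augmented (structural + artificial) columns
  vec c, l, u, x; // length N
  uvec basis;     // length m, column indices
  ivec nstat;     // 0 at lower, 1 at upper, 2 free at zero, -1 basic
  int m, n, N;
};

// One simplex phase: optimize c'x over the current basis. Returns
// 0 optimal, 2 unbounded, 3 iteration limit.
int run_phase(SimplexState &S, int max_iter) {
  int iter = 0;
  const int bland_after = 3 * (S.N + S.m) + 50;
  while (true) {
    if (++iter > max_iter) return 3;
    const bool bland = iter > bland_after;

    mat B(S.m, S.m);
    for (int i = 0; i < S.m; ++i) B.col(i) = S.A.col(S.basis[(uword)i]);
    vec cB(S.m);
    for (int i = 0; i < S.m; ++i) cB[i] = S.c[S.basis[(uword)i]];
    vec y;
    if (!solve(y, B.t(), cB, solve_opts::no_approx)) return 3;

    // pricing
    int enter = -1, dir = 0;
    double best = 0.0;
    for (int j = 0; j < S.N; ++j) {
      int st = S.nstat[j];
      if (st < 0) continue;
      if (S.u[j] - S.l[j] <= 1e-12) continue; // fixed: can never move
      double d = S.c[j] - dot(y, S.A.col(j));
      double viol = 0.0;
      int sdir = 0;
      if ((st == 0 || st == 2) && d > FEAS_TOL) { viol = d; sdir = 1; }
      if (st == 2 && d < -FEAS_TOL && -d > viol) { viol = -d; sdir = -1; }
      if (st == 1 && d < -FEAS_TOL) { viol = -d; sdir = -1; }
      if (sdir != 0) {
        if (bland) { enter = j; dir = sdir; break; }
        if (viol > best) { best = viol; enter = j; dir = sdir; }
      }
    }
    if (enter < 0) return 0; // optimal

    vec w;
    if (!solve(w, B, S.A.col(enter), solve_opts::no_approx)) return 3;

    // Harris two-pass ratio test: x_basic(t) = x_basic - dir * w * t.
    // Pass 1 finds the most permissive step under an eps_b bound
    // relaxation; pass 2 picks, among rows whose exact ratio fits under
    // it, the largest pivot magnitude (Bland mode: smallest column index),
    // which keeps the basis well conditioned at the cost of transient
    // bound violations no larger than eps_b.
    const double eps_b = 1e-7;
    const double range = S.u[enter] - S.l[enter]; // may be inf
    double t_rel = datum::inf;
    for (int i = 0; i < S.m; ++i) {
      double delta = dir * w[i];
      if (std::fabs(delta) <= PIVOT_TOL) continue;
      uword bi = S.basis[(uword)i];
      double t_i;
      if (delta > 0) {
        if (!std::isfinite(S.l[bi])) continue;
        t_i = (S.x[bi] - S.l[bi] + eps_b) / delta;
      } else {
        if (!std::isfinite(S.u[bi])) continue;
        t_i = (S.u[bi] - S.x[bi] + eps_b) / (-delta);
      }
      if (t_i < t_rel) t_rel = t_i;
    }
    int leave = -1;     // row index in basis; -1 means bound flip
    int leave_to = 0;   // 0 lower, 1 upper
    double t_max = datum::inf;
    double best_piv = 0.0;
    for (int i = 0; i < S.m; ++i) {
      double delta = dir * w[i];
      if (std::fabs(delta) <= PIVOT_TOL) continue;
      uword bi = S.basis[(uword)i];
      double t_i;
      int to;
      if (delta > 0) {
        if (!std::isfinite(S.l[bi])) continue;
        t_i = (S.x[bi] - S.l[bi]) / delta; to = 0;
      } else {
        if (!std::isfinite(S.u[bi])) continue;
        t_i = (S.u[bi] - S.x[bi]) / (-delta); to = 1;
      }
      if (t_i < 0) t_i = 0;
      if (t_i <= t_rel + 1e-12) {
        bool take;
        if (leave < 0) take = true;
        else if (bland) take = bi < S.basis[(uword)leave];
        else take = std::fabs(delta) > best_piv;
        if (take) {
          leave = i; leave_to = to; t_max = t_i;
          best_piv = std::fabs(delta);
        }
      }
    }
    if (leave >= 0 && std::isfinite(range) && range < t_max) {
      leave = -1; t_max = range; // entering hits its own bound first
    }
    if (leave < 0 && std::isfinite(range)) t_max = range;
    if (!std::isfinite(t_max)) return 2; // unbounded ray

    // apply step
    for (int i = 0; i < S.m; ++i) S.x[S.basis[(uword)i]] -= dir * w[i] * t_max;
    S.x[enter] += dir * t_max;

    if (leave < 0) {
      // entering variable flipped to its opposite bound
      S.nstat[enter] = (dir > 0) ? 1 : 0;
      S.x[enter] = (dir > 0) ? S.u[enter] : S.l[enter];
    } else {
      uword out = S.basis[(uword)leave];
      S.nstat[out] = leave_to;
      S.x[out] = (leave_to == 0) ? S.l[out] : S.u[out];
      S.basis[(uword)leave] = (uword)enter;
      S.nstat[enter] = -1;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".lp_solve_dense")]]
Rcpp::List lp_solve_dense(const arma::mat &A, const arma::vec &b,
                          const arma::vec &c, const arma::vec &l,
                          const arma::vec &u, int max_iter = 20000) {
  const int m = (int)A.n_rows, n = (int)A.n_cols;
  SimplexState S;
  S.m = m; S.n = n; S.N = n + m;
  S.A.set_size(m, S.N);
  S.A.cols(0, n - 1) = A;
  S.c = join_cols(c, zeros<vec>(m));
  S.l = join_cols(l, zeros<vec>(m));
  S.u.set_size(S.N);
  for (int j = 0; j < n; ++j) S.u[j] = u[j];
  S.x = zeros<vec>(S.N);
  S.nstat.set_size(S.N);
  S.basis.set_size(m);

  // initial nonbasic point for structural columns
  for (int j = 0; j < n; ++j) {
    if (std::isfinite(l[j])) { S.nstat[j] = 0; S.x[j] = l[j]; }
    else if (std::isfinite(u[j])) { S.nstat[j] = 1; S.x[j] = u[j]; }
    else { S.nstat[j] = 2; S.x[j] = 0.0; }
  }
  // artificial columns absorb the residual
  vec r = b - S.A.cols(0, n - 1) * S.x.head(n);
  for (int i = 0; i < m; ++i) {
    int j = n + i;
    S.A.col(j).zeros();
    S.A(i, j) = (r[i] >= 0) ? 1.0 : -1.0;
    S.u[j] = datum::inf;
    S.x[j] = std::fabs(r[i]);
    S.basis[(uword)i] = (uword)j;
    S.nstat[j] = -1;
  }

  // phase 1: minimize sum of artificials
  vec c_save = S.c;
  S.c.zeros();
  for (int i = 0; i < m; ++i) S.c[n + i] = -1.0;
  int st = run_phase(S, max_iter);
  double art = 0.0;
  for (int i = 0; i < m; ++i) art += S.x[n + i];
  int status;
  vec xout(n, fill::zeros);
  double obj = NA_REAL;
  if (st == 3) {
    status = 3;
  } else if (art > 1e-7) {
    status = 1; // infeasible
  } else {
    // phase 2: pin artificials at zero, restore true objective
    for (int i = 0; i < m; ++i) { S.u[n + i] = 0.0; S.x[n + i] = 0.0; }
    S.c = c_save;
    st = run_phase(S, max_iter);
    status = (st == 0) ? 0 : st;
    if (status == 0 || status == 2) {
      xout = S.x.head(n);
      obj = dot(c, xout);
    }
  }
  return Rcpp::List::create(Rcpp::Named("status") = status,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("x") = xout,
                            Rcpp::Named("iterations") = 0);
}
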