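// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Weighted-lasso coordinate descent with covariance updates and an
// active-set Newton acceleration.
//
// Solves, for each lambda in `lambdas` (decreasing; solutions are
// warm-started along the path),
//
//   min_g  (1/2) g' G g - c' g + lambda * sum_j w_j |g_j|
//
// where G is the Gram matrix of the cis-projected instruments and
// c their cross-product with the projected response: the profiled
// second-stage objective.  The quadratic part can be supplied either as
// the dense m x m Gram itself or in factored form G = F'F with F the
// r x m projected design (r = samples); the factored form makes each
// coordinate update O(r) instead of O(m), which wins in the
// high-dimensional regime r < m.
//
// Strategy per lambda: coordinate sweeps; once the sign pattern is
// stable, solve the KKT system on the active set exactly,
//   G_AA g_A = c_A - lambda * (w_A . s_A),
// and accept it if the solution keeps the assumed signs and no inactive
// coordinate violates its KKT bound.  Singular active sets fall back to
// plain sweeps.  Convergence: max coefficient change in a sweep below
// `tol`.
//
// The path stops early (carrying the last solution forward) once the
// model saturates (`dfmax` nonzeros) or the training fraction of
// variance explained passes `devmax`; cross-validation never selects
// that region and solving it is slow and non-unique.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

struct Quad {
  const arma::mat &M;   // G (m x m) or F (r x m)
  bool factored;
  arma::vec diag;       // diagonal of G
  arma::vec state;      // Gg (m) or u = F g (r)
  Quad(const arma::mat &M_, bool factored_) : M(M_), factored(factored_) {
    if (factored) {
      diag = arma::sum(arma::square(M), 0).t();
      state.zeros(M.n_rows);
    } else {
      diag = arma::clamp(M.diag(), 0.0, arma::datum::inf);
      state.zeros(M.n_cols);
    }
  }
  // gradient component j of the smooth part, given current g_j
  inline double partial(int j, double gj) const {
    if (factored) return arma::dot(M.col(j), state) - diag[j] * gj;
    return state[j] - diag[j] * gj;
  }
  inline void update(int j, double d) {
    if (factored) state += d * M.col(j);
    else state += d * M.col(j);  // state is Gg; M.col(j) = G col
  }
  // g' G g for the rss computation
  inline double quadForm(const arma::vec &g) const {
    if (factored) return arma::dot(state, state);
    return arma::dot(g, state);
  }
  arma::mat gramAA(const arma::uvec &A) const {
    if (factored) {
      arma::mat FA = M.cols(A);
      return FA.t() * FA;
    }
    return M.submat(A, A);
  }
  arma::vec gramTimes(const arma::uvec &A, const arma::vec &gA) const {
    if (factored) return M.t() * (M.cols(A) * gA);
    return M.cols(A) * gA;
  }
};

static double sweep(Quad &Q, const arma::vec &c, const arma::vec &w,
                    double lam, const std::vector<int> &idx,
                    arma::vec &g) {
  double maxDelta = 0.0;
  for (int j : idx) {
    if (Q.diag[j] <= 1e-300) continue;
    double z = c[j] - Q.partial(j, g[j]);
    double gj = soft(z, lam * w[j]) / Q.diag[j];
    double d = gj - g[j];
    if (d != 0.0) {
      Q.update(j, d);
      g[j] = gj;
      double ad = std::fabs(d);
      if (ad > maxDelta) maxDelta = ad;
    }
  }
  return maxDelta;
}

// [[Rcpp::export(name = ".cdWLassoPathImpl")]]
List cdWLassoPathImpl(const arma::mat &M, bool factored,
                      const arma::vec &c, const arma::vec &w,
                      const arma::vec &lambdas, double tol = 1e-7,
                      int maxit = 100000, int dfmax = -1,
                      double yss = -1.0, double devmax = 0.999,
                      Nullable<NumericVector> warm = R_NilValue) {
  const int m = M.n_cols;
  const int L = lambdas.n_elem;
  if (!factored && (int)M.n_rows != m) stop("G must be square");
  if ((int)c.n_elem != m || (int)w.n_elem != m)
    stop("c and w must match the coefficient count");
  if (dfmax < 0) dfmax = m;

  arma::mat beta(m, L, arma::fill::zeros);
  LogicalVector converged(L);
  int truncatedAt = L;
  arma::vec g(m, arma::fill::zeros);
  Quad Q(M, factored);
  if (warm.isNotNull()) {
    NumericVector w0(warm);
    if ((int)w0.size() != m) stop("warm start has the wrong length");
    for (int j = 0; j < m; ++j) g[j] = w0[j];
    if (factored) Q.state = M * g;
    else Q.state = M * g;
  }
  std::vector<int> all(m);
  for (int j = 0; j < m; ++j) all[j] = j;

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    int iter = 0;
    bool done = false;
    while (iter < maxit) {
      double maxDelta = sweep(Q, c, w, lam, all, g);
      ++iter;
      if (maxDelta < tol) { done = true; break; }
      // a few active-set sweeps to let the sign pattern settle
      std::vector<int> act;
      for (int inner = 0; inner < 5 && iter < maxit; ++inner, ++iter) {
        act.clear();
        for (int j = 0; j < m; ++j) if (g[j] != 0.0) act.push_back(j);
        if (sweep(Q, c, w, lam, act, g) < tol) break;
      }
      // exact KKT solve on the current active set
      act.clear();
      for (int j = 0; j < m; ++j) if (g[j] != 0.0) act.push_back(j);
      const int a = act.size();
      if (a > 0 && a <= dfmax) {
        arma::uvec A(a);
        arma::vec rhs(a);
        for (int i = 0; i < a; ++i) {
          A[i] = act[i];
          rhs[i] = c[act[i]] -
            lam * w[act[i]] * (g[act[i]] > 0 ? 1.0 : -1.0);
        }
        arma::vec gA;
        bool ok = arma::solve(gA, Q.gramAA(A), rhs,
                              arma::solve_opts::no_approx);
        if (ok) {
          for (int i = 0; i < a && ok; ++i)
            ok = (gA[i] > 0) == (g[A[i]] > 0) && gA[i] != 0.0;
          if (ok) {
            arma::vec grad = Q.gramTimes(A, gA);
            double slack = tol * (1.0 + arma::max(Q.diag));
            for (int j = 0; j < m && ok; ++j) {
              bool active = false;
              for (int i = 0; i < a; ++i)
                if ((int)A[i] == j) { active = true; break; }
              if (active) continue;
              ok = std::fabs(c[j] - grad[j]) <= lam * w[j] + slack;
            }
            if (ok) {
              g.zeros();
              g.elem(A) = gA;
              if (factored) Q.state = M.cols(A) * gA;
              else Q.state = grad;
              done = true;
              break;
            }
          }
        }
      }
    }
    converged[l] = done;
    beta.col(l) = g;
    int nnz = 0;
    for (int j = 0; j < m; ++j) if (g[j] != 0.0) ++nnz;
    bool saturatedFit = false;
    if (yss > 0.0) {
      double rss = yss + Q.quadForm(g) - 2.0 * arma::dot(g, c);
      saturatedFit = (1.0 - rss / yss) >= devmax;
    }
    if ((nnz >= dfmax || saturatedFit) && l + 1 < L) {
      for (int l2 = l + 1; l2 < L; ++l2) {
        converged[l2] = done;
        beta.col(l2) = g;
      }
      truncatedAt = l + 1;
      break;
    }
  }
  return List::create(_["beta"] = beta, _["converged"] = converged,
                      _["truncatedAt"] = truncatedAt);
}

// [[Rcpp::export(name = ".cdWLassoPath")]]
List cdWLassoPath(const arma::mat &G, const arma::vec &c,
                  const arma::vec &w, const arma::vec &lambdas,
                  double tol = 1e-7, int maxit = 100000, int dfmax = -1,
                  double yss = -1.0, double devmax = 0.999) {
  return cdWLassoPathImpl(G, false, c, w, lambdas, tol, maxit, dfmax,
                          yss, devmax, R_NilValue);
}
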