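// Stabilized Sinkhorn scaling for entropic optimal transport.
//
// Scaling iterations run in the ordinary domain (matrix-vector products
// against K = exp((f + g' - M)/gamma)); whenever a scaling factor leaves
// [1e-100, 1e100] it is absorbed into the dual potentials f, g and K is
// rebuilt, which keeps the iteration stable at small gamma where exp(-M/gamma)
// underflows. Marginals must be strictly positive; callers restrict to the
// support first.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static void rebuild_kernel(mat& K, const vec& f, const vec& g, const mat& M,
                           double gamma) {
  const uword n = M.n_rows, s = M.n_cols;
  for (uword j = 0; j < s; ++j) {
    K.col(j) = exp((f + g(j) - M.col(j)) / gamma);
  }
}

// One full log-domain Sinkhorn iteration (logsumexp updates of f then g);
// used to recover whenever the scaled kernel underflows to a zero row.
static void log_domain_iteration(const vec& p, const vec& q, const mat& M,
                                 double gamma, vec& f, vec& g) {
  const uword n = p.n_elem, s = q.n_elem;
  for (uword i = 0; i < n; ++i) {
    rowvec z = (g.t() - M.row(i)) / gamma;
    double mx = z.max();
    f(i) = gamma * (std::log(p(i)) - (mx + std::log(sum(exp(z - mx)))));
  }
  for (uword j = 0; j < s; ++j) {
    vec z = (f - M.col(j)) / gamma;
    double mx = z.max();
    g(j) = gamma * (std::log(q(j)) - (mx + std::log(sum(exp(z - mx)))));
  }
}

static void sanitize(vec& x) {
  x.transform([](double v) { return std::isfinite(v) ? v : 0.0; });
}

// One scaling pass at a fixed gamma; f, g, u, v updated in place.
static void sinkhorn_pass(const vec& p, const vec& q, const mat& M,
                          double gamma, int max_iter, double tol, vec& f,
                          vec& g, vec& u, vec& v, mat& K, int& iters,
                          double& err, bool& converged) {
  const double absorb_hi = 1e100, absorb_lo = 1e-100;
  converged = false;
  err = datum::inf;
  int it;
  for (it = 1; it <= max_iter; ++it) {
    vec Kv = K * v;
    if (Kv.min() <= 0.0 || !Kv.is_finite()) {
      // kernel under-/overflowed between absorptions: recover with one
      // consistent log-domain iteration from sanitised potentials
      f += gamma * log(u);
      g += gamma * log(v);
      sanitize(f);
      sanitize(g);
      u.ones();
      v.ones();
      log_domain_iteration(p, q, M, gamma, f, g);
      sanitize(f);
      sanitize(g);
      rebuild_kernel(K, f, g, M, gamma);
      Kv = K * v;
      if (Kv.min() <= 0.0) Rcpp::stop("sinkhorn kernel collapsed to zero");
    }
    u = p / Kv;
    vec Ktu = K.t() * u;
    v = q / Ktu;

    if (!u.is_finite() || !v.is_finite() || u.max() > absorb_hi ||
        v.max() > absorb_hi || u.min() < absorb_lo || v.min() < absorb_lo) {
      f += gamma * log(u);
      g += gamma * log(v);
      sanitize(f);
      sanitize(g);
      u.ones();
      v.ones();
      rebuild_kernel(K, f, g, M, gamma);
    }

    if (it % 10 == 0 || it == max_iter) {
      vec row_marg = u % (K * v);
      if (row_marg.is_finite()) {
        err = abs(row_marg - p).max();
        if (err < tol) {
          converged = true;
          break;
        }
      }
    }
  }
  iters += std::min(it, max_iter);
}

// [[Rcpp::export]]
Rcpp::List sinkhorn_core(const arma::vec& p, const arma::vec& q,
                         const arma::mat& M, double gamma, int max_iter,
                         double tol, const arma::vec& f0, const arma::vec& g0,
                         bool anneal = false, int warm_try = 0,
                         double warm_tol = 0.0) {
  const uword n = p.n_elem, s = q.n_elem;
  if (M.n_rows != n || M.n_cols != s)
    Rcpp::stop("ground cost dimensions do not match the marginals");
  if (gamma <= 0.0) Rcpp::stop("gamma must be > 0");
  if (p.min() <= 0.0 || q.min() <= 0.0)
    Rcpp::stop("sinkhorn_core requires strictly positive marginals");

  vec f = f0, g = g0;
  vec u(n, fill::ones), v(s, fill::ones);
  mat K(n, s);
  double err = datum::inf;
  bool converged = false;
  int iters = 0;

  // fast path for warm starts: if the supplied potentials are already close
  // (typical late in an outer optimisation loop), a short pass at the target
  // gamma converges directly and the annealing schedule is skipped
  if (warm_try > 0) {
    double wtol = std::max(tol, warm_tol);
    double shift0 = f.max() + g.max() - M.min();
    if (std::abs(shift0) / gamma > 100.0) f -= shift0;
    rebuild_kernel(K, f, g, M, gamma);
    bool warm_ok = false;
    sinkhorn_pass(p, q, M, gamma, warm_try, wtol, f, g, u, v, K, iters, err,
                  warm_ok);
    f += gamma * log(u);
    g += gamma * log(v);
    u.ones();
    v.ones();
    if (warm_ok) {
      anneal = false;
      converged = err < tol;
      if (!converged) {
        // close enough for a warm caller; report honestly via err/flag
        // but skip the expensive annealing restart
        max_iter = 0;
      }
    }
  }

  if (anneal && !converged) {
    // epsilon-scaling: solve a short schedule of decreasing gammas, carrying
    // the dual potentials down to the target; dramatically fewer iterations
    // than running Sinkhorn cold at a small gamma.
    std::vector<double> schedule;
    double gcur = std::max(gamma, 0.05 * M.max());
    while (gcur > gamma * 1.0001) {
      schedule.push_back(gcur);
      gcur *= 0.15;
    }
    for (double gstage : schedule) {
      bool stage_ok = false;  // stage convergence is at the stage gamma,
                              // never the caller's
      rebuild_kernel(K, f, g, M, gstage);
      sinkhorn_pass(p, q, M, gstage, 150, std::max(tol, 1e-4), f, g, u, v, K,
                    iters, err, stage_ok);
      f += gstage * log(u);
      g += gstage * log(v);
      u.ones();
      v.ones();
    }
  }

  if (!converged && max_iter > 0) {
    // normalise the kernel gauge so max(f_i + g_j - M_ij) ~ 0: a warm start
    // would otherwise over- or underflow exp()/gamma; the scaling vector u
    // absorbs the constant after one iteration.
    double shift = f.max() + g.max() - M.min();
    if (std::abs(shift) / gamma > 100.0) f -= shift;
    rebuild_kernel(K, f, g, M, gamma);
    sinkhorn_pass(p, q, M, gamma, max_iter, tol, f, g, u, v, K, iters, err,
                  converged);
  }

  // a capped, far-from-converged run can leave broken scaling factors;
  // drop them (the potentials keep the last absorbed state) rather than
  // propagate Inf/NaN into the plan
  auto keep_finite_pos = [](double x) {
    return (std::isfinite(x) && x > 0.0) ? x : 1.0;
  };
  u.transform(keep_finite_pos);
  v.transform(keep_finite_pos);
  f += gamma * log(u);
  g += gamma * log(v);
  f.transform([](double x) { return std::isfinite(x) ? x : 0.0; });
  g.transform([](double x) { return std::isfinite(x) ? x : 0.0; });
  mat plan(n, s);
  for (uword j = 0; j < s; ++j) {
    vec arg = (f + g(j) - M.col(j)) / gamma;
    arg.transform([](double x) { return x > 30.0 ? 30.0 : x; });
    plan.col(j) = exp(arg);
  }
  vec row_marg = sum(plan, 1);
  err = abs(row_marg - p).max();
  vec col_marg = sum(plan, 0).t();
  double err_c = abs(col_marg - q).max();
  if (err_c > err) err = err_c;
  if (err < tol) converged = true;

  return Rcpp::List::create(
      Rcpp::Named("f") = f, Rcpp::Named("g") = g, Rcpp::Named("plan") = plan,
      Rcpp::Named("iterations") = iters, Rcpp::Named("converged") = converged,
      Rcpp::Named("marginal_err") = err);
}
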