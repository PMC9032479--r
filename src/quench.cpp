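#include "salr.h"

// Inherent-structure quench: limited-memory BFGS with a monotone (Armijo)
// line search takes the configuration deep into its basin, then a damped
// Newton polish with the analytic Hessian finishes the job.  The Morse wall
// (rho = 30) makes the Hessian stiff (bond modes ~3.6e3 vs soft torsional
// modes), so first-order methods stall around |g| ~ 1e-6 where energy
// differences drop below double resolution; the Newton phase reaches the
// 1e-8 gradient tolerance in a handful of iterations.

namespace {

inline double dot(const std::vector<double>& a, const std::vector<double>& b) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * b[i];
  return s;
}

inline double norm2(const std::vector<double>& a) { return std::sqrt(dot(a, a)); }

// second derivative of the pair potential
inline double pair_d2vdr2(double r, const SalrParams& p) {
  const double e = std::exp(p.rho * (1.0 - r / p.sigma));
  const double d2m = 2.0 * p.rho * p.rho * p.eps_m / (p.sigma * p.sigma) *
                     e * (2.0 * e - 1.0);
  const double x = r / p.sigma;
  const double k = p.kappa_sigma;
  const double d2y = p.eps_y * std::exp(-k * (x - 1.0)) *
                     (k * k / x + 2.0 * k / (x * x) + 2.0 / (x * x * x)) /
                     (p.sigma * p.sigma);
  return d2m + d2y;
}

void cluster_hessian(const std::vector<double>& x, int n, const SalrParams& p,
                     std::vector<double>& h) {
  const int dim = 3 * n;
  h.assign(static_cast<size_t>(dim) * dim, 0.0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double u[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
      const double r = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      for (int c = 0; c < 3; ++c) u[c] /= r;
      const double v1 = pair_dvdr(r, p);
      const double v2 = pair_d2vdr2(r, p);
      for (int a = 0; a < 3; ++a) {
        for (int b = 0; b < 3; ++b) {
          const double blk = (v2 - v1 / r) * u[a] * u[b] +
                             (a == b ? v1 / r : 0.0);
          h[(3 * i + a) * dim + (3 * i + b)] += blk;
          h[(3 * j + a) * dim + (3 * j + b)] += blk;
          h[(3 * i + a) * dim + (3 * j + b)] -= blk;
          h[(3 * j + a) * dim + (3 * i + b)] -= blk;
        }
      }
    }
  }
}

// Cholesky solve of (A + mu I) d = -g; returns false if not positive definite.
bool chol_solve(std::vector<double> a, int dim, double mu,
                const std::vector<double>& g, std::vector<double>& d) {
  for (int i = 0; i < dim; ++i) a[i * dim + i] += mu;
  // in-place Cholesky, lower triangle
  for (int j = 0; j < dim; ++j) {
    double s = a[j * dim + j];
    for (int k = 0; k < j; ++k) s -= a[j * dim + k] * a[j * dim + k];
    if (s <= 0.0) return false;
    const double ljj = std::sqrt(s);
    a[j * dim + j] = ljj;
    for (int i = j + 1; i < dim; ++i) {
      double t = a[i * dim + j];
      for (int k = 0; k < j; ++k) t -= a[i * dim + k] * a[j * dim + k];
      a[i * dim + j] = t / ljj;
    }
  }
  d.assign(dim, 0.0);
  for (int i = 0; i < dim; ++i) {  // L y = -g
    double t = -g[i];
    for (int k = 0; k < i; ++k) t -= a[i * dim + k] * d[k];
    d[i] = t / a[i * dim + i];
  }
  for (int i = dim - 1; i >= 0; --i) {  // L^T d = y
    double t = d[i];
    for (int k = i + 1; k < dim; ++k) t -= a[k * dim + i] * d[k];
    d[i] = t / a[i * dim + i];
  }
  return true;
}

// Damped Newton iterations accepted on gradient-norm decrease.
int newton_polish(std::vector<double>& x, int n, const SalrParams& p,
                  double tol, int max_iter, std::vector<double>& g) {
  const int dim = 3 * n;
  std::vector<double> h, d(dim), x_new(dim), g_new(dim);
  double gn = norm2(g);
  double mu = 1e-6;
  int it = 0;
  for (; it < max_iter && gn >= tol; ++it) {
    cluster_hessian(x, n, p, h);
    bool improved = false;
    for (int trial = 0; trial < 25; ++trial) {
      if (chol_solve(h, dim, mu, g, d)) {
        for (int c = 0; c < dim; ++c) x_new[c] = x[c] + d[c];
        cluster_gradient_raw(x_new, n, p, g_new);
        const double gn_new = norm2(g_new);
        if (R_finite(gn_new) && gn_new < gn) {
          x = x_new;
          g = g_new;
          gn = gn_new;
          mu = std::max(mu * 0.25, 1e-10);
          improved = true;
          break;
        }
      }
      mu *= 10.0;
    }
    if (!improved) break;
  }
  return it;
}

}  // namespace

QuenchResult lbfgs_quench(std::vector<double>& x, int n, const SalrParams& p,
                          double tol, int max_iter) {
  const int dim = 3 * n;
  const int m_hist = 8;
  const double c1 = 1e-4;
  const double newton_gate = 1e-2;  // hand over to Newton below this |g|

  std::vector<std::vector<double> > s_hist, y_hist;
  std::vector<double> rho_hist;

  std::vector<double> g(dim), x_new(dim), g_new(dim), d(dim), q(dim);
  double f = cluster_energy_raw(x, n, p);
  cluster_gradient_raw(x, n, p, g);

  QuenchResult res;
  int it = 0;
  for (; it < max_iter; ++it) {
    const double gn = norm2(g);
    if (gn < tol || gn < newton_gate) break;
    // two-loop recursion for d = -H * g
    for (int i = 0; i < dim; ++i) q[i] = g[i];
    const int k = static_cast<int>(s_hist.size());
    std::vector<double> alpha(k);
    for (int i = k - 1; i >= 0; --i) {
      alpha[i] = rho_hist[i] * dot(s_hist[i], q);
      for (int c = 0; c < dim; ++c) q[c] -= alpha[i] * y_hist[i][c];
    }
    double gamma = 1.0;
    if (k > 0) {
      const double yy = dot(y_hist[k - 1], y_hist[k - 1]);
      if (yy > 0) gamma = dot(s_hist[k - 1], y_hist[k - 1]) / yy;
    }
    for (int c = 0; c < dim; ++c) q[c] *= gamma;
    for (int i = 0; i < k; ++i) {
      const double beta = rho_hist[i] * dot(y_hist[i], q);
      for (int c = 0; c < dim; ++c) q[c] += s_hist[i][c] * (alpha[i] - beta);
    }
    for (int c = 0; c < dim; ++c) d[c] = -q[c];

    double gd = dot(g, d);
    if (gd > -1e-14) {  // not a descent direction: restart from steepest descent
      for (int c = 0; c < dim; ++c) d[c] = -g[c];
      gd = -dot(g, g);
      s_hist.clear();
      y_hist.clear();
      rho_hist.clear();
    }
    // cap the initial trial step so no particle moves more than 0.5 sigma
    double dmax = 0.0;
    for (int c = 0; c < dim; ++c) dmax = std::max(dmax, std::fabs(d[c]));
    double step = (dmax > 0.5 * p.sigma) ? 0.5 * p.sigma / dmax : 1.0;

    double f_new = f;
    bool moved = false;
    for (int ls = 0; ls < 40; ++ls) {
      for (int c = 0; c < dim; ++c) x_new[c] = x[c] + step * d[c];
      f_new = cluster_energy_raw(x_new, n, p);
      if (R_finite(f_new) && f_new <= f + c1 * step * gd) {
        moved = true;
        break;
      }
      step *= 0.5;
    }
    if (!moved) break;  // energy differences exhausted: Newton takes over

    cluster_gradient_raw(x_new, n, p, g_new);
    std::vector<double> s(dim), y(dim);
    for (int c = 0; c < dim; ++c) {
      s[c] = x_new[c] - x[c];
      y[c] = g_new[c] - g[c];
    }
    const double sy = dot(s, y);
    if (sy > 1e-12) {
      s_hist.push_back(s);
      y_hist.push_back(y);
      rho_hist.push_back(1.0 / sy);
      if (static_cast<int>(s_hist.size()) > m_hist) {
        s_hist.erase(s_hist.begin());
        y_hist.erase(y_hist.begin());
        rho_hist.erase(rho_hist.begin());
      }
    }
    x.swap(x_new);
    g.swap(g_new);
    f = f_new;
  }
  it += newton_polish(x, n, p, tol, max_iter - it > 50 ? 50 : max_iter - it, g);
  res.energy = cluster_energy_raw(x, n, p);
  res.grad_norm = norm2(g);
  res.iterations = it;
  res.converged = res.grad_norm < tol;
  return res;
}
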