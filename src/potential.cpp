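#include "salr.h"

using namespace Rcpp;

double cluster_energy_raw(const std::vector<double>& x, int n, const SalrParams& p) {
  double v = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[3 * i] - x[3 * j];
      const double dy = x[3 * i + 1] - x[3 * j + 1];
      const double dz = x[3 * i + 2] - x[3 * j + 2];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      v += pair_e(r, p);
    }
  }
  return v;
}

void cluster_gradient_raw(const std::vector<double>& x, int n, const SalrParams& p,
                          std::vector<double>& g) {
  g.assign(3 * n, 0.0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[3 * i] - x[3 * j];
      const double dy = x[3 * i + 1] - x[3 * j + 1];
      const double dz = x[3 * i + 2] - x[3 * j + 2];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double f = pair_dvdr(r, p) / r;
      g[3 * i] += f * dx;
      g[3 * i + 1] += f * dy;
      g[3 * i + 2] += f * dz;
      g[3 * j] -= f * dx;
      g[3 * j + 1] -= f * dy;
      g[3 * j + 2] -= f * dz;
    }
  }
}

bool is_bound_raw(const std::vector<double>& x, int n, double r_cut, bool connected) {
  const double rc2 = r_cut * r_cut;
  std::vector<char> adj(static_cast<size_t>(n) * n, 0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[3 * i] - x[3 * j];
      const double dy = x[3 * i + 1] - x[3 * j + 1];
      const double dz = x[3 * i + 2] - x[3 * j + 2];
      if (dx * dx + dy * dy + dz * dz <= rc2) {
        adj[i * n + j] = adj[j * n + i] = 1;
      }
    }
  }
  if (!connected) {
    for (int i = 0; i < n; ++i) {
      bool has = false;
      for (int j = 0; j < n && !has; ++j) {
        if (j != i && adj[i * n + j]) has = true;
      }
      if (!has) return false;
    }
    return true;
  }
  // BFS from particle 0
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  stack.push_back(0);
  seen[0] = 1;
  int count = 1;
  while (!stack.empty()) {
    int i = stack.back();
    stack.pop_back();
    for (int j = 0; j < n; ++j) {
      if (!seen[j] && adj[i * n + j]) {
        seen[j] = 1;
        ++count;
        stack.push_back(j);
      }
    }
  }
  return count == n;
}

static std::vector<double> coords_to_vec(const NumericMatrix& coords) {
  const int n = coords.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = coords(i, 0);
    x[3 * i + 1] = coords(i, 1);
    x[3 * i + 2] = coords(i, 2);
  }
  return x;
}

// [[Rcpp::export]]
double cpp_cluster_energy(NumericMatrix coords, NumericVector params) {
  SalrParams p = params_from_vector(params);
  std::vector<double> x = coords_to_vec(coords);
  return cluster_energy_raw(x, coords.nrow(), p);
}

// [[Rcpp::export]]
NumericMatrix cpp_cluster_gradient(NumericMatrix coords, NumericVector params) {
  SalrParams p = params_from_vector(params);
  const int n = coords.nrow();
  std::vector<double> x = coords_to_vec(coords);
  std::vector<double> g;
  cluster_gradient_raw(x, n, p, g);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = g[3 * i];
    out(i, 1) = g[3 * i + 1];
    out(i, 2) = g[3 * i + 2];
  }
  return out;
}

// [[Rcpp::export]]
bool cpp_is_bound(NumericMatrix coords, double r_cut, bool connected) {
  std::vector<double> x = coords_to_vec(coords);
  return is_bound_raw(x, coords.nrow(), r_cut, connected);
}

// [[Rcpp::export]]
List cpp_relax(NumericMatrix coords, NumericVector params, double tol, int max_iter) {
  SalrParams p = params_from_vector(params);
  const int n = coords.nrow();
  std::vector<double> x = coords_to_vec(coords);
  QuenchResult qr = lbfgs_quench(x, n, p, tol, max_iter);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[3 * i];
    out(i, 1) = x[3 * i + 1];
    out(i, 2) = x[3 * i + 2];
  }
  return List::create(_["coords"] = out, _["energy"] = qr.energy,
                      _["grad_norm"] = qr.grad_norm, _["iterations"] = qr.iterations,
                      _["converged"] = qr.converged);
}

// Relax a stack of configurations stored as rows (x1 y1 z1 x2 y2 z2 ...).
// [[Rcpp::export]]
List cpp_relax_many(NumericMatrix stack, NumericVector params, double tol, int max_iter) {
  SalrParams p = params_from_vector(params);
  const int m = stack.nrow();
  const int n = stack.ncol() / 3;
  NumericMatrix out(m, 3 * n);
  NumericVector energies(m), gnorms(m);
  LogicalVector conv(m);
  std::vector<double> x(3 * n);
  for (int k = 0; k < m; ++k) {
    for (int c = 0; c < 3 * n; ++c) x[c] = stack(k, c);
    QuenchResult qr = lbfgs_quench(x, n, p, tol, max_iter);
    for (int c = 0; c < 3 * n; ++c) out(k, c) = x[c];
    energies[k] = qr.energy;
    gnorms[k] = qr.grad_norm;
    conv[k] = qr.converged;
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["coords"] = out, _["energy"] = energies,
                      _["grad_norm"] = gnorms, _["converged"] = conv);
}
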