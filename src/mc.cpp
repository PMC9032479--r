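#include "salr.h"

using namespace Rcpp;

// Parallel tempering engine.  Each replica owns its configuration, a cached
// pair-energy matrix and distance matrix (so one attempted single-particle
// move costs N-1 fresh pair evaluations), an adaptive maximum step size, and
// an independent PCG32 stream derived deterministically from the master seed,
// which makes whole runs bit-reproducible.  Replica exchange follows the
// deterministic even-odd (DEO) schedule on adjacent temperature pairs.

namespace {

struct Replica {
  std::vector<double> x;     // 3N coordinates
  std::vector<double> pe;    // N x N pair energies (symmetric, diag 0)
  std::vector<double> dist;  // N x N distances
  double energy;
  double step;
  long long att, acc;        // lifetime counters
  long long blk_att, blk_acc;  // current adaptation block
  Pcg32 rng;
};

void init_caches(Replica& r, int n, const SalrParams& p) {
  r.pe.assign(static_cast<size_t>(n) * n, 0.0);
  r.dist.assign(static_cast<size_t>(n) * n, 0.0);
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = r.x[3 * i] - r.x[3 * j];
      const double dy = r.x[3 * i + 1] - r.x[3 * j + 1];
      const double dz = r.x[3 * i + 2] - r.x[3 * j + 2];
      const double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double v = pair_e_fast_impl(rr, p);
      r.dist[i * n + j] = r.dist[j * n + i] = rr;
      r.pe[i * n + j] = r.pe[j * n + i] = v;
      e += v;
    }
  }
  r.energy = e;
}

double energy_from_cache(const Replica& r, int n) {
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) e += r.pe[i * n + j];
  return e;
}

// scratch buffers reused across attempts (BFS allocation is off the hot path)
struct Workspace {
  std::vector<double> rnew, penew;
  std::vector<char> seen;
  std::vector<int> stack;
  Workspace(int n) : rnew(n), penew(n), seen(n), stack() { stack.reserve(n); }
};

// Boundedness of the trial configuration in which particle i has the
// distances rnew[] to all others; all other pairs keep the cached distances.
bool trial_bound(const Replica& r, int n, int i, Workspace& ws, double r_cut,
                 bool connected) {
  const std::vector<double>& rnew = ws.rnew;
  if (!connected) {
    for (int k = 0; k < n; ++k) {
      bool has = false;
      for (int j = 0; j < n && !has; ++j) {
        if (j == k) continue;
        const double d = (k == i) ? rnew[j] : (j == i ? rnew[k] : r.dist[k * n + j]);
        if (d <= r_cut) has = true;
      }
      if (!has) return false;
    }
    return true;
  }
  // fast path: if the move breaks none of i's current bonds, the trial graph
  // is a supergraph of the current (connected) one
  bool lost = false;
  bool has_new = false;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    if (rnew[j] <= r_cut) has_new = true;
    if (r.dist[i * n + j] <= r_cut && rnew[j] > r_cut) {
      lost = true;
      break;
    }
  }
  if (!lost) return has_new;
  std::fill(ws.seen.begin(), ws.seen.end(), 0);
  ws.stack.clear();
  ws.stack.push_back(0);
  ws.seen[0] = 1;
  int count = 1;
  while (!ws.stack.empty()) {
    const int k = ws.stack.back();
    ws.stack.pop_back();
    for (int j = 0; j < n; ++j) {
      if (ws.seen[j] || j == k) continue;
      const double d = (k == i) ? rnew[j] : (j == i ? rnew[k] : r.dist[k * n + j]);
      if (d <= r_cut) {
        ws.seen[j] = 1;
        ++count;
        ws.stack.push_back(j);
      }
    }
  }
  return count == n;
}

// One attempted single-particle displacement (one "MC step").
void attempt_move(Replica& r, int n, double temp, const SalrParams& p, bool connected,
                  Workspace& ws) {
  std::vector<double>& rnew = ws.rnew;
  std::vector<double>& penew = ws.penew;
  const int i = r.rng.uniform_int(n);
  const double nx = r.x[3 * i] + (2.0 * r.rng.uniform() - 1.0) * r.step;
  const double ny = r.x[3 * i + 1] + (2.0 * r.rng.uniform() - 1.0) * r.step;
  const double nz = r.x[3 * i + 2] + (2.0 * r.rng.uniform() - 1.0) * r.step;
  double d_e = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    const double dx = nx - r.x[3 * j];
    const double dy = ny - r.x[3 * j + 1];
    const double dz = nz - r.x[3 * j + 2];
    const double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
    rnew[j] = rr;
    penew[j] = pair_e_fast_impl(rr, p);
    d_e += penew[j] - r.pe[i * n + j];
  }
  bool accept = false;
  if (R_finite(d_e)) {
    if (d_e <= 0.0) {
      accept = true;
    } else {
      accept = r.rng.uniform() < fast_exp(-d_e / temp);
    }
  }
  // rupture-rejection criterion: a Metropolis-accepted move is still refused
  // if it leaves the cluster unbound under the cutoff test
  if (accept && !trial_bound(r, n, i, ws, p.r_cut, connected)) accept = false;
  ++r.att;
  ++r.blk_att;
  if (accept) {
    ++r.acc;
    ++r.blk_acc;
    r.x[3 * i] = nx;
    r.x[3 * i + 1] = ny;
    r.x[3 * i + 2] = nz;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      r.dist[i * n + j] = r.dist[j * n + i] = rnew[j];
      r.pe[i * n + j] = r.pe[j * n + i] = penew[j];
    }
    r.energy += d_e;
  }
}

void adapt_step(Replica& r, int n, double target, double sigma) {
  const double rate = static_cast<double>(r.blk_acc) / static_cast<double>(r.blk_att);
  double fac = rate / target;
  if (fac < 0.5) fac = 0.5;
  if (fac > 2.0) fac = 2.0;
  r.step *= fac;
  if (r.step < 1e-4) r.step = 1e-4;
  if (r.step > 2.0 * sigma) r.step = 2.0 * sigma;
  r.blk_att = 0;
  r.blk_acc = 0;
  r.energy = energy_from_cache(r, n);  // resynchronize against drift
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_ptmc(NumericMatrix coords0, NumericVector params, NumericVector temps,
                  double n_therm, double n_prod, int swap_stride, int record_stride,
                  int sample_stride, int adapt_block, double target_acc, double step0,
                  bool connected, double master_seed, int run_id, bool store_samples,
                  bool adapt) {
  const SalrParams p = params_from_vector(params);
  const int n = coords0.nrow();
  const int m = temps.size();
  if (n < 2) stop("need at least two particles");
  if (m < 1) stop("need at least one temperature");

  const std::uint64_t base =
      splitmix64(splitmix64(static_cast<std::uint64_t>(master_seed)) ^
                 (0x5bd1e995ULL * static_cast<std::uint64_t>(run_id + 1)));

  std::vector<Replica> reps(m);
  for (int k = 0; k < m; ++k) {
    reps[k].x.resize(3 * n);
    for (int i = 0; i < n; ++i) {
      reps[k].x[3 * i] = coords0(i, 0);
      reps[k].x[3 * i + 1] = coords0(i, 1);
      reps[k].x[3 * i + 2] = coords0(i, 2);
    }
    init_caches(reps[k], n, p);
    reps[k].step = step0;
    reps[k].att = reps[k].acc = reps[k].blk_att = reps[k].blk_acc = 0;
    reps[k].rng.seed(splitmix64(base + static_cast<std::uint64_t>(k)),
                     static_cast<std::uint64_t>(k));
  }
  if (!is_bound_raw(reps[0].x, n, p.r_cut, connected))
    stop("seed structure is not bound under the cutoff criterion");

  Pcg32 swap_rng;
  swap_rng.seed(splitmix64(base + 0x9e3779b9ULL), static_cast<std::uint64_t>(m) + 7u);

  const long long therm = static_cast<long long>(n_therm);
  const long long prod = static_cast<long long>(n_prod);
  const long long total = therm + prod;
  const long long n_rec = (record_stride > 0) ? prod / record_stride : 0;
  const long long n_samp =
      (store_samples && sample_stride > 0) ? prod / sample_stride : 0;

  NumericMatrix traces(static_cast<int>(n_rec), m);
  List samples(m);
  if (n_samp > 0) {
    for (int k = 0; k < m; ++k) samples[k] = NumericMatrix(static_cast<int>(n_samp), 3 * n);
  }

  std::vector<long long> swap_att(std::max(m - 1, 0), 0), swap_acc(std::max(m - 1, 0), 0);
  Workspace ws(n);
  long long done = 0;
  long long round_index = 0;
  while (done < total) {
    const long long chunk = std::min<long long>(swap_stride, total - done);
    for (int k = 0; k < m; ++k) {
      Replica& r = reps[k];
      for (long long s = 0; s < chunk; ++s) {
        attempt_move(r, n, temps[k], p, connected, ws);
        if (adapt && adapt_block > 0 && r.blk_att >= adapt_block)
          adapt_step(r, n, target_acc, p.sigma);
        const long long idx = done + s + 1;
        if (idx > therm) {
          const long long pa = idx - therm;
          if (record_stride > 0 && pa % record_stride == 0)
            traces(static_cast<int>(pa / record_stride) - 1, k) = r.energy;
          if (n_samp > 0 && pa % sample_stride == 0) {
            NumericMatrix sm = samples[k];
            const int row = static_cast<int>(pa / sample_stride) - 1;
            for (int c = 0; c < 3 * n; ++c) sm(row, c) = r.x[c];
          }
        }
      }
    }
    done += chunk;
    if (m > 1 && done < total) {
      const int start = (round_index % 2 == 0) ? 0 : 1;
      for (int a = start; a + 1 < m; a += 2) {
        const double prob_exp = (reps[a].energy - reps[a + 1].energy) *
                                (1.0 / temps[a] - 1.0 / temps[a + 1]);
        const double u = swap_rng.uniform();
        ++swap_att[a];
        if (prob_exp >= 0.0 || u < std::exp(prob_exp)) {
          ++swap_acc[a];
          std::swap(reps[a].x, reps[a + 1].x);
          std::swap(reps[a].pe, reps[a + 1].pe);
          std::swap(reps[a].dist, reps[a + 1].dist);
          std::swap(reps[a].energy, reps[a + 1].energy);
        }
      }
      ++round_index;
    }
    if ((done / std::max(1, swap_stride)) % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List finals(m);
  NumericVector energy(m), steps(m), acc_rate(m);
  for (int k = 0; k < m; ++k) {
    NumericMatrix fc(n, 3);
    for (int i = 0; i < n; ++i) {
      fc(i, 0) = reps[k].x[3 * i];
      fc(i, 1) = reps[k].x[3 * i + 1];
      fc(i, 2) = reps[k].x[3 * i + 2];
    }
    finals[k] = fc;
    energy[k] = energy_from_cache(reps[k], n);
    steps[k] = reps[k].step;
    acc_rate[k] = reps[k].att > 0
                      ? static_cast<double>(reps[k].acc) / static_cast<double>(reps[k].att)
                      : NA_REAL;
  }
  return List::create(
      _["temps"] = temps, _["traces"] = traces, _["samples"] = samples,
      _["final_coords"] = finals, _["final_energy"] = energy,
      _["step_sizes"] = steps, _["acceptance"] = acc_rate,
      _["swap_attempts"] = IntegerVector(swap_att.begin(), swap_att.end()),
      _["swap_accepts"] = IntegerVector(swap_acc.begin(), swap_acc.end()),
      _["rounds"] = static_cast<double>(round_index));
}
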