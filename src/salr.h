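#ifndef SALRMC_SALR_H
#define SALRMC_SALR_H

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <vector>

// SALR pair potential parameters, reduced units (k = 1, lengths in sigma).
struct SalrParams {
  double rho;          // Morse range parameter
  double eps_m;        // Morse well depth
  double sigma;        // particle diameter (unit of length)
  double eps_y;        // Yukawa strength
  double kappa_sigma;  // inverse Debye length times sigma
  double r_cut;        // bound-interaction cutoff (boundedness test only)
};

inline SalrParams params_from_vector(const Rcpp::NumericVector& p) {
  SalrParams q;
  q.rho = p[0];
  q.eps_m = p[1];
  q.sigma = p[2];
  q.eps_y = p[3];
  q.kappa_sigma = p[4];
  q.r_cut = p[5];
  return q;
}

inline double morse_e(double r, const SalrParams& p) {
  const double e = std::exp(p.rho * (1.0 - r / p.sigma));
  return p.eps_m * e * (e - 2.0);
}

inline double yukawa_e(double r, const SalrParams& p) {
  const double x = r / p.sigma;
  return p.eps_y * std::exp(-p.kappa_sigma * (x - 1.0)) / x;
}

inline double pair_e(double r, const SalrParams& p) {
  return morse_e(r, p) + yukawa_e(r, p);
}



// dV/dr of the pair potential
inline double pair_dvdr(double r, const SalrParams& p) {
  const double e = std::exp(p.rho * (1.0 - r / p.sigma));
  const double dmorse = -2.0 * p.rho * p.eps_m / p.sigma * e * (e - 1.0);
  const double x = r / p.sigma;
  const double dyuk = p.eps_y * std::exp(-p.kappa_sigma * (x - 1.0)) *
                      (-p.kappa_sigma / x - 1.0 / (x * x)) / p.sigma;
  return dmorse + dyuk;
}

// Fast exp for the Monte Carlo hot path: argument reduction against a
// two-part ln(2) plus a degree-10 polynomial on the reduced interval, then an
// exponent-bit scale.  Relative accuracy ~2e-14 over the normal range --
// far below the 1e-6 energy-identity tolerance used anywhere downstream.
inline double fast_exp(double x) {
  if (x > 709.0) return std::numeric_limits<double>::infinity();
  if (x < -745.0) return 0.0;
  const double LOG2E = 1.4426950408889634074;
  const double C1 = 6.93145751953125e-1;     // high part of ln 2
  const double C2 = 1.42860682030941723212e-6;  // low part of ln 2
  double k = std::floor(LOG2E * x + 0.5);
  double r = (x - k * C1) - k * C2;
  // Taylor polynomial of exp on |r| <= 0.3466, Horner form
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.6666666666666666e-1 +
             r * (4.1666666666666664e-2 + r * (8.3333333333333332e-3 +
             r * (1.3888888888888889e-3 + r * (1.9841269841269841e-4 +
             r * (2.4801587301587302e-5 + r * (2.7557319223985893e-6 +
             r * 2.7557319223985888e-7)))))))));
  // scale by 2^k through the exponent bits (|k| <= 1075 here)
  int ik = static_cast<int>(k);
  if (ik > 1023) {  // spill into two scales to avoid overflow in the bits
    return p * std::ldexp(1.0, ik);
  }
  union {
    double d;
    std::uint64_t u;
  } s;
  if (ik < -1022) {  // subnormal range: fall back to ldexp
    return std::ldexp(p, ik);
  }
  s.u = static_cast<std::uint64_t>(ik + 1023) << 52;
  return p * s.d;
}

inline double pair_e_fast_impl(double r, const SalrParams& p) {
  const double e = fast_exp(p.rho * (1.0 - r / p.sigma));
  const double x = r / p.sigma;
  return p.eps_m * e * (e - 2.0) +
         p.eps_y * fast_exp(-p.kappa_sigma * (x - 1.0)) / x;
}

double cluster_energy_raw(const std::vector<double>& x, int n, const SalrParams& p);
void cluster_gradient_raw(const std::vector<double>& x, int n, const SalrParams& p,
                          std::vector<double>& g);
bool is_bound_raw(const std::vector<double>& x, int n, double r_cut, bool connected);

// L-BFGS quench; returns final energy, writes relaxed coords in place.
struct QuenchResult {
  double energy;
  double grad_norm;
  int iterations;
  bool converged;
};
QuenchResult lbfgs_quench(std::vector<double>& x, int n, const SalrParams& p,
                          double tol, int max_iter);

// PCG32 random stream (O'Neill); one independent stream per replica.
struct Pcg32 {
  std::uint64_t state;
  std::uint64_t inc;
  void seed(std::uint64_t initstate, std::uint64_t initseq) {
    state = 0u;
    inc = (initseq << 1u) | 1u;
    next();
    state += initstate;
    next();
  }
  std::uint32_t next() {
    std::uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    std::uint32_t xorshifted = static_cast<std::uint32_t>(((old >> 18u) ^ old) >> 27u);
    std::uint32_t rot = static_cast<std::uint32_t>(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double uniform() {  // in [0, 1)
    return next() * (1.0 / 4294967296.0);
  }
  int uniform_int(int n) {  // in 0..n-1, negligible modulo bias for small n
    return static_cast<int>(next() % static_cast<std::uint32_t>(n));
  }
};

inline std::uint64_t splitmix64(std::uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

#endif
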