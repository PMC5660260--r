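#ifndef VWFMARG_ENGINE_H
#define VWFMARG_ENGINE_H

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

// ---- counter-based RNG -------------------------------------------------
// splitmix64 keyed by (seed, step, i, j): the random pair force is
// reproducible independent of pair enumeration order.
static inline uint64_t sm64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double u01(uint64_t h) {
  // 53-bit mantissa uniform in (0,1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// symmetric unit-variance draw for the DPD random force
static inline double pair_xi(uint64_t seed, uint64_t step, int i, int j) {
  if (i > j) { int t = i; i = j; j = t; }
  uint64_t key = sm64(seed ^ sm64(step ^ 0x5bf03635ULL));
  uint64_t h = sm64(key ^ (((uint64_t)(uint32_t)i << 32) | (uint32_t)j));
  return 1.7320508075688772 * (2.0 * u01(h) - 1.0);
}

// species codes
enum { SP_FLUID = 0, SP_WALL = 1, SP_RBC = 2, SP_VWF = 3, SP_REP = 4 };

// force components
enum {
  C_CONS = 1, C_DISS = 2, C_RAND = 4,
  C_BOND = 8, C_LJ = 16, C_CROSS = 32,
  C_SPRING = 64, C_BEND = 128, C_AREA = 256,
  C_ALL = 0x7fffffff
};

struct Ring {
  int start, n;
  int form;          // 0 = wlc+pow, 1 = harmonic
  double p, l0, lm, kp, k_harm;
  double kb, theta0;
  double ka, A0;
};

struct Chain {
  int start, n;
  int mode;          // 0 = attractive, 1 = repulsive
  double ks, lb, sigma, eps;
};

struct PairParams {
  double a, gamma, s, rc, kBT;
  double gamma_fs;
  double sig_mem, eps_mem, sig_cross, eps_cross, sig_chain, eps_chain;
};

struct System {
  int N;
  std::vector<int> species, sid, bidx;
  std::vector<char> mobile;
  double Lx, W;
  bool per_x, per_y;
  double ypad;       // wall slab thickness beyond [0, W] (0 if periodic y)
  double mass;
  PairParams pp;
  std::vector<Ring> rings;
  std::vector<Chain> chains;
};

// truncated-shifted LJ; repulsive = WCA (cut at 2^(1/6) sigma), attractive
// cut at 2.5 sigma. Returns scalar force f (positive = repulsive) such that
// force on i is f * rhat_ij; adds energy to *u if requested.
static inline double lj_scalar(double r, double sigma, double eps,
                               bool attractive, double* u) {
  double cut = attractive ? 2.5 * sigma : 1.1224620483089301 * sigma;
  if (r >= cut) return 0.0;
  double sr2 = sigma * sigma / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double f = 24.0 * eps * (2.0 * sr12 - sr6) / r;
  if (u) {
    double ushift;
    if (attractive) {
      double c2 = sigma * sigma / (cut * cut);
      double c6 = c2 * c2 * c2;
      ushift = 4.0 * eps * (c6 * c6 - c6);
    } else {
      ushift = -eps;
    }
    *u += 4.0 * eps * (sr12 - sr6) - ushift;
  }
  return f;
}

System parse_system(const Rcpp::List& sys);

void compute_forces(const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<double>& vx, const std::vector<double>& vy,
                    std::vector<double>& fx, std::vector<double>& fy,
                    const System& S, double dt, uint64_t seed, uint64_t step,
                    int mask);

Rcpp::NumericVector energy_terms(const std::vector<double>& x,
                                 const std::vector<double>& y,
                                 const System& S, int mask);

#endif
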