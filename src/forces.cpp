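#include "engine.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// system parsing
// ---------------------------------------------------------------------------

System parse_system(const List& sys) {
  System S;
  IntegerVector sp = sys["species"];
  IntegerVector sid = sys["sid"];
  IntegerVector bidx = sys["bidx"];
  LogicalVector mob = sys["mobile"];
  S.N = sp.size();
  S.species.assign(sp.begin(), sp.end());
  S.sid.assign(sid.begin(), sid.end());
  S.bidx.assign(bidx.begin(), bidx.end());
  S.mobile.resize(S.N);
  for (int i = 0; i < S.N; ++i) S.mobile[i] = mob[i] ? 1 : 0;
  S.Lx = as<double>(sys["Lx"]);
  S.W = as<double>(sys["W"]);
  S.per_x = as<bool>(sys["per_x"]);
  S.per_y = as<bool>(sys["per_y"]);
  S.ypad = as<double>(sys["ypad"]);
  S.mass = as<double>(sys["mass"]);

  List pp = sys["pair"];
  S.pp.a = as<double>(pp["a"]);
  S.pp.gamma = as<double>(pp["gamma"]);
  S.pp.s = as<double>(pp["s"]);
  S.pp.rc = as<double>(pp["rc"]);
  S.pp.kBT = as<double>(pp["kBT"]);
  S.pp.gamma_fs = as<double>(pp["gamma_fs"]);
  S.pp.sig_mem = as<double>(pp["sig_mem"]);
  S.pp.eps_mem = as<double>(pp["eps_mem"]);
  S.pp.sig_cross = as<double>(pp["sig_cross"]);
  S.pp.eps_cross = as<double>(pp["eps_cross"]);
  S.pp.sig_chain = as<double>(pp["sig_chain"]);
  S.pp.eps_chain = as<double>(pp["eps_chain"]);

  List rings = sys["rings"];
  for (int k = 0; k < rings.size(); ++k) {
    List r = rings[k];
    Ring R;
    R.start = as<int>(r["start"]);
    R.n = as<int>(r["n"]);
    R.form = as<int>(r["form"]);
    R.p = as<double>(r["p"]);
    R.l0 = as<double>(r["l0"]);
    R.lm = as<double>(r["lm"]);
    R.kp = as<double>(r["kp"]);
    R.k_harm = as<double>(r["k_harm"]);
    R.kb = as<double>(r["kb"]);
    R.theta0 = as<double>(r["theta0"]);
    R.ka = as<double>(r["ka"]);
    R.A0 = as<double>(r["A0"]);
    S.rings.push_back(R);
  }
  List chains = sys["chains"];
  for (int k = 0; k < chains.size(); ++k) {
    List c = chains[k];
    Chain C;
    C.start = as<int>(c["start"]);
    C.n = as<int>(c["n"]);
    C.mode = as<int>(c["mode"]);
    C.ks = as<double>(c["ks"]);
    C.lb = as<double>(c["lb"]);
    C.sigma = as<double>(c["sigma"]);
    C.eps = as<double>(c["eps"]);
    S.chains.push_back(C);
  }
  return S;
}

// minimum-image displacement from j to i
static inline void min_image(const System& S, double dx, double dy,
                             double& ox, double& oy) {
  if (S.per_x) {
    if (dx > 0.5 * S.Lx) dx -= S.Lx;
    else if (dx < -0.5 * S.Lx) dx += S.Lx;
  }
  if (S.per_y) {
    if (dy > 0.5 * S.W) dy -= S.W;
    else if (dy < -0.5 * S.W) dy += S.W;
  }
  ox = dx; oy = dy;
}

// ---------------------------------------------------------------------------
// pair interactions
// ---------------------------------------------------------------------------

// WLC (attractive) + power-law (repulsive) ring spring; positive = repulsive
static inline double ring_spring_scalar(const Ring& R, double kBT, double r,
                                        double* u) {
  if (R.form == 1) {
    if (u) *u += 0.5 * R.k_harm * (r - R.l0) * (r - R.l0);
    return -R.k_harm * (r - R.l0);
  }
  double x = r / R.lm;
  // clamp the WLC divergence: linear force continuation beyond x = 0.95
  // keeps transient overshoots during relaxation integrable
  double xe = (x < 0.95) ? x : 0.95;
  double om = 1.0 - xe;
  double fwlc = (kBT / R.p) * (0.25 / (om * om) - 0.25 + xe);
  if (x > 0.95) {
    double slope = (kBT / R.p) * (0.5 / (om * om * om) + 1.0);
    fwlc += slope * (x - 0.95);
  }
  if (u) {
    *u += kBT * R.lm * (3.0 * xe * xe - 2.0 * xe * xe * xe) / (4.0 * R.p * om)
        + R.kp / r;
  }
  return R.kp / (r * r) - fwlc;
}

// ---------------------------------------------------------------------------
// cell list
// ---------------------------------------------------------------------------

struct CellList {
  int nx, ny;
  double x0, y0, cw, chh;
  std::vector<int> head, nxt;
  bool per_x, per_y;
};

static void build_cells(CellList& cl, const std::vector<double>& x,
                        const std::vector<double>& y, const System& S,
                        double cutoff) {
  double ymin = S.per_y ? 0.0 : -S.ypad;
  double yext = S.per_y ? S.W : (S.W + 2.0 * S.ypad);
  cl.per_x = S.per_x; cl.per_y = S.per_y;
  cl.nx = std::max(1, (int)std::floor(S.Lx / cutoff));
  cl.ny = std::max(1, (int)std::floor(yext / cutoff));
  if (S.per_x && cl.nx < 3) cl.nx = 1;  // degenerate: single cell column
  if (S.per_y && cl.ny < 3) cl.ny = 1;
  cl.x0 = 0.0; cl.y0 = ymin;
  cl.cw = S.Lx / cl.nx;
  cl.chh = yext / cl.ny;
  int N = (int)x.size();
  cl.head.assign(cl.nx * cl.ny, -1);
  cl.nxt.assign(N, -1);
  for (int i = 0; i < N; ++i) {
    int cx = (int)std::floor((x[i] - cl.x0) / cl.cw);
    int cy = (int)std::floor((y[i] - cl.y0) / cl.chh);
    if (cx < 0) cx = 0; if (cx >= cl.nx) cx = cl.nx - 1;
    if (cy < 0) cy = 0; if (cy >= cl.ny) cy = cl.ny - 1;
    int c = cy * cl.nx + cx;
    cl.nxt[i] = cl.head[c];
    cl.head[c] = i;
  }
}

// visit all unordered pairs with distance < cutoff via half stencil
template <typename F>
static void for_pairs(const CellList& cl, const std::vector<double>& x,
                      const std::vector<double>& y, const System& S,
                      double cutoff, F&& fn) {
  double c2 = cutoff * cutoff;
  // offsets: self handled separately; half stencil E, NW, N, NE
  const int offs[4][2] = { {1, 0}, {-1, 1}, {0, 1}, {1, 1} };
  for (int cy = 0; cy < cl.ny; ++cy) {
    for (int cx = 0; cx < cl.nx; ++cx) {
      int c = cy * cl.nx + cx;
      // pairs within the cell
      for (int i = cl.head[c]; i >= 0; i = cl.nxt[i]) {
        for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j]) {
          double dx, dy;
          min_image(S, x[i] - x[j], y[i] - y[j], dx, dy);
          double r2 = dx * dx + dy * dy;
          if (r2 < c2) fn(i, j, dx, dy, r2);
        }
      }
      // neighbours (dedup guards against degenerate small periodic grids,
      // where distinct stencil offsets can alias the same cell)
      int seen[4]; int nseen = 0;
      for (int k = 0; k < 4; ++k) {
        int ox = cx + offs[k][0], oy = cy + offs[k][1];
        if (cl.per_x) { if (ox < 0) ox += cl.nx; if (ox >= cl.nx) ox -= cl.nx; }
        else if (ox < 0 || ox >= cl.nx) continue;
        if (cl.per_y) { if (oy < 0) oy += cl.ny; if (oy >= cl.ny) oy -= cl.ny; }
        else if (oy < 0 || oy >= cl.ny) continue;
        if (ox == cx && oy == cy) continue;  // tiny grids
        int c2i = oy * cl.nx + ox;
        bool dup = false;
        for (int q = 0; q < nseen; ++q) if (seen[q] == c2i) dup = true;
        if (dup) continue;
        seen[nseen++] = c2i;
        for (int i = cl.head[c]; i >= 0; i = cl.nxt[i]) {
          for (int j = cl.head[c2i]; j >= 0; j = cl.nxt[j]) {
            double dx, dy;
            min_image(S, x[i] - x[j], y[i] - y[j], dx, dy);
            double r2 = dx * dx + dy * dy;
            if (r2 < c2) fn(i, j, dx, dy, r2);
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// nonbonded forces
// ---------------------------------------------------------------------------

static void nonbonded_forces(const std::vector<double>& x,
                             const std::vector<double>& y,
                             const std::vector<double>& vx,
                             const std::vector<double>& vy,
                             std::vector<double>& fx, std::vector<double>& fy,
                             const System& S, double dt, uint64_t seed,
                             uint64_t step, int mask) {
  const PairParams& P = S.pp;
  double inv_sqrt_dt = 1.0 / std::sqrt(dt);
  double sig_ff = std::sqrt(2.0 * P.gamma * P.kBT);
  double sig_fs = std::sqrt(2.0 * P.gamma_fs * P.kBT);
  CellList cl;
  build_cells(cl, x, y, S, P.rc);
  for_pairs(cl, x, y, S, P.rc, [&](int i, int j, double dx, double dy, double r2) {
    int si = S.species[i], sj = S.species[j];
    bool wi = (si == SP_WALL), wj = (sj == SP_WALL);
    if (wi && wj) return;
    bool flu_i = (si <= SP_WALL), flu_j = (sj <= SP_WALL);
    if (!flu_i && !flu_j && S.sid[i] == S.sid[j]) return;  // intra-structure: bonded terms
    if (r2 < 1e-24)
      stop("degenerate pair: particles %d and %d overlap", i + 1, j + 1);
    double r = std::sqrt(r2);
    double rinv = 1.0 / r;
    double ex = dx * rinv, ey = dy * rinv;
    double f = 0.0;
    if (flu_i && flu_j) {
      // fluid-fluid / fluid-wall: full DPD
      double w = 1.0 - r / P.rc;
      if (mask & C_CONS) f += P.a * w;
      double wr = (P.s == 1.0) ? w : std::pow(w, P.s);
      if (mask & C_DISS) {
        double vdotr = (vx[i] - vx[j]) * ex + (vy[i] - vy[j]) * ey;
        f -= P.gamma * wr * wr * vdotr;
      }
      if (mask & C_RAND)
        f += sig_ff * wr * pair_xi(seed, step, i, j) * inv_sqrt_dt;
    } else if (flu_i || flu_j) {
      // fluid/wall with a structure bead: viscous coupling only (no
      // conservative term): the solvent couples through friction
      double w = 1.0 - r / P.rc;
      double wr = (P.s == 1.0) ? w : std::pow(w, P.s);
      if (mask & C_DISS) {
        double vdotr = (vx[i] - vx[j]) * ex + (vy[i] - vy[j]) * ey;
        f -= P.gamma_fs * wr * wr * vdotr;
      }
      if (mask & C_RAND)
        f += sig_fs * wr * pair_xi(seed, step, i, j) * inv_sqrt_dt;
    } else if (mask & C_CROSS) {
      // structure-structure, different structures: excluded volume
      bool mem_i = (si == SP_RBC), mem_j = (sj == SP_RBC);
      if (mem_i && mem_j)
        f += lj_scalar(r, P.sig_mem, P.eps_mem, false, nullptr);
      else if (mem_i || mem_j)
        f += lj_scalar(r, P.sig_cross, P.eps_cross, false, nullptr);
      else
        f += lj_scalar(r, P.sig_chain, P.eps_chain, false, nullptr);
    }
    fx[i] += f * ex; fy[i] += f * ey;
    fx[j] -= f * ex; fy[j] -= f * ey;
  });
}

// ---------------------------------------------------------------------------
// bonded terms
// ---------------------------------------------------------------------------

// unwrap a contiguous block of n beads along the periodic axes by walking
// the bonds; scratch vectors are resized by the caller
static void unwrap_block(const std::vector<double>& x, const std::vector<double>& y,
                         const System& S, int start, int n, bool ring_close,
                         std::vector<double>& ux, std::vector<double>& uy) {
  ux.resize(n); uy.resize(n);
  ux[0] = x[start]; uy[0] = y[start];
  for (int k = 1; k < n; ++k) {
    double dx, dy;
    min_image(S, x[start + k] - x[start + k - 1], y[start + k] - y[start + k - 1], dx, dy);
    ux[k] = ux[k - 1] + dx;
    uy[k] = uy[k - 1] + dy;
  }
  (void)ring_close;
}

static void ring_forces(const std::vector<double>& x, const std::vector<double>& y,
                        std::vector<double>& fx, std::vector<double>& fy,
                        const System& S, int mask, double* u_spring,
                        double* u_bend, double* u_area) {
  std::vector<double> ux, uy;
  for (const Ring& R : S.rings) {
    unwrap_block(x, y, S, R.start, R.n, true, ux, uy);
    int n = R.n;
    // springs along the closed ring
    if (mask & C_SPRING) {
      for (int k = 0; k < n; ++k) {
        int k2 = (k + 1) % n;
        double dx = ux[k2] - ux[k], dy = uy[k2] - uy[k];
        if (k2 == 0) { // closing bond: use minimum image directly
          min_image(S, x[R.start] - x[R.start + n - 1], y[R.start] - y[R.start + n - 1], dx, dy);
        }
        double r = std::sqrt(dx * dx + dy * dy);
        if (r < 1e-12) stop("ring spring with zero length");
        double f = ring_spring_scalar(R, S.pp.kBT, r, u_spring);
        double ex = dx / r, ey = dy / r;
        // f > 0 pushes k2 away from k
        fx[R.start + k2] += f * ex; fy[R.start + k2] += f * ey;
        fx[R.start + k] -= f * ex;  fy[R.start + k] -= f * ey;
      }
    }
    // bending on every vertex angle
    if (mask & C_BEND) {
      for (int k = 0; k < n; ++k) {
        int km = (k - 1 + n) % n, kp = (k + 1) % n;
        double b1x, b1y, b2x, b2y;
        min_image(S, x[R.start + k] - x[R.start + km], y[R.start + k] - y[R.start + km], b1x, b1y);
        min_image(S, x[R.start + kp] - x[R.start + k], y[R.start + kp] - y[R.start + k], b2x, b2y);
        double n1 = b1x * b1x + b1y * b1y, n2 = b2x * b2x + b2y * b2y;
        if (n1 < 1e-24 || n2 < 1e-24) stop("degenerate bending triple (zero bond length)");
        double theta = std::atan2(b1x * b2y - b1y * b2x, b1x * b2x + b1y * b2y);
        double dudth = R.kb * std::sin(theta - R.theta0);
        if (u_bend) *u_bend += R.kb * (1.0 - std::cos(theta - R.theta0));
        // d theta / d b1 = -b1_perp / |b1|^2 ; d theta / d b2 = b2_perp / |b2|^2
        double g1x = -(-b1y) / n1, g1y = -(b1x) / n1;
        double g2x = (-b2y) / n2,  g2y = (b2x) / n2;
        // b1 = r_k - r_km, b2 = r_kp - r_k
        fx[R.start + km] += dudth * g1x;        fy[R.start + km] += dudth * g1y;
        fx[R.start + k]  -= dudth * (g1x - g2x); fy[R.start + k] -= dudth * (g1y - g2y);
        fx[R.start + kp] -= dudth * g2x;        fy[R.start + kp] -= dudth * g2y;
      }
    }
    // global area constraint (shoelace on the unwrapped polygon)
    if (mask & C_AREA) {
      double A = 0.0;
      for (int k = 0; k < n; ++k) {
        int k2 = (k + 1) % n;
        A += ux[k] * uy[k2] - ux[k2] * uy[k];
      }
      A *= 0.5;
      if (u_area) *u_area += R.ka * (A - R.A0) * (A - R.A0) / (2.0 * R.A0);
      double lam = -R.ka * (A - R.A0) / R.A0;  // force = lam * dA/dr
      for (int k = 0; k < n; ++k) {
        int km = (k - 1 + n) % n, kp = (k + 1) % n;
        fx[R.start + k] += lam * 0.5 * (uy[kp] - uy[km]);
        fy[R.start + k] += lam * 0.5 * (ux[km] - ux[kp]);
      }
    }
  }
}

static void chain_forces(const std::vector<double>& x, const std::vector<double>& y,
                         std::vector<double>& fx, std::vector<double>& fy,
                         const System& S, int mask, double* u_bond, double* u_lj) {
  for (const Chain& C : S.chains) {
    if (mask & C_BOND) {
      for (int k = 0; k + 1 < C.n; ++k) {
        int i = C.start + k, j = C.start + k + 1;
        double dx, dy;
        min_image(S, x[j] - x[i], y[j] - y[i], dx, dy);
        double r = std::sqrt(dx * dx + dy * dy);
        if (r < 1e-12) stop("chain bond with zero length");
        double f = -C.ks * (r - C.lb);  // positive = repulsive (push j away)
        if (u_bond) *u_bond += 0.5 * C.ks * (r - C.lb) * (r - C.lb);
        double ex = dx / r, ey = dy / r;
        fx[j] += f * ex; fy[j] += f * ey;
        fx[i] -= f * ex; fy[i] -= f * ey;
      }
    }
    if (mask & C_LJ) {
      bool attract = (C.mode == 0);
      for (int k = 0; k < C.n; ++k) {
        for (int m = k + 2; m < C.n; ++m) {  // directly bonded pairs excluded
          int i = C.start + k, j = C.start + m;
          double dx, dy;
          min_image(S, x[i] - x[j], y[i] - y[j], dx, dy);
          double r2 = dx * dx + dy * dy;
          double cut = attract ? 2.5 * C.sigma : 1.1224620483089301 * C.sigma;
          if (r2 >= cut * cut) continue;
          if (r2 < 1e-24) stop("degenerate chain pair");
          double r = std::sqrt(r2);
          double f = lj_scalar(r, C.sigma, C.eps, attract, u_lj);
          double ex = dx / r, ey = dy / r;
          fx[i] += f * ex; fy[i] += f * ey;
          fx[j] -= f * ex; fy[j] -= f * ey;
        }
      }
    }
  }
}

void compute_forces(const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<double>& vx, const std::vector<double>& vy,
                    std::vector<double>& fx, std::vector<double>& fy,
                    const System& S, double dt, uint64_t seed, uint64_t step,
                    int mask) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  if (mask & (C_CONS | C_DISS | C_RAND | C_CROSS))
    nonbonded_forces(x, y, vx, vy, fx, fy, S, dt, seed, step, mask);
  if (!S.rings.empty() && (mask & (C_SPRING | C_BEND | C_AREA)))
    ring_forces(x, y, fx, fy, S, mask, nullptr, nullptr, nullptr);
  if (!S.chains.empty() && (mask & (C_BOND | C_LJ)))
    chain_forces(x, y, fx, fy, S, mask, nullptr, nullptr);
}

// ---------------------------------------------------------------------------
// energies (conservative terms only; used by finite-difference oracles and
// the energy-drift diagnostic)
// ---------------------------------------------------------------------------

Rcpp::NumericVector energy_terms(const std::vector<double>& x,
                                 const std::vector<double>& y,
                                 const System& S, int mask) {
  const PairParams& P = S.pp;
  double u_cons = 0.0, u_cross = 0.0;
  if (mask & (C_CONS | C_CROSS)) {
    CellList cl;
    build_cells(cl, x, y, S, P.rc);
    std::vector<double> dummy;
    for_pairs(cl, x, y, S, P.rc, [&](int i, int j, double dx, double dy, double r2) {
      int si = S.species[i], sj = S.species[j];
      if (si == SP_WALL && sj == SP_WALL) return;
      bool flu_i = (si <= SP_WALL), flu_j = (sj <= SP_WALL);
      double r = std::sqrt(r2);
      if (flu_i && flu_j) {
        if (mask & C_CONS) {
          double w = 1.0 - r / P.rc;
          u_cons += 0.5 * P.a * P.rc * w * w;
        }
      } else if (!flu_i && !flu_j && S.sid[i] != S.sid[j] && (mask & C_CROSS)) {
        bool mi = (si == SP_RBC), mj = (sj == SP_RBC);
        double u = 0.0;
        if (mi && mj) lj_scalar(r, P.sig_mem, P.eps_mem, false, &u);
        else if (mi || mj) lj_scalar(r, P.sig_cross, P.eps_cross, false, &u);
        else lj_scalar(r, P.sig_chain, P.eps_chain, false, &u);
        u_cross += u;
      }
    });
  }
  double u_spring = 0.0, u_bend = 0.0, u_area = 0.0;
  double u_bond = 0.0, u_lj = 0.0;
  std::vector<double> fx(S.N, 0.0), fy(S.N, 0.0);
  if (!S.rings.empty() && (mask & (C_SPRING | C_BEND | C_AREA)))
    ring_forces(x, y, fx, fy, S, mask & (C_SPRING | C_BEND | C_AREA),
                &u_spring, &u_bend, &u_area);
  if (!S.chains.empty() && (mask & (C_BOND | C_LJ)))
    chain_forces(x, y, fx, fy, S, mask & (C_BOND | C_LJ), &u_bond, &u_lj);
  NumericVector out = NumericVector::create(
    _["dpd_cons"] = u_cons, _["cross"] = u_cross, _["spring"] = u_spring,
    _["bend"] = u_bend, _["area"] = u_area, _["bond"] = u_bond,
    _["lj"] = u_lj);
  out.attr("total") = u_cons + u_cross + u_spring + u_bend + u_area + u_bond + u_lj;
  return out;
}

// ---------------------------------------------------------------------------
// exported helpers
// ---------------------------------------------------------------------------

static int mask_from_components(CharacterVector comp) {
  int mask = 0;
  for (int i = 0; i < comp.size(); ++i) {
    std::string c = as<std::string>(comp[i]);
    if (c == "all") mask |= C_ALL;
    else if (c == "conservative") mask |= C_CONS;
    else if (c == "dissipative") mask |= C_DISS;
    else if (c == "random") mask |= C_RAND;
    else if (c == "bond") mask |= C_BOND;
    else if (c == "lj") mask |= C_LJ;
    else if (c == "cross") mask |= C_CROSS;
    else if (c == "spring") mask |= C_SPRING;
    else if (c == "bend") mask |= C_BEND;
    else if (c == "area") mask |= C_AREA;
    else stop("unknown force component '%s'", c.c_str());
  }
  return mask;
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, double Lx, double Ly,
                                 double rc, bool per_x, bool per_y,
                                 double ypad) {
  if (rc <= 0) stop("r_c must be > 0");
  int N = pos.nrow();
  System S;
  S.N = N; S.Lx = Lx; S.W = Ly; S.per_x = per_x; S.per_y = per_y;
  S.ypad = ypad;
  std::vector<double> x(N), y(N);
  for (int i = 0; i < N; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  CellList cl;
  build_cells(cl, x, y, S, rc);
  std::vector<int> ii, jj;
  for_pairs(cl, x, y, S, rc, [&](int i, int j, double, double, double) {
    ii.push_back(std::min(i, j) + 1);
    jj.push_back(std::max(i, j) + 1);
  });
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, NumericMatrix vel, List sys,
                         double dt, double seed, double step,
                         CharacterVector components) {
  System S = parse_system(sys);
  int N = S.N;
  if (pos.nrow() != N) stop("positions/system size mismatch");
  std::vector<double> x(N), y(N), vx(N), vy(N), fx(N), fy(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1);
  }
  int mask = mask_from_components(components);
  compute_forces(x, y, vx, vy, fx, fy, S, dt, (uint64_t)seed, (uint64_t)step, mask);
  NumericMatrix out(N, 2);
  for (int i = 0; i < N; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix pos, List sys, CharacterVector components) {
  System S = parse_system(sys);
  int N = S.N;
  std::vector<double> x(N), y(N);
  for (int i = 0; i < N; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  return energy_terms(x, y, S, mask_from_components(components));
}
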