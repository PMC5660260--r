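#include "engine.h"
using namespace Rcpp;

// velocity-Verlet DPD loop for the slit channel (or a fully periodic box).
// Walls are frozen particles outside [0, W]; mobile particles bounce back
// at the wall planes; a tangential adaptive shear force on the near-wall
// fluid layer enforces no-slip.
// [[Rcpp::export]]
List cpp_run_channel(NumericMatrix pos0, NumericMatrix vel0, List sys, List ctrl) {
  System S = parse_system(sys);
  const int N = S.N;
  if (pos0.nrow() != N || vel0.nrow() != N) stop("state/system size mismatch");

  const double dt = as<double>(ctrl["dt"]);
  const uint64_t seed = (uint64_t)as<double>(ctrl["seed"]);
  const long n_steps = (long)as<double>(ctrl["n_steps"]);
  const long warmup = (long)as<double>(ctrl["warmup"]);
  const long stride = (long)as<double>(ctrl["stride"]);
  const double g = as<double>(ctrl["g"]);
  const bool bounce = as<bool>(ctrl["bounce"]);
  const bool adaptive = as<bool>(ctrl["adaptive"]);
  const double k_gain = as<double>(ctrl["k_gain"]);
  const long interval = (long)as<double>(ctrl["interval"]);
  const bool record = as<bool>(ctrl["record"]);
  const bool record_vel = as<bool>(ctrl["record_vel"]);
  const double damp = as<double>(ctrl["damp"]);
  const double fcap = as<double>(ctrl["fcap"]); // 0 = off; overlap relaxation
  const double temp_tol = as<double>(ctrl["temp_tol"]);
  const int temp_action = as<int>(ctrl["temp_action"]); // 0 none, 1 warn, 2 abort
  const long check_every = (long)as<double>(ctrl["check_every"]);
  if (dt < 0) stop("dt must be >= 0");

  std::vector<double> x(N), y(N), vx(N), vy(N), fx(N, 0.0), fy(N, 0.0);
  for (int i = 0; i < N; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1);
  }
  const double m = S.mass, inv_m = 1.0 / S.mass;
  const double rc = S.pp.rc, W = S.W, Lx = S.Lx;

  long nf = 0;
  if (record && n_steps > warmup) nf = (n_steps - warmup) / stride;
  NumericVector tr_pos(record ? (R_xlen_t)nf * N * 2 : 0);
  NumericVector tr_vel((record && record_vel) ? (R_xlen_t)nf * N * 2 : 0);
  NumericVector tr_time(record ? nf : 0);
  long frame = 0;

  std::vector<double> temp_trace, vbar_trace, corr_lo_trace, corr_hi_trace;
  double temp_ema = S.pp.kBT;   // smoothed estimate for the excursion check
  double corr_lo = 0.0, corr_hi = 0.0;
  double acc_lo_a = 0.0, acc_lo_b = 0.0, acc_hi_a = 0.0, acc_hi_b = 0.0;
  long n_lo_a = 0, n_lo_b = 0, n_hi_a = 0, n_hi_b = 0;
  bool temp_flag = false;

  // extra per-particle force: body force + adaptive wall correction
  auto apply_external = [&](void) {
    for (int i = 0; i < N; ++i) {
      if (!S.mobile[i]) continue;
      fx[i] += m * g;
      if (damp > 0.0) { fx[i] -= damp * vx[i]; fy[i] -= damp * vy[i]; }
      if (adaptive && S.species[i] == SP_FLUID) {
        if (y[i] < rc) fx[i] += corr_lo;
        else if (y[i] > W - rc) fx[i] += corr_hi;
      }
      if (fcap > 0.0) {
        double fn = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i]);
        if (fn > fcap) { fx[i] *= fcap / fn; fy[i] *= fcap / fn; }
      }
    }
  };

  compute_forces(x, y, vx, vy, fx, fy, S, dt, seed, 0, C_ALL);
  apply_external();

  for (long s = 1; s <= n_steps; ++s) {
    // kick
    for (int i = 0; i < N; ++i) {
      if (!S.mobile[i]) continue;
      vx[i] += 0.5 * dt * fx[i] * inv_m;
      vy[i] += 0.5 * dt * fy[i] * inv_m;
    }
    // drift + wrap + bounce-back
    for (int i = 0; i < N; ++i) {
      if (!S.mobile[i]) continue;
      x[i] += dt * vx[i];
      y[i] += dt * vy[i];
      if (S.per_x) {
        if (x[i] >= Lx) x[i] -= Lx;
        else if (x[i] < 0.0) x[i] += Lx;
      }
      if (S.per_y) {
        if (y[i] >= W) y[i] -= W;
        else if (y[i] < 0.0) y[i] += W;
      } else if (bounce) {
        if (y[i] < 0.0) {
          y[i] = -y[i];
          vx[i] = -vx[i]; vy[i] = -vy[i];
        } else if (y[i] > W) {
          y[i] = 2.0 * W - y[i];
          vx[i] = -vx[i]; vy[i] = -vy[i];
        }
        if (y[i] < -S.ypad || y[i] > W + S.ypad)
          stop("numerical blow-up: particle %d left the domain at step %ld", i + 1, s);
      }
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]))
        stop("numerical blow-up: non-finite coordinate at step %ld", s);
    }
    // forces at new positions (velocities at half step, standard DPD-VV)
    compute_forces(x, y, vx, vy, fx, fy, S, dt, seed, (uint64_t)s, C_ALL);
    apply_external();
    // kick
    for (int i = 0; i < N; ++i) {
      if (!S.mobile[i]) continue;
      vx[i] += 0.5 * dt * fx[i] * inv_m;
      vy[i] += 0.5 * dt * fy[i] * inv_m;
    }

    // adaptive wall shear-force controller
    if (adaptive) {
      for (int i = 0; i < N; ++i) {
        if (S.species[i] != SP_FLUID) continue;
        if (y[i] < 0.5 * rc) { acc_lo_a += vx[i]; ++n_lo_a; }
        else if (y[i] < rc) { acc_lo_b += vx[i]; ++n_lo_b; }
        else if (y[i] > W - 0.5 * rc) { acc_hi_a += vx[i]; ++n_hi_a; }
        else if (y[i] > W - rc) { acc_hi_b += vx[i]; ++n_hi_b; }
      }
      if (s % interval == 0) {
        if (n_lo_a > 0 && n_lo_b > 0) {
          double slip = 1.5 * acc_lo_a / n_lo_a - 0.5 * acc_lo_b / n_lo_b;
          corr_lo += -k_gain * slip;
        }
        if (n_hi_a > 0 && n_hi_b > 0) {
          double slip = 1.5 * acc_hi_a / n_hi_a - 0.5 * acc_hi_b / n_hi_b;
          corr_hi += -k_gain * slip;
        }
        corr_lo_trace.push_back(corr_lo);
        corr_hi_trace.push_back(corr_hi);
        acc_lo_a = acc_lo_b = acc_hi_a = acc_hi_b = 0.0;
        n_lo_a = n_lo_b = n_hi_a = n_hi_b = 0;
      }
    }

    // diagnostics: kinetic temperature from the wall-normal velocity
    // component (free of the imposed mean flow) and the mean axial velocity
    if (s % check_every == 0) {
      double svy2 = 0.0, svx = 0.0;
      long nm = 0, nfl = 0;
      for (int i = 0; i < N; ++i) {
        if (!S.mobile[i]) continue;
        svy2 += m * vy[i] * vy[i]; ++nm;
        if (S.species[i] == SP_FLUID) { svx += vx[i]; ++nfl; }
      }
      double T = (nm > 0) ? svy2 / nm : NA_REAL;
      temp_trace.push_back(T);
      vbar_trace.push_back(nfl > 0 ? svx / nfl : NA_REAL);
      temp_ema = 0.9 * temp_ema + 0.1 * T;
      if (temp_action > 0 && s > warmup && S.pp.kBT > 0 && nm > 1) {
        if (std::fabs(temp_ema - S.pp.kBT) / S.pp.kBT > temp_tol) {
          temp_flag = true;
          if (temp_action == 2)
            stop("temperature excursion at step %ld: kT = %g (target %g)", s, T, S.pp.kBT);
        }
      }
    }

    if (record && s > warmup && (s - warmup) % stride == 0 && frame < nf) {
      R_xlen_t off = (R_xlen_t)frame * N * 2;
      for (int i = 0; i < N; ++i) {
        tr_pos[off + i] = x[i];
        tr_pos[off + N + i] = y[i];
      }
      if (record_vel) {
        for (int i = 0; i < N; ++i) {
          tr_vel[off + i] = vx[i];
          tr_vel[off + N + i] = vy[i];
        }
      }
      tr_time[frame] = s * dt;
      ++frame;
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(N, 2), vel_out(N, 2);
  for (int i = 0; i < N; ++i) {
    pos_out(i, 0) = x[i]; pos_out(i, 1) = y[i];
    vel_out(i, 0) = vx[i]; vel_out(i, 1) = vy[i];
  }
  if (record) tr_pos.attr("dim") = IntegerVector::create(N, 2, (int)nf);
  if (record && record_vel) tr_vel.attr("dim") = IntegerVector::create(N, 2, (int)nf);

  return List::create(
    _["pos"] = tr_pos, _["vel"] = tr_vel, _["times"] = tr_time,
    _["n_frames"] = (double)frame,
    _["final_pos"] = pos_out, _["final_vel"] = vel_out,
    _["temp_trace"] = wrap(temp_trace), _["vbar_trace"] = wrap(vbar_trace),
    _["corr_lo"] = wrap(corr_lo_trace), _["corr_hi"] = wrap(corr_hi_trace),
    _["temp_flag"] = temp_flag);
}

// ---------------------------------------------------------------------------
// single chain in an unbounded linear shear background flow, inertial
// Langevin dynamics (BAOAB splitting); used for the stretching calibration
// ---------------------------------------------------------------------------

static inline double gauss_draw(uint64_t seed, uint64_t step, int i, int comp) {
  uint64_t k1 = sm64(seed ^ sm64(step * 0x9e3779b9ULL + 0x7f4a7c15ULL));
  uint64_t h1 = sm64(k1 ^ (((uint64_t)i << 3) | (uint64_t)comp));
  uint64_t h2 = sm64(h1 ^ 0xda942042e4dd58b5ULL);
  double u1 = u01(h1), u2 = u01(h2);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

// [[Rcpp::export]]
List cpp_run_shear_chain(NumericMatrix pos0, int mode, double ks, double lb,
                         double sigma, double eps, double gamma_dot,
                         double zeta, double kBT, double mass, double dt,
                         double n_steps_d, double warmup_d, double stride_d,
                         double seed_d) {
  const int N = pos0.nrow();
  const long n_steps = (long)n_steps_d, warmup = (long)warmup_d,
             stride = (long)stride_d;
  const uint64_t seed = (uint64_t)seed_d;
  std::vector<double> x(N), y(N), vx(N, 0.0), vy(N, 0.0), fx(N), fy(N);
  for (int i = 0; i < N; ++i) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); }
  const double c1 = std::exp(-zeta * dt / mass);
  const double c2 = std::sqrt(kBT / mass * (1.0 - c1 * c1));
  const double inv_m = 1.0 / mass;
  const bool attract = (mode == 0);

  auto forces = [&](void) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int k = 0; k + 1 < N; ++k) {
      double dx = x[k + 1] - x[k], dy = y[k + 1] - y[k];
      double r = std::sqrt(dx * dx + dy * dy);
      if (r < 1e-12) stop("chain bond with zero length");
      double f = -ks * (r - lb);
      double ex = dx / r, ey = dy / r;
      fx[k + 1] += f * ex; fy[k + 1] += f * ey;
      fx[k] -= f * ex; fy[k] -= f * ey;
    }
    double cut = attract ? 2.5 * sigma : 1.1224620483089301 * sigma;
    double cut2 = cut * cut;
    for (int k = 0; k < N; ++k) {
      for (int j = k + 2; j < N; ++j) {
        double dx = x[k] - x[j], dy = y[k] - y[j];
        double r2 = dx * dx + dy * dy;
        if (r2 >= cut2) continue;
        double r = std::sqrt(r2);
        double f = lj_scalar(r, sigma, eps, attract, nullptr);
        double ex = dx / r, ey = dy / r;
        fx[k] += f * ex; fy[k] += f * ey;
        fx[j] -= f * ex; fy[j] -= f * ey;
      }
    }
  };

  long nsamp = (n_steps > warmup) ? (n_steps - warmup) / stride : 0;
  NumericVector rs_out(nsamp), rg_out(nsamp), t_out(nsamp);
  long is = 0;

  forces();
  for (long s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < N; ++i) { // B
      vx[i] += 0.5 * dt * fx[i] * inv_m;
      vy[i] += 0.5 * dt * fy[i] * inv_m;
    }
    for (int i = 0; i < N; ++i) { // A
      x[i] += 0.5 * dt * vx[i];
      y[i] += 0.5 * dt * vy[i];
    }
    for (int i = 0; i < N; ++i) { // O: OU about the local background flow
      double u = gamma_dot * y[i];
      vx[i] = u + c1 * (vx[i] - u) + c2 * gauss_draw(seed, (uint64_t)s, i, 0);
      vy[i] = c1 * vy[i] + c2 * gauss_draw(seed, (uint64_t)s, i, 1);
    }
    for (int i = 0; i < N; ++i) { // A
      x[i] += 0.5 * dt * vx[i];
      y[i] += 0.5 * dt * vy[i];
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]))
        stop("numerical blow-up in shear scan at step %ld", s);
    }
    forces();
    for (int i = 0; i < N; ++i) { // B
      vx[i] += 0.5 * dt * fx[i] * inv_m;
      vy[i] += 0.5 * dt * fy[i] * inv_m;
    }
    if (s > warmup && (s - warmup) % stride == 0 && is < nsamp) {
      double xmin = x[0], xmax = x[0], cx = 0.0, cy = 0.0;
      for (int i = 0; i < N; ++i) {
        if (x[i] < xmin) xmin = x[i];
        if (x[i] > xmax) xmax = x[i];
        cx += x[i]; cy += y[i];
      }
      cx /= N; cy /= N;
      double rg2 = 0.0;
      for (int i = 0; i < N; ++i)
        rg2 += (x[i] - cx) * (x[i] - cx) + (y[i] - cy) * (y[i] - cy);
      rs_out[is] = xmax - xmin;
      rg_out[is] = std::sqrt(rg2 / N);
      t_out[is] = s * dt;
      ++is;
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix pos_out(N, 2);
  for (int i = 0; i < N; ++i) { pos_out(i, 0) = x[i]; pos_out(i, 1) = y[i]; }
  return List::create(_["Rs"] = rs_out, _["Rg"] = rg_out, _["t"] = t_out,
                      _["final_pos"] = pos_out);
}
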