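// BAOAB Langevin integrator for axial ion dynamics in the channel force
// field. Positions/velocities in SI (m, m/s); the R wrappers convert units.
//
// The conservative force mirrors axial_force() in R (rings, dipole rings,
// self-energy bump, walls, voltage ramp, screened pair repulsion); the two
// implementations are cross-checked in the test suite.

#include <Rcpp.h>
using namespace Rcpp;

struct Channel {
  // generalized charge rings: EEEE ring 1, EEEE ring 2, dipole inner (-),
  // dipole outer (+); each U = C / sqrt((z-zc)^2 + R^2)
  std::vector<double> ring_C, ring_zc, ring_R2;
  double ring_ilam;                       // 1/screening length of fixed terms
  double pol_A, pol_zc, pol_w;           // gaussian self-energy bump
  double wall_A, wall_w, wall_lo, wall_hi; // onset positions (m)
  double q;                               // ion charge (C)
  double volt_F;                          // constant force inside membrane (N)
  double mem_lo, mem_hi;
  double pair_C, pair_lambda, clamp;      // screened Coulomb pair term
};

static Channel make_channel(const List& p) {
  Channel c;
  c.ring_C  = as<std::vector<double>>(p["ring_C"]);
  c.ring_zc = as<std::vector<double>>(p["ring_zc"]);
  c.ring_R2 = as<std::vector<double>>(p["ring_R2"]);
  c.ring_ilam = p["ring_ilam"];
  c.pol_A = p["pol_A"]; c.pol_zc = p["pol_zc"]; c.pol_w = p["pol_w"];
  c.wall_A = p["wall_A"]; c.wall_w = p["wall_w"];
  c.wall_lo = p["wall_lo"]; c.wall_hi = p["wall_hi"];
  c.q = p["q"];
  c.volt_F = p["volt_F"]; c.mem_lo = p["mem_lo"]; c.mem_hi = p["mem_hi"];
  c.pair_C = p["pair_C"]; c.pair_lambda = p["pair_lambda"];
  c.clamp = p["clamp"];
  return c;
}

// conservative force on each ion (N); n small (2-3)
static inline void forces(const Channel& c, const double* z, int n,
                          double* f) {
  for (int i = 0; i < n; ++i) {
    double zi = z[i], fi = 0.0;
    for (size_t r = 0; r < c.ring_C.size(); ++r) {
      double dz = zi - c.ring_zc[r];
      double rr = std::sqrt(dz * dz + c.ring_R2[r]);
      fi += c.ring_C[r] * std::exp(-rr * c.ring_ilam) *
            (1.0 / rr + c.ring_ilam) * dz / (rr * rr);
    }
    double dp = zi - c.pol_zc;
    fi += c.pol_A * std::exp(-dp * dp / (2.0 * c.pol_w * c.pol_w)) * dp /
          (c.pol_w * c.pol_w);
    if (zi > c.wall_hi) {
      double u = (zi - c.wall_hi) / c.wall_w;
      double u4 = u * u * u * u;
      fi -= 10.0 * c.wall_A / c.wall_w * u4 * u4 * u;
    } else if (zi < c.wall_lo) {
      double u = (c.wall_lo - zi) / c.wall_w;
      double u4 = u * u * u * u;
      fi += 10.0 * c.wall_A / c.wall_w * u4 * u4 * u;
    }
    if (zi > c.mem_lo && zi < c.mem_hi) fi += c.volt_F;
    f[i] = fi;
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dz = z[i] - z[j];
      double r = std::fabs(dz);
      if (r < c.clamp) r = c.clamp;
      double u = c.pair_C * std::exp(-r / c.pair_lambda) / r;
      double fr = u * (1.0 / r + 1.0 / c.pair_lambda); // magnitude, repulsive
      double s = (dz >= 0) ? 1.0 : -1.0;
      f[i] += s * fr;
      f[j] -= s * fr;
    }
  }
}

static inline double field_force(double q, double amp, double freq,
                                 double onset, double phase, double t) {
  if (amp == 0.0 || t < onset) return 0.0;
  return q * amp * std::sin(2.0 * M_PI * freq * (t - onset) + phase);
}

// [[Rcpp::export]]
List baoab_channel_run(List pars, NumericVector z0, NumericVector v0,
                       double dt, double nsteps_d, double gamma, double mass,
                       double temperature,
                       double famp, double ffreq, double fonset, double fphase,
                       int stride, bool reset, double exit_z,
                       double res_lo, double res_hi, bool store, double t0) {
  Channel ch = make_channel(pars);
  const R_xlen_t nsteps = (R_xlen_t) nsteps_d;
  const int n = z0.size();
  std::vector<double> z(z0.begin(), z0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> f(n), fmid(n);

  const double kB = 1.380649e-23;
  const double cO = std::exp(-(gamma / mass) * dt);
  const double sO = std::sqrt(kB * temperature / mass * (1.0 - cO * cO));
  const double vth = std::sqrt(kB * temperature / mass);

  const R_xlen_t nstore = store ? (nsteps / stride) : 0;
  NumericMatrix Z(nstore, n), V(nstore, n), A(nstore, n);
  NumericVector Tgrid(nstore);
  std::vector<double> ev_t;
  std::vector<int> ev_ion;

  forces(ch, z.data(), n, f.data());
  double t = t0;
  R_xlen_t kstore = 0;

  for (R_xlen_t s = 0; s < nsteps; ++s) {
    // B: half kick with force at t
    for (int i = 0; i < n; ++i) {
      double fi = f[i] + field_force(ch.q, famp, ffreq, fonset, fphase, t);
      v[i] += 0.5 * dt * fi / mass;
    }
    // A: half drift
    for (int i = 0; i < n; ++i) z[i] += 0.5 * dt * v[i];
    // O: exact Ornstein-Uhlenbeck
    for (int i = 0; i < n; ++i) v[i] = cO * v[i] + sO * norm_rand();
    // A: half drift
    for (int i = 0; i < n; ++i) z[i] += 0.5 * dt * v[i];
    t = t0 + (s + 1) * dt;
    // B: half kick with force at t_{n+1}
    forces(ch, z.data(), n, f.data());
    for (int i = 0; i < n; ++i) {
      double fi = f[i] + field_force(ch.q, famp, ffreq, fonset, fphase, t);
      v[i] += 0.5 * dt * fi / mass;
    }

    if (reset) {
      bool moved = false;
      for (int i = 0; i < n; ++i) {
        if (z[i] < exit_z) {
          ev_t.push_back(t);
          ev_ion.push_back(i + 1);
          z[i] = res_lo + unif_rand() * (res_hi - res_lo);
          v[i] = vth * norm_rand();
          moved = true;
        }
      }
      if (moved) forces(ch, z.data(), n, f.data());
    }

    if (!std::isfinite(z[0]))
      stop("non-finite position at step %td", (ptrdiff_t) s);

    if (store && ((s + 1) % stride == 0) && kstore < nstore) {
      for (int i = 0; i < n; ++i) {
        Z(kstore, i) = z[i];
        V(kstore, i) = v[i];
        A(kstore, i) = (f[i] + field_force(ch.q, famp, ffreq, fonset,
                                           fphase, t)) / mass;
      }
      Tgrid[kstore] = t;
      ++kstore;
    }
  }

  return List::create(_["z"] = Z, _["v"] = V, _["a"] = A, _["time"] = Tgrid,
                      _["event_times"] = NumericVector(ev_t.begin(), ev_t.end()),
                      _["event_ion"] = IntegerVector(ev_ion.begin(), ev_ion.end()),
                      _["z_final"] = NumericVector(z.begin(), z.end()),
                      _["v_final"] = NumericVector(v.begin(), v.end()));
}

// [[Rcpp::export]]
NumericVector channel_forces_cpp(List pars, NumericVector z) {
  Channel ch = make_channel(pars);
  int n = z.size();
  NumericVector f(n);
  std::vector<double> zz(z.begin(), z.end()), ff(n);
  forces(ch, zz.data(), n, ff.data());
  for (int i = 0; i < n; ++i) f[i] = ff[i];
  return f;
}

// Reference BAOAB run in simple analytic potentials (integrator physics
// tests): kind 0 = free particle, 1 = harmonic well (pars[0] = k, N/m),
// 2 = symmetric quartic double well U = h ((z/a)^2 - 1)^2
// (pars[0] = h in J, pars[1] = a in m).
// [[Rcpp::export]]
List baoab_reference_run(int kind, NumericVector pars, double z0, double v0,
                         double dt, double nsteps_d, double gamma,
                         double mass, double temperature, int stride) {
  const R_xlen_t nsteps = (R_xlen_t) nsteps_d;
  const double kB = 1.380649e-23;
  const double cO = std::exp(-(gamma / mass) * dt);
  const double sO = std::sqrt(kB * temperature / mass * (1.0 - cO * cO));
  double z = z0, v = v0;
  auto force = [&](double x) {
    if (kind == 0) return 0.0;
    if (kind == 1) return -pars[0] * x;
    double a2 = pars[1] * pars[1];
    double u = x * x / a2 - 1.0;
    return -4.0 * pars[0] * u * x / a2;
  };
  const R_xlen_t nstore = nsteps / stride;
  NumericVector Z(nstore), V(nstore);
  double f = force(z);
  R_xlen_t kstore = 0;
  for (R_xlen_t s = 0; s < nsteps; ++s) {
    v += 0.5 * dt * f / mass;
    z += 0.5 * dt * v;
    v = cO * v + sO * norm_rand();
    z += 0.5 * dt * v;
    f = force(z);
    v += 0.5 * dt * f / mass;
    if ((s + 1) % stride == 0 && kstore < nstore) {
      Z[kstore] = z;
      V[kstore] = v;
      ++kstore;
    }
  }
  return List::create(_["z"] = Z, _["v"] = V);
}
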