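// Finite-field Langevin dynamics engine for a single cation in a bath of
// dipolar solvent particles.
//
// Units: Angstrom, fs, amu, eV, elementary charge. Atom 0 is the ion.
// Translation: BAOAB velocity-Verlet/Langevin splitting; pair forces are
// truncated-and-shifted Lennard-Jones under cubic minimum-image periodic
// boundaries; the external field acts on the ion through its Born-charge
// tensor q*I (solvent particles carry zero net Born charge, so a homogeneous
// field exerts no net translational force on them).
// Rotation: overdamped Brownian dynamics of the solvent dipole unit vectors
// on the sphere, driven by the torque from the external field plus the
// Coulomb field of the ion; the stationary distribution is Boltzmann in the
// dipole-field energy.
// Positions are integrated unwrapped; minimum image is applied inside the
// force loop only.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double MASS_UNIT = 103.64269573;   // amu -> eV fs^2/A^2
static const double COULOMB_K = 14.399645;      // eV A / e^2

struct MinImage {
  double box;
  inline double wrap(double d) const { return d - box * std::round(d / box); }
};

// Truncated-shifted LJ pair force on atom i from atom j; returns force vector
// contribution via f[]. eps == 0 disables the pair.
static inline void lj_accum(double dx, double dy, double dz, double r2,
                            double sig, double eps, double rc2,
                            double* fi) {
  if (eps == 0.0 || r2 >= rc2) return;
  double s2 = sig * sig / r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  // dV/dr / r with V = 4 eps (s12 - s6): F = 24 eps (2 s12 - s6)/r2 * rvec
  double fmag = 24.0 * eps * (2.0 * s12 - s6) / r2;
  fi[0] += fmag * dx;
  fi[1] += fmag * dy;
  fi[2] += fmag * dz;
}

static void compute_forces(const std::vector<double>& x, int n,
                           const MinImage& mi,
                           double sig_ss, double eps_ss, double rc2_ss,
                           double sig_is, double eps_is, double rc2_is,
                           double q_ion, const double* field,
                           std::vector<double>& f) {
  std::fill(f.begin(), f.end(), 0.0);
  // ion-solvent
  for (int j = 1; j < n; ++j) {
    double dx = mi.wrap(x[0] - x[3 * j]);
    double dy = mi.wrap(x[1] - x[3 * j + 1]);
    double dz = mi.wrap(x[2] - x[3 * j + 2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    double fi[3] = {0, 0, 0};
    lj_accum(dx, dy, dz, r2, sig_is, eps_is, rc2_is, fi);
    f[0] += fi[0]; f[1] += fi[1]; f[2] += fi[2];
    f[3 * j] -= fi[0]; f[3 * j + 1] -= fi[1]; f[3 * j + 2] -= fi[2];
  }
  // solvent-solvent
  for (int i = 1; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = mi.wrap(x[3 * i] - x[3 * j]);
      double dy = mi.wrap(x[3 * i + 1] - x[3 * j + 1]);
      double dz = mi.wrap(x[3 * i + 2] - x[3 * j + 2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2_ss) continue;
      double fi[3] = {0, 0, 0};
      lj_accum(dx, dy, dz, r2, sig_ss, eps_ss, rc2_ss, fi);
      f[3 * i] += fi[0]; f[3 * i + 1] += fi[1]; f[3 * i + 2] += fi[2];
      f[3 * j] -= fi[0]; f[3 * j + 1] -= fi[1]; f[3 * j + 2] -= fi[2];
    }
  }
  // field force on the ion (Born charge tensor q*I)
  f[0] += q_ion * field[0];
  f[1] += q_ion * field[1];
  f[2] += q_ion * field[2];
}

// [[Rcpp::export]]
List ff_langevin_run(NumericMatrix pos0, NumericMatrix vel0,
                     NumericMatrix dip0,
                     double box, NumericVector mass,
                     double q_ion, double mu_dip,
                     double sig_ss, double eps_ss,
                     double sig_is, double eps_is,
                     double rc_ss, double rc_is,
                     double gamma_t, double gamma_r, double rot_inertia,
                     double temperature, double dt,
                     NumericVector field,
                     int nsteps, int ion_stride, int frame_stride,
                     double vmax, double dipole_cutoff) {
  const int n = pos0.nrow();
  const double kBT = 8.617333262e-5 * temperature;
  MinImage mi{box};
  const double rc2_ss = rc_ss * rc_ss, rc2_is = rc_is * rc_is;
  const double rc2_cd = dipole_cutoff * dipole_cutoff;

  std::vector<double> x(3 * n), v(3 * n), u(3 * n), f(3 * n), minv(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] = pos0(i, k);
      v[3 * i + k] = vel0(i, k);
      u[3 * i + k] = dip0(i, k);
    }
    minv[i] = 1.0 / (mass[i] * MASS_UNIT);
  }

  // Langevin O-step coefficients
  const double c1 = std::exp(-gamma_t * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  // rotational diffusion constant (rad^2/fs) and mobility
  const double Ir = rot_inertia * MASS_UNIT;
  const double Dr = kBT / (Ir * gamma_r);
  const double mob_r = Dr / kBT;
  const double rot_noise = std::sqrt(2.0 * Dr * dt);

  const int n_ion = nsteps / ion_stride;
  const int n_frame = nsteps / frame_stride;
  NumericMatrix ion_pos(n_ion, 3), ion_vel(n_ion, 3);
  NumericVector ion_t(n_ion), temp_series(n_ion);
  NumericVector fr_pos(n_frame > 0 ? (R_xlen_t)n * 3 * n_frame : 0);
  NumericVector fr_vel(n_frame > 0 ? (R_xlen_t)n * 3 * n_frame : 0);
  NumericVector fr_dip(n_frame > 0 ? (R_xlen_t)n * 3 * n_frame : 0);
  NumericVector fr_t(n_frame);

  double fld[3] = {field[0], field[1], field[2]};
  compute_forces(x, n, mi, sig_ss, eps_ss, rc2_ss,
                 sig_is, eps_is, rc2_is, q_ion, fld, f);

  RNGScope scope;
  int io = 0, fo = 0;
  for (int step = 1; step <= nsteps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] += 0.5 * dt * f[3 * i + k] * minv[i];
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O: friction + noise
    for (int i = 0; i < n; ++i) {
      double s = c2 * std::sqrt(kBT * minv[i]);
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] = c1 * v[3 * i + k] + s * norm_rand();
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // recompute forces, B: half kick
    compute_forces(x, n, mi, sig_ss, eps_ss, rc2_ss,
                   sig_is, eps_is, rc2_is, q_ion, fld, f);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] += 0.5 * dt * f[3 * i + k] * minv[i];

    // rotational Brownian step for solvent dipoles
    if (mu_dip != 0.0) {
      for (int j = 1; j < n; ++j) {
        double ex = fld[0], ey = fld[1], ez = fld[2];
        // Coulomb field of the ion at solvent j (cutoff-based)
        double dx = mi.wrap(x[3 * j] - x[0]);
        double dy = mi.wrap(x[3 * j + 1] - x[1]);
        double dz = mi.wrap(x[3 * j + 2] - x[2]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2_cd && r2 > 1e-12) {
          double ir3 = COULOMB_K * q_ion / (r2 * std::sqrt(r2));
          ex += ir3 * dx; ey += ir3 * dy; ez += ir3 * dz;
        }
        double ux = u[3 * j], uy = u[3 * j + 1], uz = u[3 * j + 2];
        double ue = ux * ex + uy * ey + uz * ez;
        // deterministic alignment drift: mob_r * mu * (E - (u.E)u)
        double a = dt * mob_r * mu_dip;
        double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
        double gu = gx * ux + gy * uy + gz * uz;
        ux += a * (ex - ue * ux) + rot_noise * (gx - gu * ux);
        uy += a * (ey - ue * uy) + rot_noise * (gy - gu * uy);
        uz += a * (ez - ue * uz) + rot_noise * (gz - gu * uz);
        double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        u[3 * j] = ux / nrm; u[3 * j + 1] = uy / nrm; u[3 * j + 2] = uz / nrm;
      }
    }

    // stability check
    for (int i = 0; i < n; ++i) {
      double v2 = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                  v[3 * i + 2] * v[3 * i + 2];
      if (!(v2 < vmax * vmax)) {
        stop("integration failure: |v| exceeded %g A/fs at step %d (atom %d)",
             vmax, step, i + 1);
      }
    }

    if (step % ion_stride == 0 && io < n_ion) {
      ion_t[io] = step * dt;
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        double v2 = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                    v[3 * i + 2] * v[3 * i + 2];
        ke += 0.5 * mass[i] * MASS_UNIT * v2;
      }
      temp_series[io] = 2.0 * ke / (3.0 * n * 8.617333262e-5);
      for (int k = 0; k < 3; ++k) {
        ion_pos(io, k) = x[k];
        ion_vel(io, k) = v[k];
      }
      ++io;
    }
    if (step % frame_stride == 0 && fo < n_frame) {
      fr_t[fo] = step * dt;
      R_xlen_t base = (R_xlen_t)fo * 3 * n;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          fr_pos[base + (R_xlen_t)k * n + i] = x[3 * i + k];
          fr_vel[base + (R_xlen_t)k * n + i] = v[3 * i + k];
          fr_dip[base + (R_xlen_t)k * n + i] = u[3 * i + k];
        }
      ++fo;
    }
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3), dip_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      pos_out(i, k) = x[3 * i + k];
      vel_out(i, k) = v[3 * i + k];
      dip_out(i, k) = u[3 * i + k];
    }

  return List::create(
    _["ion_t"] = ion_t, _["ion_pos"] = ion_pos, _["ion_vel"] = ion_vel,
    _["temperature"] = temp_series,
    _["frame_t"] = fr_t, _["frame_pos"] = fr_pos, _["frame_vel"] = fr_vel,
    _["frame_dip"] = fr_dip,
    _["final_pos"] = pos_out, _["final_vel"] = vel_out,
    _["final_dip"] = dip_out);
}
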