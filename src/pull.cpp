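// Langevin dynamics of a single ligand bead in a field of fixed
// Lennard-Jones + Coulomb sites, pulled by a moving harmonic spring.
// Units: kJ/mol, nm, ps, amu, elementary charge (GROMACS conventions).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.008314462618;     // kJ mol^-1 K^-1
static const double FCOUL = 138.935458;      // kJ mol^-1 nm e^-2

// Pairwise energies and force on the ligand at position x.
// Plain cutoff: both LJ and Coulomb vanish beyond `cutoff`.
static void pair_terms(const NumericMatrix& pos, const NumericVector& eps,
                       const NumericVector& sig, const NumericVector& q,
                       double qlig, double cutoff, double dielectric,
                       const double x[3], double f[3],
                       double& e_cou, double& e_vdw) {
  f[0] = f[1] = f[2] = 0.0;
  e_cou = e_vdw = 0.0;
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < pos.nrow(); ++i) {
    double dx = x[0] - pos(i, 0);
    double dy = x[1] - pos(i, 1);
    double dz = x[2] - pos(i, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > c2) continue;
    if (r2 == 0.0) stop("singularity: ligand coincides with site %d", i + 1);
    double inv_r2 = 1.0 / r2;
    double sr2 = sig[i] * sig[i] * inv_r2;
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    e_vdw += 4.0 * eps[i] * (sr12 - sr6);
    double fr = 24.0 * eps[i] * (2.0 * sr12 - sr6) * inv_r2;  // dV/dr * -1/r
    if (q[i] != 0.0 && qlig != 0.0) {
      double r = std::sqrt(r2);
      double ec = FCOUL * q[i] * qlig / (dielectric * r);
      e_cou += ec;
      fr += ec * inv_r2;
    }
    f[0] += fr * dx;
    f[1] += fr * dy;
    f[2] += fr * dz;
  }
}

// [[Rcpp::export(name = ".interaction_energy_cpp")]]
NumericVector interaction_energy_cpp(NumericMatrix site_pos,
                                     NumericVector eps, NumericVector sigma,
                                     NumericVector charge, double lig_charge,
                                     NumericVector lig_pos, double cutoff,
                                     double dielectric) {
  double x[3] = { lig_pos[0], lig_pos[1], lig_pos[2] };
  double f[3], e_cou, e_vdw;
  pair_terms(site_pos, eps, sigma, charge, lig_charge, cutoff, dielectric,
             x, f, e_cou, e_vdw);
  return NumericVector::create(_["E_cou"] = e_cou, _["E_vdW"] = e_vdw);
}

// BAOAB Langevin integrator with a harmonic spring whose anchor moves at
// speed v along `axis` after an equilibration phase with a stationary
// anchor. Spring force (recorded) acts only along the pull axis on the
// ligand's axial projection. Uses R's RNG (seed via set.seed upstream).
// [[Rcpp::export(name = ".run_pull_cpp")]]
List run_pull_cpp(NumericMatrix site_pos, NumericVector eps,
                  NumericVector sigma, NumericVector charge,
                  double lig_mass, double lig_charge, NumericVector lig_pos,
                  double cutoff, double temperature, double friction,
                  double dielectric, double k_spring, double v_pull,
                  double dt, int n_eq_steps, int n_pull_steps,
                  int force_every, int metric_every, NumericVector axis,
                  double box_bound) {
  if (dt <= 0 || lig_mass <= 0) stop("invalid timestep or mass");
  const int n_steps = n_eq_steps + n_pull_steps;
  double x[3] = { lig_pos[0], lig_pos[1], lig_pos[2] };
  double vel[3] = { 0.0, 0.0, 0.0 };
  double ax[3] = { axis[0], axis[1], axis[2] };

  const double c1 = std::exp(-friction * dt);
  const double kT = KB * temperature;
  const double cnoise = (temperature > 0.0)
      ? std::sqrt((1.0 - c1 * c1) * kT / lig_mass) : 0.0;

  const double z0 = x[0] * ax[0] + x[1] * ax[1] + x[2] * ax[2];
  double f[3], e_cou, e_vdw;

  const int n_force = n_steps / force_every + 1;
  const int n_metric = n_steps / metric_every + 1;
  NumericVector t_force(n_force), force(n_force), disp(n_force);
  NumericVector t_metric(n_metric), E_cou(n_metric), E_vdw(n_metric);

  double anchor = z0;
  double zlig = z0;
  double fspring = k_spring * (anchor - zlig);
  pair_terms(site_pos, eps, sigma, charge, lig_charge, cutoff, dielectric,
             x, f, e_cou, e_vdw);
  f[0] += fspring * ax[0];
  f[1] += fspring * ax[1];
  f[2] += fspring * ax[2];

  int i_force = 0, i_metric = 0;
  t_force[0] = 0.0; force[0] = fspring; disp[0] = 0.0;
  t_metric[0] = 0.0; E_cou[0] = e_cou; E_vdw[0] = e_vdw;
  ++i_force; ++i_metric;

  for (int step = 1; step <= n_steps; ++step) {
    // B
    double h = 0.5 * dt / lig_mass;
    vel[0] += h * f[0]; vel[1] += h * f[1]; vel[2] += h * f[2];
    // A
    x[0] += 0.5 * dt * vel[0]; x[1] += 0.5 * dt * vel[1];
    x[2] += 0.5 * dt * vel[2];
    // O
    if (cnoise > 0.0) {
      vel[0] = c1 * vel[0] + cnoise * R::norm_rand();
      vel[1] = c1 * vel[1] + cnoise * R::norm_rand();
      vel[2] = c1 * vel[2] + cnoise * R::norm_rand();
    } else {
      vel[0] *= c1; vel[1] *= c1; vel[2] *= c1;
    }
    // A
    x[0] += 0.5 * dt * vel[0]; x[1] += 0.5 * dt * vel[1];
    x[2] += 0.5 * dt * vel[2];
    // force at new positions / time
    double t = step * dt;
    anchor = (step <= n_eq_steps) ? z0
             : z0 + v_pull * (t - n_eq_steps * dt);
    zlig = x[0] * ax[0] + x[1] * ax[1] + x[2] * ax[2];
    fspring = k_spring * (anchor - zlig);
    pair_terms(site_pos, eps, sigma, charge, lig_charge, cutoff, dielectric,
               x, f, e_cou, e_vdw);
    f[0] += fspring * ax[0];
    f[1] += fspring * ax[1];
    f[2] += fspring * ax[2];
    // B
    vel[0] += h * f[0]; vel[1] += h * f[1]; vel[2] += h * f[2];

    if (std::fabs(x[0]) > box_bound || std::fabs(x[1]) > box_bound ||
        std::fabs(x[2]) > box_bound)
      stop("simulation diverged at step %d", step);

    if (step % force_every == 0) {
      t_force[i_force] = t;
      force[i_force] = fspring;
      disp[i_force] = zlig - z0;
      ++i_force;
    }
    if (step % metric_every == 0) {
      t_metric[i_metric] = t;
      E_cou[i_metric] = e_cou;
      E_vdw[i_metric] = e_vdw;
      ++i_metric;
    }
  }

  return List::create(
    _["t_force"] = t_force, _["force"] = force, _["displacement"] = disp,
    _["t_metric"] = t_metric, _["E_cou"] = E_cou, _["E_vdW"] = E_vdw,
    _["final_position"] = NumericVector::create(x[0], x[1], x[2]));
}
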