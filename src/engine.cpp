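// Coarse-grained force field + map-coupling kernels and integrators.
//
// Units: length Angstrom, energy kcal/mol, mass amu, time in AKMA units
// (1 AKMA = 48.88821 fs), so acceleration = F/m directly.  kB in kcal/mol/K.
// All randomness is drawn from R's RNG (norm_rand/unif_rand) so that
// set.seed() on the R side makes trajectories bitwise reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.0019872; // kcal/mol/K

struct MapPot {
  std::vector<double> v;
  int nx, ny, nz;
  double ox, oy, oz, vx, vy, vz;
  double zeta;
  bool present;
  MapPot() : present(false) {}
};

static MapPot unpack_pot(Nullable<List> pot_) {
  MapPot p;
  if (pot_.isNull()) return p;
  List pot(pot_);
  NumericVector vals = pot["values"];
  IntegerVector dim = vals.attr("dim");
  p.nx = dim[0]; p.ny = dim[1]; p.nz = dim[2];
  p.v.assign(vals.begin(), vals.end());
  NumericVector o = pot["origin"], vx = pot["voxel"];
  p.ox = o[0]; p.oy = o[1]; p.oz = o[2];
  p.vx = vx[0]; p.vy = vx[1]; p.vz = vx[2];
  p.zeta = as<double>(pot["zeta"]);
  p.present = true;
  return p;
}

// Trilinear interpolation of the potential and its exact gradient.
// Outside the grid (or in the outermost half-open cell) the potential is the
// flat plateau value zeta with zero force.
static inline double interp_pot(const MapPot& p, double x, double y, double z,
                                double* gx, double* gy, double* gz) {
  *gx = *gy = *gz = 0.0;
  double fx = (x - p.ox) / p.vx, fy = (y - p.oy) / p.vy, fz = (z - p.oz) / p.vz;
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
  if (i0 < 0 || i0 >= p.nx - 1 || j0 < 0 || j0 >= p.ny - 1 || k0 < 0 || k0 >= p.nz - 1)
    return p.zeta;
  double tx = fx - i0, ty = fy - j0, tz = fz - k0;
  const double* v = p.v.data();
  long nx = p.nx, nxy = (long)p.nx * p.ny;
  long base = i0 + (long)j0 * nx + (long)k0 * nxy;
  double c000 = v[base],            c100 = v[base + 1];
  double c010 = v[base + nx],       c110 = v[base + nx + 1];
  double c001 = v[base + nxy],      c101 = v[base + nxy + 1];
  double c011 = v[base + nx + nxy], c111 = v[base + nx + nxy + 1];
  double c00 = c000 * (1 - tx) + c100 * tx;
  double c10 = c010 * (1 - tx) + c110 * tx;
  double c01 = c001 * (1 - tx) + c101 * tx;
  double c11 = c011 * (1 - tx) + c111 * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  double val = c0 * (1 - tz) + c1 * tz;
  // dV/dtx etc., then chain rule through voxel spacing
  double dx = ((c100 - c000) * (1 - ty) + (c110 - c010) * ty) * (1 - tz) +
              ((c101 - c001) * (1 - ty) + (c111 - c011) * ty) * tz;
  double dy = (c10 - c00) * (1 - tz) + (c11 - c01) * tz;
  double dz = c1 - c0;
  *gx = dx / p.vx; *gy = dy / p.vy; *gz = dz / p.vz;
  return val;
}

static inline double wrap_pi(double x) {
  while (x > M_PI) x -= 2.0 * M_PI;
  while (x < -M_PI) x += 2.0 * M_PI;
  return x;
}

struct EnergyOut { double u_bond, u_angle, u_dih, u_contact, u_ev, u_ss, u_em; };

// Accumulate all forces into F (N x 3, row-major triples) and return energies.
static EnergyOut compute_forces(const std::vector<double>& X, int n,
                                const NumericMatrix& bonds,
                                const NumericMatrix& angles,
                                const NumericMatrix& dihedrals,
                                const NumericMatrix& contacts,
                                const IntegerMatrix& evpairs,
                                double ev_sigma, double ev_eps, double ev_cutoff,
                                const NumericMatrix& rdih,
                                const NumericMatrix& rdist,
                                const MapPot& pot,
                                const std::vector<double>& w,
                                std::vector<double>& F) {
  EnergyOut e = {0, 0, 0, 0, 0, 0, 0};
  std::fill(F.begin(), F.end(), 0.0);
  const double* x = X.data();

  // bonds: U = k/2 (r - r0)^2
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
    double r0 = bonds(b, 2), k = bonds(b, 3);
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - r0;
    e.u_bond += 0.5 * k * dr * dr;
    double fac = -k * dr / std::max(r, 1e-12);
    F[3*i] += fac * dx; F[3*i+1] += fac * dy; F[3*i+2] += fac * dz;
    F[3*j] -= fac * dx; F[3*j+1] -= fac * dy; F[3*j+2] -= fac * dz;
  }

  // angles: U = k/2 (theta - th0)^2, vertex is the middle bead
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = (int)angles(a, 0) - 1, j = (int)angles(a, 1) - 1, k2 = (int)angles(a, 2) - 1;
    double th0 = angles(a, 3), kth = angles(a, 4);
    double ux = x[3*i] - x[3*j], uy = x[3*i+1] - x[3*j+1], uz = x[3*i+2] - x[3*j+2];
    double wx = x[3*k2] - x[3*j], wy = x[3*k2+1] - x[3*j+1], wz = x[3*k2+2] - x[3*j+2];
    double nu = std::sqrt(ux*ux + uy*uy + uz*uz), nw = std::sqrt(wx*wx + wy*wy + wz*wz);
    double c = (ux*wx + uy*wy + uz*wz) / (nu * nw);
    c = std::max(-1.0, std::min(1.0, c));
    double s = std::sqrt(std::max(1.0 - c * c, 1e-12));
    double th = std::acos(c);
    double dth = th - th0;
    e.u_angle += 0.5 * kth * dth * dth;
    double coef = kth * dth / s;
    double fi_x = coef * (wx / nw - c * ux / nu) / nu;
    double fi_y = coef * (wy / nw - c * uy / nu) / nu;
    double fi_z = coef * (wz / nw - c * uz / nu) / nu;
    double fk_x = coef * (ux / nu - c * wx / nw) / nw;
    double fk_y = coef * (uy / nu - c * wy / nw) / nw;
    double fk_z = coef * (uz / nu - c * wz / nw) / nw;
    F[3*i] += fi_x; F[3*i+1] += fi_y; F[3*i+2] += fi_z;
    F[3*k2] += fk_x; F[3*k2+1] += fk_y; F[3*k2+2] += fk_z;
    F[3*j] -= fi_x + fk_x; F[3*j+1] -= fi_y + fk_y; F[3*j+2] -= fi_z + fk_z;
  }

  // dihedral helper shared by Go dihedrals and harmonic SS restraints
  auto dihedral_term = [&](int i, int j, int k2, int l, double phi0,
                           double kd, bool harmonic, double& u_acc) {
    double b1x = x[3*j] - x[3*i], b1y = x[3*j+1] - x[3*i+1], b1z = x[3*j+2] - x[3*i+2];
    double b2x = x[3*k2] - x[3*j], b2y = x[3*k2+1] - x[3*j+1], b2z = x[3*k2+2] - x[3*j+2];
    double b3x = x[3*l] - x[3*k2], b3y = x[3*l+1] - x[3*k2+1], b3z = x[3*l+2] - x[3*k2+2];
    double n1x = b1y*b2z - b1z*b2y, n1y = b1z*b2x - b1x*b2z, n1z = b1x*b2y - b1y*b2x;
    double n2x = b2y*b3z - b2z*b3y, n2y = b2z*b3x - b2x*b3z, n2z = b2x*b3y - b2y*b3x;
    double n1sq = n1x*n1x + n1y*n1y + n1z*n1z;
    double n2sq = n2x*n2x + n2y*n2y + n2z*n2z;
    double nb2 = std::sqrt(b2x*b2x + b2y*b2y + b2z*b2z);
    if (n1sq < 1e-12 || n2sq < 1e-12 || nb2 < 1e-12) return;
    double mx = n1y*n2z - n1z*n2y, my = n1z*n2x - n1x*n2z, mz = n1x*n2y - n1y*n2x;
    double sinp = (mx*b2x + my*b2y + mz*b2z) / nb2;
    double cosp = n1x*n2x + n1y*n2y + n1z*n2z;
    double phi = std::atan2(sinp, cosp);
    double dphi = wrap_pi(phi - phi0);
    double dudphi;
    if (harmonic) {
      u_acc += 0.5 * kd * dphi * dphi;
      dudphi = kd * dphi;
    } else {
      u_acc += kd * (1.0 - std::cos(dphi)) + 0.5 * kd * (1.0 - std::cos(3.0 * dphi));
      dudphi = kd * std::sin(dphi) + 1.5 * kd * std::sin(3.0 * dphi);
    }
    // dphi/dr (Blondel-Karplus form)
    double gix = -nb2 / n1sq * n1x, giy = -nb2 / n1sq * n1y, giz = -nb2 / n1sq * n1z;
    double glx =  nb2 / n2sq * n2x, gly =  nb2 / n2sq * n2y, glz =  nb2 / n2sq * n2z;
    double d12 = (b1x*b2x + b1y*b2y + b1z*b2z) / (nb2 * nb2);
    double d32 = (b3x*b2x + b3y*b2y + b3z*b2z) / (nb2 * nb2);
    double gjx = -(1.0 + d12) * gix + d32 * glx;
    double gjy = -(1.0 + d12) * giy + d32 * gly;
    double gjz = -(1.0 + d12) * giz + d32 * glz;
    double gkx = d12 * gix - (1.0 + d32) * glx;
    double gky = d12 * giy - (1.0 + d32) * gly;
    double gkz = d12 * giz - (1.0 + d32) * glz;
    F[3*i] -= dudphi * gix; F[3*i+1] -= dudphi * giy; F[3*i+2] -= dudphi * giz;
    F[3*j] -= dudphi * gjx; F[3*j+1] -= dudphi * gjy; F[3*j+2] -= dudphi * gjz;
    F[3*k2] -= dudphi * gkx; F[3*k2+1] -= dudphi * gky; F[3*k2+2] -= dudphi * gkz;
    F[3*l] -= dudphi * glx; F[3*l+1] -= dudphi * gly; F[3*l+2] -= dudphi * glz;
  };

  for (int d = 0; d < dihedrals.nrow(); ++d)
    dihedral_term((int)dihedrals(d, 0) - 1, (int)dihedrals(d, 1) - 1,
                  (int)dihedrals(d, 2) - 1, (int)dihedrals(d, 3) - 1,
                  dihedrals(d, 4), dihedrals(d, 5), false, e.u_dih);

  // native contacts: LJ 10-12, U = eps (5 q^12 - 6 q^10), q = r0/r, min -eps at r0
  for (int c = 0; c < contacts.nrow(); ++c) {
    int i = (int)contacts(c, 0) - 1, j = (int)contacts(c, 1) - 1;
    double r0 = contacts(c, 2), eps = contacts(c, 3);
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double r2 = dx*dx + dy*dy + dz*dz;
    double r = std::sqrt(r2);
    double q2 = (r0 * r0) / r2;
    double q10 = q2 * q2 * q2 * q2 * q2, q12 = q10 * q2;
    e.u_contact += eps * (5.0 * q12 - 6.0 * q10);
    double dudr = -60.0 * eps * (q12 - q10) / r;  // dU/dr
    double fac = -dudr / r;
    F[3*i] += fac * dx; F[3*i+1] += fac * dy; F[3*i+2] += fac * dz;
    F[3*j] -= fac * dx; F[3*j+1] -= fac * dy; F[3*j+2] -= fac * dz;
  }

  // soft excluded volume on non-bonded, non-contact pairs (energy-shifted r^-12)
  if (evpairs.nrow() > 0 && ev_eps > 0) {
    double rc2 = ev_cutoff * ev_cutoff;
    double s12 = std::pow(ev_sigma, 12.0);
    double shift = s12 / std::pow(ev_cutoff, 12.0);
    for (int p2 = 0; p2 < evpairs.nrow(); ++p2) {
      int i = evpairs(p2, 0) - 1, j = evpairs(p2, 1) - 1;
      double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= rc2) continue;
      double inv2 = 1.0 / r2;
      double inv12 = inv2 * inv2 * inv2; inv12 *= inv12;
      e.u_ev += ev_eps * (s12 * inv12 - shift);
      double fac = 12.0 * ev_eps * s12 * inv12 * inv2; // -dU/dr / r
      F[3*i] += fac * dx; F[3*i+1] += fac * dy; F[3*i+2] += fac * dz;
      F[3*j] -= fac * dx; F[3*j+1] -= fac * dy; F[3*j+2] -= fac * dz;
    }
  }

  // secondary-structure restraints: harmonic pseudo-dihedrals + 1-4 distances
  for (int d = 0; d < rdih.nrow(); ++d)
    dihedral_term((int)rdih(d, 0) - 1, (int)rdih(d, 1) - 1,
                  (int)rdih(d, 2) - 1, (int)rdih(d, 3) - 1,
                  rdih(d, 4), rdih(d, 5), true, e.u_ss);
  for (int b = 0; b < rdist.nrow(); ++b) {
    int i = (int)rdist(b, 0) - 1, j = (int)rdist(b, 1) - 1;
    double r0 = rdist(b, 2), k = rdist(b, 3);
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - r0;
    e.u_ss += 0.5 * k * dr * dr;
    double fac = -k * dr / std::max(r, 1e-12);
    F[3*i] += fac * dx; F[3*i+1] += fac * dy; F[3*i+2] += fac * dz;
    F[3*j] -= fac * dx; F[3*j+1] -= fac * dy; F[3*j+2] -= fac * dz;
  }

  // map coupling: U_EM = sum_i w_i V(r_i), F_i = -w_i grad V
  if (pot.present) {
    for (int i = 0; i < n; ++i) {
      if (w[i] == 0.0) continue;
      double gx, gy, gz;
      double v = interp_pot(pot, x[3*i], x[3*i+1], x[3*i+2], &gx, &gy, &gz);
      e.u_em += w[i] * v;
      F[3*i] -= w[i] * gx; F[3*i+1] -= w[i] * gy; F[3*i+2] -= w[i] * gz;
    }
  }
  return e;
}

struct Unpacked {
  NumericMatrix bonds, angles, dihedrals, contacts, rdih, rdist;
  IntegerMatrix evpairs;
  double ev_sigma, ev_eps, ev_cutoff;
};

static Unpacked unpack(List topo, List restr) {
  Unpacked u;
  u.bonds = as<NumericMatrix>(topo["bonds"]);
  u.angles = as<NumericMatrix>(topo["angles"]);
  u.dihedrals = as<NumericMatrix>(topo["dihedrals"]);
  u.contacts = as<NumericMatrix>(topo["contacts"]);
  u.evpairs = as<IntegerMatrix>(topo["ev_pairs"]);
  u.ev_sigma = as<double>(topo["ev_sigma"]);
  u.ev_eps = as<double>(topo["ev_eps"]);
  u.ev_cutoff = as<double>(topo["ev_cutoff"]);
  u.rdih = as<NumericMatrix>(restr["dihedrals"]);
  u.rdist = as<NumericMatrix>(restr["distances"]);
  return u;
}

// [[Rcpp::export]]
List cg_energy_forces_cpp(NumericMatrix X, List topo, List restraints,
                          Nullable<List> potential, NumericVector weights) {
  int n = X.nrow();
  Unpacked u = unpack(topo, restraints);
  MapPot pot = unpack_pot(potential);
  std::vector<double> xs(3 * n), F(3 * n), w(weights.begin(), weights.end());
  for (int i = 0; i < n; ++i) {
    xs[3*i] = X(i, 0); xs[3*i+1] = X(i, 1); xs[3*i+2] = X(i, 2);
    if (!std::isfinite(xs[3*i]) || !std::isfinite(xs[3*i+1]) || !std::isfinite(xs[3*i+2]))
      stop("non-finite bead position at index %d", i + 1);
  }
  EnergyOut e = compute_forces(xs, n, u.bonds, u.angles, u.dihedrals, u.contacts,
                               u.evpairs, u.ev_sigma, u.ev_eps, u.ev_cutoff,
                               u.rdih, u.rdist, pot, w, F);
  NumericMatrix Fout(n, 3);
  for (int i = 0; i < n; ++i) {
    Fout(i, 0) = F[3*i]; Fout(i, 1) = F[3*i+1]; Fout(i, 2) = F[3*i+2];
  }
  double u_md = e.u_bond + e.u_angle + e.u_dih + e.u_contact + e.u_ev;
  return List::create(_["U_md"] = u_md, _["U_ss"] = e.u_ss, _["U_em"] = e.u_em,
                      _["U_total"] = u_md + e.u_ss + e.u_em,
                      _["forces"] = Fout);
}

// BAOAB Langevin integrator.  dt and gamma are in AKMA units; temps gives the
// target temperature (K) at every step.  With gamma = 0 this reduces to
// velocity Verlet (NVE).  Frames are recorded every `stride` steps.
// [[Rcpp::export]]
List run_langevin_cpp(NumericMatrix X0, NumericMatrix V0, NumericVector mass,
                      List topo, List restraints, Nullable<List> potential,
                      NumericVector weights, double dt, double gamma,
                      NumericVector temps, int nsteps, int stride) {
  int n = X0.nrow();
  Unpacked u = unpack(topo, restraints);
  MapPot pot = unpack_pot(potential);
  std::vector<double> xs(3 * n), vs(3 * n), F(3 * n), w(weights.begin(), weights.end());
  for (int i = 0; i < n; ++i) {
    xs[3*i] = X0(i, 0); xs[3*i+1] = X0(i, 1); xs[3*i+2] = X0(i, 2);
    vs[3*i] = V0(i, 0); vs[3*i+1] = V0(i, 1); vs[3*i+2] = V0(i, 2);
  }
  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (gamma > 0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  int nframes = nsteps / stride;
  NumericVector frames(Dimension(nframes, n, 3));
  NumericMatrix energies(nframes, 6); // step, U_md, U_ss, U_em, U_total, Ekin
  colnames(energies) = CharacterVector::create("step", "U_md", "U_ss", "U_em",
                                               "U_total", "E_kin");
  EnergyOut e = compute_forces(xs, n, u.bonds, u.angles, u.dihedrals, u.contacts,
                               u.evpairs, u.ev_sigma, u.ev_eps, u.ev_cutoff,
                               u.rdih, u.rdist, pot, w, F);
  int fidx = 0;
  for (int step = 0; step < nsteps; ++step) {
    double half = 0.5 * dt;
    for (int i = 0; i < n; ++i) {
      double im = 1.0 / mass[i];
      vs[3*i] += half * F[3*i] * im;
      vs[3*i+1] += half * F[3*i+1] * im;
      vs[3*i+2] += half * F[3*i+2] * im;
      xs[3*i] += half * vs[3*i];
      xs[3*i+1] += half * vs[3*i+1];
      xs[3*i+2] += half * vs[3*i+2];
    }
    if (gamma > 0) {
      double kT = KB * temps[step];
      for (int i = 0; i < n; ++i) {
        double sd = std::sqrt(kT / mass[i]);
        vs[3*i] = c1 * vs[3*i] + c2 * sd * norm_rand();
        vs[3*i+1] = c1 * vs[3*i+1] + c2 * sd * norm_rand();
        vs[3*i+2] = c1 * vs[3*i+2] + c2 * sd * norm_rand();
      }
    }
    for (int i = 0; i < n; ++i) {
      xs[3*i] += half * vs[3*i];
      xs[3*i+1] += half * vs[3*i+1];
      xs[3*i+2] += half * vs[3*i+2];
    }
    e = compute_forces(xs, n, u.bonds, u.angles, u.dihedrals, u.contacts,
                       u.evpairs, u.ev_sigma, u.ev_eps, u.ev_cutoff,
                       u.rdih, u.rdist, pot, w, F);
    double u_md = e.u_bond + e.u_angle + e.u_dih + e.u_contact + e.u_ev;
    double u_tot = u_md + e.u_ss + e.u_em;
    if (!std::isfinite(u_tot) || std::fabs(u_tot) > 1e12)
      stop("dynamics unstable at step %d (energy %g): reduce the timestep", step + 1, u_tot);
    for (int i = 0; i < n; ++i) {
      double im = 1.0 / mass[i];
      vs[3*i] += half * F[3*i] * im;
      vs[3*i+1] += half * F[3*i+1] * im;
      vs[3*i+2] += half * F[3*i+2] * im;
    }
    if ((step + 1) % stride == 0 && fidx < nframes) {
      double ekin = 0.0;
      for (int i = 0; i < n; ++i)
        ekin += 0.5 * mass[i] * (vs[3*i]*vs[3*i] + vs[3*i+1]*vs[3*i+1] + vs[3*i+2]*vs[3*i+2]);
      for (int i = 0; i < n; ++i) {
        frames[fidx + (long)nframes * i] = xs[3*i];
        frames[fidx + (long)nframes * (n + i)] = xs[3*i+1];
        frames[fidx + (long)nframes * (2L * n + i)] = xs[3*i+2];
      }
      energies(fidx, 0) = step + 1;
      energies(fidx, 1) = u_md; energies(fidx, 2) = e.u_ss; energies(fidx, 3) = e.u_em;
      energies(fidx, 4) = u_tot; energies(fidx, 5) = ekin;
      ++fidx;
    }
  }
  NumericMatrix Xout(n, 3), Vout(n, 3);
  for (int i = 0; i < n; ++i) {
    Xout(i, 0) = xs[3*i]; Xout(i, 1) = xs[3*i+1]; Xout(i, 2) = xs[3*i+2];
    Vout(i, 0) = vs[3*i]; Vout(i, 1) = vs[3*i+1]; Vout(i, 2) = vs[3*i+2];
  }
  return List::create(_["X"] = Xout, _["V"] = Vout, _["frames"] = frames,
                      _["energies"] = energies);
}

// Steepest descent with backtracking line search; deterministic.
// [[Rcpp::export]]
List minimize_cpp(NumericMatrix X0, List topo, List restraints,
                  Nullable<List> potential, NumericVector weights, int steps) {
  int n = X0.nrow();
  Unpacked u = unpack(topo, restraints);
  MapPot pot = unpack_pot(potential);
  std::vector<double> xs(3 * n), xt(3 * n), F(3 * n), w(weights.begin(), weights.end());
  for (int i = 0; i < n; ++i) {
    xs[3*i] = X0(i, 0); xs[3*i+1] = X0(i, 1); xs[3*i+2] = X0(i, 2);
  }
  EnergyOut e = compute_forces(xs, n, u.bonds, u.angles, u.dihedrals, u.contacts,
                               u.evpairs, u.ev_sigma, u.ev_eps, u.ev_cutoff,
                               u.rdih, u.rdist, pot, w, F);
  double U = e.u_bond + e.u_angle + e.u_dih + e.u_contact + e.u_ev + e.u_ss + e.u_em;
  if (!std::isfinite(U)) stop("minimization started from a non-finite energy");
  double alpha = 0.02; // initial step, Angstrom per unit force
  for (int s = 0; s < steps; ++s) {
    double fmax = 0.0;
    for (int i = 0; i < 3 * n; ++i) fmax = std::max(fmax, std::fabs(F[i]));
    if (fmax < 1e-10) break;
    double scale = alpha / std::max(fmax, 1.0);
    bool accepted = false;
    for (int tries = 0; tries < 30; ++tries) {
      for (int i = 0; i < 3 * n; ++i) xt[i] = xs[i] + scale * F[i];
      std::vector<double> Ft(3 * n);
      EnergyOut et = compute_forces(xt, n, u.bonds, u.angles, u.dihedrals, u.contacts,
                                    u.evpairs, u.ev_sigma, u.ev_eps, u.ev_cutoff,
                                    u.rdih, u.rdist, pot, w, Ft);
      double Ut = et.u_bond + et.u_angle + et.u_dih + et.u_contact + et.u_ev +
                  et.u_ss + et.u_em;
      if (std::isfinite(Ut) && Ut <= U) {
        xs.swap(xt); F.swap(Ft); U = Ut; e = et;
        alpha = std::min(alpha * 1.2, 0.5);
        accepted = true;
        break;
      }
      scale *= 0.5;
      alpha *= 0.5;
    }
    if (!accepted) break;
    if (!std::isfinite(U)) stop("minimization diverged (energy became non-finite)");
  }
  NumericMatrix Xout(n, 3);
  for (int i = 0; i < n; ++i) {
    Xout(i, 0) = xs[3*i]; Xout(i, 1) = xs[3*i+1]; Xout(i, 2) = xs[3*i+2];
  }
  double u_md = e.u_bond + e.u_angle + e.u_dih + e.u_contact + e.u_ev;
  return List::create(_["X"] = Xout, _["U_md"] = u_md, _["U_ss"] = e.u_ss,
                      _["U_em"] = e.u_em, _["U_total"] = U);
}
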