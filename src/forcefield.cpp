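// Lightweight small-molecule force field: harmonic bonds and angles, cosine
// torsions, Lennard-Jones 12-6, and Coulomb electrostatics with a
// distance-dependent dielectric eps = 4R (so E_el = 332.0637 q_i q_j / (4 R^2)).
// Energies in kcal/mol, distances in Angstrom.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void axpy3(double a, const double *x, double *y) {
  y[0] += a * x[0]; y[1] += a * x[1]; y[2] += a * x[2];
}

static inline void cross(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// [[Rcpp::export(name = ".ff_energy_gradient")]]
List ff_energy_gradient(NumericVector coords,
                        IntegerMatrix bonds, NumericVector bond_r0, NumericVector bond_k,
                        IntegerMatrix angles, NumericVector angle_t0, NumericVector angle_k,
                        IntegerMatrix torsions, IntegerVector tor_n,
                        NumericVector tor_phi0, NumericVector tor_v,
                        IntegerMatrix nb, NumericVector nb_qfac,
                        NumericVector nb_eps, NumericVector nb_rmin,
                        bool want_gradient) {
  const int natom = coords.size() / 3;
  const double *x = coords.begin();
  NumericVector grad(want_gradient ? coords.size() : 0);
  double *g = grad.begin();
  double energy = 0.0;

  // bonds
  for (int b = 0; b < bonds.nrow(); ++b) {
    const int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1], x[3 * i + 2] - x[3 * j + 2]};
    double r = std::sqrt(dot(d, d));
    double dr = r - bond_r0[b];
    energy += bond_k[b] * dr * dr;
    if (want_gradient && r > 1e-12) {
      double f = 2.0 * bond_k[b] * dr / r;
      axpy3(f, d, g + 3 * i);
      axpy3(-f, d, g + 3 * j);
    }
  }

  // angles (i - j - k, j central)
  for (int a = 0; a < angles.nrow(); ++a) {
    const int i = angles(a, 0) - 1, j = angles(a, 1) - 1, k = angles(a, 2) - 1;
    double u[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1], x[3 * i + 2] - x[3 * j + 2]};
    double v[3] = {x[3 * k] - x[3 * j], x[3 * k + 1] - x[3 * j + 1], x[3 * k + 2] - x[3 * j + 2]};
    double nu = std::sqrt(dot(u, u)), nv = std::sqrt(dot(v, v));
    if (nu < 1e-12 || nv < 1e-12) continue;
    double c = dot(u, v) / (nu * nv);
    c = std::max(-1.0, std::min(1.0, c));
    double theta = std::acos(c);
    double dt = theta - angle_t0[a];
    energy += angle_k[a] * dt * dt;
    if (want_gradient) {
      double s = std::sqrt(std::max(1e-8, 1.0 - c * c));
      double dEdt = 2.0 * angle_k[a] * dt;
      double gi[3], gk[3];
      for (int d = 0; d < 3; ++d) {
        gi[d] = (c * u[d] / nu - v[d] / nv) / (nu * s);
        gk[d] = (c * v[d] / nv - u[d] / nu) / (nv * s);
      }
      for (int d = 0; d < 3; ++d) {
        g[3 * i + d] += dEdt * gi[d];
        g[3 * k + d] += dEdt * gk[d];
        g[3 * j + d] -= dEdt * (gi[d] + gk[d]);
      }
    }
  }

  // torsions (i - j - k - l)
  for (int t = 0; t < torsions.nrow(); ++t) {
    const int i = torsions(t, 0) - 1, j = torsions(t, 1) - 1;
    const int k = torsions(t, 2) - 1, l = torsions(t, 3) - 1;
    double b1[3] = {x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1], x[3 * j + 2] - x[3 * i + 2]};
    double b2[3] = {x[3 * k] - x[3 * j], x[3 * k + 1] - x[3 * j + 1], x[3 * k + 2] - x[3 * j + 2]};
    double b3[3] = {x[3 * l] - x[3 * k], x[3 * l + 1] - x[3 * k + 1], x[3 * l + 2] - x[3 * k + 2]};
    double n1[3], n2[3];
    cross(b1, b2, n1);
    cross(b2, b3, n2);
    double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
    double nb2 = std::sqrt(dot(b2, b2));
    if (n1sq < 1e-10 || n2sq < 1e-10 || nb2 < 1e-10) continue;
    double m[3];
    cross(n1, n2, m);
    double yv = dot(m, b2) / nb2;
    double xv = dot(n1, n2);
    double phi = std::atan2(yv, xv);
    double arg = tor_n[t] * phi - tor_phi0[t];
    energy += 0.5 * tor_v[t] * (1.0 + std::cos(arg));
    if (want_gradient) {
      double dEdphi = -0.5 * tor_v[t] * tor_n[t] * std::sin(arg);
      double F[3], G[3];
      for (int d = 0; d < 3; ++d) {
        F[d] = -(nb2 / n1sq) * n1[d]; // dphi/dpi
        G[d] = (nb2 / n2sq) * n2[d];  // dphi/dpl
      }
      double c12 = dot(b1, b2) / (nb2 * nb2);
      double c32 = dot(b3, b2) / (nb2 * nb2);
      for (int d = 0; d < 3; ++d) {
        double gj = -(1.0 + c12) * F[d] + c32 * G[d];
        double gk2 = -(1.0 + c32) * G[d] + c12 * F[d];
        g[3 * i + d] += dEdphi * F[d];
        g[3 * j + d] += dEdphi * gj;
        g[3 * k + d] += dEdphi * gk2;
        g[3 * l + d] += dEdphi * G[d];
      }
    }
  }

  // nonbonded pairs: LJ 12-6 (rmin form) + Coulomb with eps = 4R
  for (int p = 0; p < nb.nrow(); ++p) {
    const int i = nb(p, 0) - 1, j = nb(p, 1) - 1;
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1], x[3 * i + 2] - x[3 * j + 2]};
    double r2 = dot(d, d);
    if (r2 < 1e-6) r2 = 1e-6;
    double r = std::sqrt(r2);
    double rm = nb_rmin[p];
    double s6 = std::pow(rm * rm / r2, 3.0);
    double elj = nb_eps[p] * (s6 * s6 - 2.0 * s6);
    double eel = nb_qfac[p] / r2; // qfac = 332.0637 * qi * qj * scale / 4
    energy += elj + eel;
    if (want_gradient) {
      // dE/dr * 1/r
      double dlj = nb_eps[p] * (-12.0 * s6 * s6 + 12.0 * s6) / r2;
      double del = -2.0 * nb_qfac[p] / (r2 * r2);
      double f = dlj + del;
      axpy3(f, d, g + 3 * i);
      axpy3(-f, d, g + 3 * j);
    }
  }

  if (want_gradient) return List::create(_["energy"] = energy, _["gradient"] = grad);
  return List::create(_["energy"] = energy);
}
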