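// Grid-based pocket scoring.
//
// Three channels are precomputed on a regular lattice over the pocket box:
//   surf: buried-surface reward, a negative Gaussian shell at contact
//         distance (vdw + probe) from each receptor atom;
//   elec: Coulomb potential of the receptor charges with the
//         distance-dependent dielectric eps = 4R (kcal/mol per unit charge);
//   rep : soft-core penalty inside the receptor vdW envelope.
// A pose is scored by trilinear interpolation at each ligand atom:
//   score = sum_atoms w_surf*surf + w_elec*q_atom*elec + w_rep*rep.
// Lower is better. The pose search is exhaustive and deterministic.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".grid_build")]]
List grid_build(NumericMatrix rec_xyz, NumericVector rec_q, NumericVector rec_vdw,
                NumericVector origin, NumericVector spacing, IntegerVector dims,
                double probe, double shell_width, double rep_range, double rep_k,
                double surf_cap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t npt = (R_xlen_t)nx * ny * nz;
  NumericVector surf(npt), elec(npt), rep(npt);
  const int natom = rec_xyz.nrow();
  const double elec_cut = 12.0;

  for (int a = 0; a < natom; ++a) {
    const double ax = rec_xyz(a, 0), ay = rec_xyz(a, 1), az = rec_xyz(a, 2);
    const double q = rec_q[a], vr = rec_vdw[a];
    const double rc = vr + probe;
    const double rrep = vr + rep_range;
    double cut = rc + 3.0 * shell_width;
    if (q != 0.0 && elec_cut > cut) cut = elec_cut;
    // lattice sub-range within cutoff
    int ix0 = (int)std::ceil((ax - cut - origin[0]) / spacing[0]);
    int ix1 = (int)std::floor((ax + cut - origin[0]) / spacing[0]);
    int iy0 = (int)std::ceil((ay - cut - origin[1]) / spacing[1]);
    int iy1 = (int)std::floor((ay + cut - origin[1]) / spacing[1]);
    int iz0 = (int)std::ceil((az - cut - origin[2]) / spacing[2]);
    int iz1 = (int)std::floor((az + cut - origin[2]) / spacing[2]);
    if (ix0 < 0) ix0 = 0; if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy0 < 0) iy0 = 0; if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz0 < 0) iz0 = 0; if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * spacing[2] - az;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * spacing[1] - ay;
        const double d2xy = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + ix * spacing[0] - ax;
          const double r2 = dx * dx + d2xy;
          const double r = std::sqrt(r2);
          R_xlen_t idx = base + ix;
          const double dr = r - rc;
          if (std::fabs(dr) < 3.0 * shell_width) {
            surf[idx] -= std::exp(-dr * dr / (2.0 * shell_width * shell_width));
          }
          if (q != 0.0 && r < elec_cut) {
            double reff = r < 1.0 ? 1.0 : r;
            elec[idx] += 332.0637 * q / (4.0 * reff * reff);
          }
          if (r < rrep) {
            const double t = (rrep - r) / rep_range;
            rep[idx] += rep_k * t * t;
          }
        }
      }
    }
  }
  // Burial saturates: a surface patch can only be buried once (ASA-like),
  // so the contact reward is clamped while repulsion keeps growing.
  if (surf_cap > 0) {
    for (R_xlen_t i = 0; i < npt; ++i) {
      if (surf[i] < -surf_cap) surf[i] = -surf_cap;
    }
  }
  return List::create(_["surf"] = surf, _["elec"] = elec, _["rep"] = rep);
}

static inline bool trilinear(const double *grid, int nx, int ny, int nz,
                             const double *origin, const double *spacing,
                             double x, double y, double z, double &val) {
  const double fx = (x - origin[0]) / spacing[0];
  const double fy = (y - origin[1]) / spacing[1];
  const double fz = (z - origin[2]) / spacing[2];
  if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1)
    return false;
  int ix = (int)fx, iy = (int)fy, iz = (int)fz;
  if (ix > nx - 2) ix = nx - 2;
  if (iy > ny - 2) iy = ny - 2;
  if (iz > nz - 2) iz = nz - 2;
  const double tx = fx - ix, ty = fy - iy, tz = fz - iz;
  double acc = 0.0;
  for (int c = 0; c < 8; ++c) {
    const int ox = c & 1, oy = (c >> 1) & 1, oz = (c >> 2) & 1;
    const double w = (ox ? tx : 1 - tx) * (oy ? ty : 1 - ty) * (oz ? tz : 1 - tz);
    const R_xlen_t idx = (R_xlen_t)(ix + ox) +
      (R_xlen_t)nx * ((iy + oy) + (R_xlen_t)ny * (iz + oz));
    acc += w * grid[idx];
  }
  val = acc;
  return true;
}

// Exhaustive pose scan for one conformer: rotations x translation lattice.
// conf_xyz must be centered (centroid at origin). Returns the best (lowest)
// score with its pose, and the number of fully scored poses. The charge-
// independent channels are combined once (combo = w_surf*surf + w_rep*rep);
// the electrostatic term is only interpolated when it can be nonzero.
// [[Rcpp::export(name = ".dock_scan")]]
List dock_scan(NumericMatrix conf_xyz, NumericVector lig_q,
               NumericMatrix rotations, // nrot x 9, row-major 3x3
               NumericVector origin, NumericVector spacing, IntegerVector dims,
               NumericVector surf, NumericVector elec, NumericVector rep,
               NumericVector box_lo, NumericVector box_hi, double tstep,
               double w_surf, double w_elec, double w_rep) {
  const int natom = conf_xyz.nrow();
  const int nrot = rotations.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *org = origin.begin(), *spc = spacing.begin();

  std::vector<double> combo(surf.size());
  double c_min = 0.0, e_absmax = 0.0;
  for (R_xlen_t i = 0; i < surf.size(); ++i) {
    combo[i] = w_surf * surf[i] + w_rep * rep[i];
    if (combo[i] < c_min) c_min = combo[i];
    const double ae = std::fabs(elec[i]);
    if (ae > e_absmax) e_absmax = ae;
  }
  double q_absmax = 0.0;
  for (int a = 0; a < natom; ++a) {
    const double aq = std::fabs(lig_q[a]);
    if (aq > q_absmax) q_absmax = aq;
  }
  const bool has_elec = (w_elec != 0.0) && (e_absmax > 0.0) && (q_absmax > 0.0);
  // branch-and-bound: a per-atom lower bound on the score contribution lets
  // hopeless poses terminate early without changing the exhaustive optimum
  const double per_atom_lb =
    c_min - (has_elec ? std::fabs(w_elec) * q_absmax * e_absmax : 0.0);
  const double *gc = combo.data(), *ge = elec.begin();

  double best = R_PosInf;
  int best_rot = -1;
  double best_t[3] = {0, 0, 0};
  long n_valid = 0;

  std::vector<double> rx(natom), ry(natom), rz(natom);
  for (int rot = 0; rot < nrot; ++rot) {
    double R9[9];
    for (int k = 0; k < 9; ++k) R9[k] = rotations(rot, k);
    double rlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double rhi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int a = 0; a < natom; ++a) {
      const double x = conf_xyz(a, 0), y = conf_xyz(a, 1), z = conf_xyz(a, 2);
      rx[a] = R9[0] * x + R9[1] * y + R9[2] * z;
      ry[a] = R9[3] * x + R9[4] * y + R9[5] * z;
      rz[a] = R9[6] * x + R9[7] * y + R9[8] * z;
      rlo[0] = std::min(rlo[0], rx[a]); rhi[0] = std::max(rhi[0], rx[a]);
      rlo[1] = std::min(rlo[1], ry[a]); rhi[1] = std::max(rhi[1], ry[a]);
      rlo[2] = std::min(rlo[2], rz[a]); rhi[2] = std::max(rhi[2], rz[a]);
    }
    // restrict the anchored translation lattice to poses that fit the box
    int k0[3], k1[3];
    bool fits = true;
    for (int d = 0; d < 3; ++d) {
      k0[d] = (int)std::ceil((box_lo[d] - rlo[d] - box_lo[d]) / tstep - 1e-9);
      k1[d] = (int)std::floor((box_hi[d] - rhi[d] - box_lo[d]) / tstep + 1e-9);
      if (k0[d] < 0) k0[d] = 0;
      const int kmax = (int)std::floor((box_hi[d] - box_lo[d]) / tstep);
      if (k1[d] > kmax) k1[d] = kmax;
      if (k0[d] > k1[d]) { fits = false; break; }
    }
    if (!fits) continue;
    for (int itz = k0[2]; itz <= k1[2]; ++itz) {
      const double tz = box_lo[2] + itz * tstep;
      for (int ity = k0[1]; ity <= k1[1]; ++ity) {
        const double ty = box_lo[1] + ity * tstep;
        for (int itx = k0[0]; itx <= k1[0]; ++itx) {
          const double tx = box_lo[0] + itx * tstep;
          double score = 0.0;
          bool ok = true;
          for (int a = 0; a < natom; ++a) {
            double vc, ve;
            const double px = rx[a] + tx, py = ry[a] + ty, pz = rz[a] + tz;
            if (!trilinear(gc, nx, ny, nz, org, spc, px, py, pz, vc)) {
              ok = false;
              break;
            }
            score += vc;
            if (has_elec && lig_q[a] != 0.0) {
              if (!trilinear(ge, nx, ny, nz, org, spc, px, py, pz, ve)) {
                ok = false;
                break;
              }
              score += w_elec * lig_q[a] * ve;
            }
            if (score + (natom - 1 - a) * per_atom_lb >= best) {
              ok = false; // cannot beat the incumbent; pose is still valid,
              break;      // but incomplete scoring must not update `best`
            }
          }
          if (!ok) continue;
          ++n_valid;
          if (score < best) {
            best = score;
            best_rot = rot;
            best_t[0] = tx; best_t[1] = ty; best_t[2] = tz;
          }
        }
      }
    }
  }
  return List::create(
    _["score"] = best, _["rotation_index"] = best_rot + 1,
    _["translation"] = NumericVector::create(best_t[0], best_t[1], best_t[2]),
    _["n_valid_poses"] = (double)n_valid
  );
}
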