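// Numerical kernels for the molecular interaction field engine: probe-field
// energies on a regular grid, level-set summaries, per-atom field minima and
// dot-density solvent-accessible surface areas.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Probe interaction energy at every grid node.
//
// E(node) = sum_atoms [ LJ 12-6 + Coulomb (distance-dependent dielectric
// eps(r) = diel_k * r) + 12-10 hydrogen-bond term for complementary pairs ],
// clamped from above at `clamp`.
//
// Per-atom pair parameters are precomputed in R:
//   eps_pair  sqrt(eps_atom * eps_probe)        [kcal/mol]
//   rmin_pair r_vdw_atom + r_vdw_probe          [Angstrom]
//   qq        332.0636 * q_atom * q_probe       [kcal*A/mol, before dielectric]
//   hb_eps    well depth of the H-bond term, 0 when the pair is not
//             donor/acceptor complementary      [kcal/mol]
//   hb_r0     H-bond equilibrium distance       [Angstrom]
// [[Rcpp::export]]
NumericVector field_energy_grid(NumericMatrix xyz,
                                NumericVector eps_pair,
                                NumericVector rmin_pair,
                                NumericVector qq,
                                NumericVector hb_eps,
                                NumericVector hb_r0,
                                NumericVector origin,
                                double spacing,
                                IntegerVector dims,
                                double diel_k,
                                double clamp) {
  const int natoms = xyz.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nnodes = (R_xlen_t)nx * ny * nz;
  NumericVector energy(nnodes);
  double *e = REAL(energy);
  const double r2min = 0.16; // 0.4 A floor avoids singularities inside atoms
  const double inv_diel = 1.0 / diel_k;

  // accumulate one atom at a time; the inner (x) loop is branch-light
  for (int a = 0; a < natoms; ++a) {
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    const double rm2 = rmin_pair[a] * rmin_pair[a];
    const double epsa = eps_pair[a];
    const double qqa = qq[a] * inv_diel;
    const double ha = hb_eps[a];
    const double h02 = hb_r0[a] * hb_r0[a];
    R_xlen_t idx = 0;
    for (int kz = 0; kz < nz; ++kz) {
      const double dz = origin[2] + kz * spacing - az;
      const double dz2 = dz * dz;
      for (int ky = 0; ky < ny; ++ky) {
        const double dy = origin[1] + ky * spacing - ay;
        const double dyz2 = dy * dy + dz2;
        double dx = origin[0] - ax;
        for (int kx = 0; kx < nx; ++kx, ++idx, dx += spacing) {
          double r2 = dx * dx + dyz2;
          if (r2 < r2min) r2 = r2min;
          const double inv = 1.0 / r2;
          const double s2 = rm2 * inv;
          const double s6 = s2 * s2 * s2;
          double ea = epsa * (s6 * s6 - 2.0 * s6) + qqa * inv;
          if (ha > 0.0) {
            const double t2 = h02 * inv;
            const double t10 = t2 * t2 * t2 * t2 * t2;
            ea += ha * (5.0 * t10 * t2 - 6.0 * t10);
          }
          e[idx] += ea;
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < nnodes; ++i) {
    if (e[i] > clamp) e[i] = clamp;
  }
  return energy;
}

// Energy-weighted level-set summaries of a grid field: for each cutoff c_k,
// the node count with E <= c_k and the |E|-weighted barycenter of those nodes.
// Returns a (n_cutoffs x 5) matrix: count, bx, by, bz, sum|E|.
// [[Rcpp::export]]
NumericMatrix level_set_summary(NumericVector energy,
                                NumericVector origin,
                                double spacing,
                                IntegerVector dims,
                                NumericVector cutoffs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nc = cutoffs.size();
  NumericMatrix out(nc, 5);
  R_xlen_t idx = 0;
  for (int kz = 0; kz < nz; ++kz) {
    const double z = origin[2] + kz * spacing;
    for (int ky = 0; ky < ny; ++ky) {
      const double y = origin[1] + ky * spacing;
      for (int kx = 0; kx < nx; ++kx, ++idx) {
        const double e = energy[idx];
        if (e > cutoffs[0]) continue; // cutoffs ordered shallowest first
        const double x = origin[0] + kx * spacing;
        const double w = -e;
        for (int k = 0; k < nc; ++k) {
          if (e <= cutoffs[k]) {
            out(k, 0) += 1.0;
            out(k, 1) += w * x;
            out(k, 2) += w * y;
            out(k, 3) += w * z;
            out(k, 4) += w;
          }
        }
      }
    }
  }
  return out;
}

// Per-atom field minimum: the lowest node energy within `radius` of each
// atom centre. Used to locate the atoms hosting the strongest polar and
// apolar interactions.
// [[Rcpp::export]]
NumericVector atom_region_min(NumericVector energy,
                              NumericVector origin,
                              double spacing,
                              IntegerVector dims,
                              NumericMatrix xyz,
                              double radius) {
  const int natoms = xyz.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double r2max = radius * radius;
  NumericVector out(natoms);
  for (int a = 0; a < natoms; ++a) {
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    int lo[3], hi[3];
    const double ctr[3] = {ax, ay, az};
    const int nn[3] = {nx, ny, nz};
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::max(0, (int)std::ceil((ctr[d] - radius - origin[d]) /
                                         spacing));
      hi[d] = std::min(nn[d] - 1,
                       (int)std::floor((ctr[d] + radius - origin[d]) /
                                       spacing));
    }
    double best = R_PosInf;
    for (int kz = lo[2]; kz <= hi[2]; ++kz) {
      const double dz = origin[2] + kz * spacing - az;
      for (int ky = lo[1]; ky <= hi[1]; ++ky) {
        const double dy = origin[1] + ky * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2max) continue;
        const R_xlen_t base = ((R_xlen_t)kz * ny + ky) * nx;
        for (int kx = lo[0]; kx <= hi[0]; ++kx) {
          const double dx = origin[0] + kx * spacing - ax;
          if (dx * dx + dyz2 > r2max) continue;
          const double e = energy[base + kx];
          if (e < best) best = e;
        }
      }
    }
    out[a] = best;
  }
  return out;
}

// Solvent-accessible surface area by the dot-density (Shrake-Rupley) method.
// `radius` already includes the solvent probe radius. Returns per-atom SASA.
// [[Rcpp::export]]
NumericVector sasa_dots(NumericMatrix xyz, NumericVector radius, int n_dots) {
  const int natoms = xyz.nrow();
  NumericVector area(natoms);
  // Fibonacci sphere directions, shared across atoms
  std::vector<double> ux(n_dots), uy(n_dots), uz(n_dots);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n_dots; ++i) {
    const double zz = 1.0 - 2.0 * (i + 0.5) / n_dots;
    const double rr = std::sqrt(1.0 - zz * zz);
    const double th = golden * i;
    ux[i] = rr * std::cos(th);
    uy[i] = rr * std::sin(th);
    uz[i] = zz;
  }
  for (int a = 0; a < natoms; ++a) {
    const double ra = radius[a];
    // neighbours that can occlude atom a
    std::vector<int> nb;
    for (int b = 0; b < natoms; ++b) {
      if (b == a) continue;
      const double dx = xyz(a, 0) - xyz(b, 0);
      const double dy = xyz(a, 1) - xyz(b, 1);
      const double dz = xyz(a, 2) - xyz(b, 2);
      const double lim = ra + radius[b];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(b);
    }
    int exposed = 0;
    for (int i = 0; i < n_dots; ++i) {
      const double px = xyz(a, 0) + ra * ux[i];
      const double py = xyz(a, 1) + ra * uy[i];
      const double pz = xyz(a, 2) + ra * uz[i];
      bool free_dot = true;
      for (size_t j = 0; j < nb.size(); ++j) {
        const int b = nb[j];
        const double dx = px - xyz(b, 0);
        const double dy = py - xyz(b, 1);
        const double dz = pz - xyz(b, 2);
        if (dx * dx + dy * dy + dz * dz < radius[b] * radius[b]) {
          free_dot = false;
          break;
        }
      }
      if (free_dot) ++exposed;
    }
    area[a] = 4.0 * M_PI * ra * ra * exposed / n_dots;
  }
  return area;
}
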