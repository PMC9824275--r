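#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <functional>
#include <cmath>
using namespace Rcpp;

// Minimum-image displacement along one box dimension; L <= 0 disables wrapping.
static inline double mi(double d, double L) {
  if (L > 0.0) d -= L * std::nearbyint(d / L);
  return d;
}

// wrap a coordinate into [0, L) without libm fmod
static inline double wrap0(double x, double L) {
  double y = x - L * std::floor(x / L);
  if (y >= L) y -= L;  // guard the x/L rounding edge
  if (y < 0) y = 0;
  return y;
}

// Pairwise forces for the nanoparticle assembly stage (vacuum, no PBC):
// truncated Lennard-Jones attraction between all non-bonded bead pairs,
// harmonic bonds, Debye-screened Coulomb between charged beads, and a weak
// harmonic confinement toward the instantaneous centroid (vacuum-droplet
// surrogate that lets dispersed chains find each other).
// [[Rcpp::export]]
NumericMatrix cpp_pair_forces(const NumericMatrix& pos,
                              const IntegerMatrix& bonds,
                              const NumericVector& r0,
                              double k_bond,
                              const NumericVector& charges,
                              double eps, double sigma, double rcut,
                              double ke, double lambda,
                              double k_confine) {
  const int n = pos.nrow();
  NumericMatrix F(n, 3);
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += pos(i,0); cy += pos(i,1); cz += pos(i,2); }
  cx /= n; cy /= n; cz /= n;

  std::unordered_set<long long> bonded;
  const int m = bonds.nrow();
  for (int b = 0; b < m; ++b) {
    long long i = bonds(b,0), j = bonds(b,1);
    bonded.insert(std::min(i,j) * (long long)n + std::max(i,j));
  }

  bool any_q = false;
  for (int i = 0; i < n; ++i) if (charges[i] != 0.0) { any_q = true; break; }
  const double rc2 = rcut * rcut;
  const double relec = 5.0 * lambda;
  const double rmax = std::max(eps > 0 ? rcut : 0.0,
                               (any_q && ke != 0.0) ? relec : 0.0);
  const double rmax2 = rmax * rmax;

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i,0) - pos(j,0);
      double dy = pos(i,1) - pos(j,1);
      double dz = pos(i,2) - pos(j,2);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 > rmax2 || r2 == 0.0) continue;
      if (bonded.count((long long)i * (long long)n + j)) continue;
      double r = std::sqrt(r2);
      double fmag = 0.0;  // radial force, positive = repulsive
      if (eps > 0 && r2 <= rc2) {
        double sr2 = sigma * sigma / r2;
        double sr6 = sr2 * sr2 * sr2;
        fmag += 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r;
      }
      if (any_q && ke != 0.0 && charges[i] != 0.0 && charges[j] != 0.0 && r <= relec) {
        double v = ke * charges[i] * charges[j] * std::exp(-r / lambda) / r;
        fmag += v * (1.0 / r + 1.0 / lambda);
      }
      if (fmag != 0.0) {
        double fx = fmag * dx / r, fy = fmag * dy / r, fz = fmag * dz / r;
        F(i,0) += fx; F(i,1) += fy; F(i,2) += fz;
        F(j,0) -= fx; F(j,1) -= fy; F(j,2) -= fz;
      }
    }
  }

  for (int b = 0; b < m; ++b) {
    int i = bonds(b,0), j = bonds(b,1);
    double dx = pos(i,0) - pos(j,0);
    double dy = pos(i,1) - pos(j,1);
    double dz = pos(i,2) - pos(j,2);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < 1e-12) continue;
    double fmag = -k_bond * (r - r0[b]);
    double fx = fmag * dx / r, fy = fmag * dy / r, fz = fmag * dz / r;
    F(i,0) += fx; F(i,1) += fy; F(i,2) += fz;
    F(j,0) -= fx; F(j,1) -= fy; F(j,2) -= fz;
  }

  if (k_confine > 0) {
    for (int i = 0; i < n; ++i) {
      F(i,0) -= k_confine * (pos(i,0) - cx);
      F(i,1) -= k_confine * (pos(i,1) - cy);
      F(i,2) -= k_confine * (pos(i,2) - cz);
    }
  }
  return F;
}

// Brute-force closest pair between two bead sets (optionally minimum-image).
// [[Rcpp::export]]
List cpp_min_pair(const NumericMatrix& A, const NumericMatrix& B,
                  const NumericVector& box) {
  double Lx = box[0], Ly = box[1], Lz = box[2];
  double best = R_PosInf;
  int bi = 0, bj = 0;
  for (int i = 0; i < A.nrow(); ++i) {
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = mi(A(i,0) - B(j,0), Lx);
      double dy = mi(A(i,1) - B(j,1), Ly);
      double dz = mi(A(i,2) - B(j,2), Lz);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < best) { best = r2; bi = i; bj = j; }
    }
  }
  return List::create(_["dist"] = std::sqrt(best),
                      _["i"] = bi + 1, _["j"] = bj + 1);
}

// Per-residue minimum bead-bead distance between fibril and nanoparticle,
// reported only for residues with at least one pair within `cutoff`
// (others stay +Inf). Cell-list accelerated when the periodic box allows at
// least a 4x4x4 grid at the cutoff; falls back to an exact double loop
// otherwise. Both branches wrap coordinates into [0, L) first and then use
// the identical minimum-image arithmetic, so forcing one branch or the
// other (`method` 1 = brute, 2 = cells, 0 = automatic) gives bitwise
// identical results.
// [[Rcpp::export]]
NumericVector cpp_residue_min_dists(const NumericMatrix& fib,
                                    const IntegerVector& resid,
                                    int n_res,
                                    const NumericMatrix& np,
                                    const NumericVector& box,
                                    double cutoff,
                                    int method = 0) {
  NumericVector out(n_res, R_PosInf);
  const int m = np.nrow(), nf = fib.nrow();
  if (m == 0 || nf == 0) return out;
  double Lx = box[0], Ly = box[1], Lz = box[2];
  bool pbc = (Lx > 0 && Ly > 0 && Lz > 0);
  int nx = pbc ? (int)std::floor(Lx / cutoff) : 0;
  int ny = pbc ? (int)std::floor(Ly / cutoff) : 0;
  int nz = pbc ? (int)std::floor(Lz / cutoff) : 0;
  const double c2 = cutoff * cutoff;
  bool cells_ok = pbc && nx >= 4 && ny >= 4 && nz >= 4;
  if (method == 2 && !cells_ok)
    stop("cell list requires a periodic box of at least 4 cutoffs per side");
  bool use_cells = (method == 2) || (method == 0 && cells_ok);

  // wrapped coordinates shared by both branches (identity when not periodic)
  std::vector<double> wx(m), wy(m), wz(m);
  for (int j = 0; j < m; ++j) {
    wx[j] = pbc ? wrap0(np(j,0), Lx) : np(j,0);
    wy[j] = pbc ? wrap0(np(j,1), Ly) : np(j,1);
    wz[j] = pbc ? wrap0(np(j,2), Lz) : np(j,2);
  }

  if (!use_cells) {
    for (int i = 0; i < nf; ++i) {
      int r = resid[i] - 1;
      double x = pbc ? wrap0(fib(i,0), Lx) : fib(i,0);
      double y = pbc ? wrap0(fib(i,1), Ly) : fib(i,1);
      double z = pbc ? wrap0(fib(i,2), Lz) : fib(i,2);
      for (int j = 0; j < m; ++j) {
        double dx = mi(x - wx[j], Lx);
        double dy = mi(y - wy[j], Ly);
        double dz = mi(z - wz[j], Lz);
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 <= c2) {
          double d = std::sqrt(d2);
          if (d < out[r]) out[r] = d;
        }
      }
    }
    return out;
  }

  // bin NP beads on a periodic grid
  const int ncell = nx * ny * nz;
  std::vector<int> head(ncell, -1), nxt(m, -1);
  for (int j = 0; j < m; ++j) {
    int cxi = std::min(nx - 1, (int)(wx[j] / Lx * nx));
    int cyi = std::min(ny - 1, (int)(wy[j] / Ly * ny));
    int czi = std::min(nz - 1, (int)(wz[j] / Lz * nz));
    int c = (czi * ny + cyi) * nx + cxi;
    nxt[j] = head[c]; head[c] = j;
  }
  for (int i = 0; i < nf; ++i) {
    int r = resid[i] - 1;
    double x = wrap0(fib(i,0), Lx);
    double y = wrap0(fib(i,1), Ly);
    double z = wrap0(fib(i,2), Lz);
    int cxi = std::min(nx - 1, (int)(x / Lx * nx));
    int cyi = std::min(ny - 1, (int)(y / Ly * ny));
    int czi = std::min(nz - 1, (int)(z / Lz * nz));
    for (int dzc = -1; dzc <= 1; ++dzc) {
      int zc = (czi + dzc + nz) % nz;
      for (int dyc = -1; dyc <= 1; ++dyc) {
        int yc = (cyi + dyc + ny) % ny;
        for (int dxc = -1; dxc <= 1; ++dxc) {
          int xc = (cxi + dxc + nx) % nx;
          for (int j = head[(zc * ny + yc) * nx + xc]; j != -1; j = nxt[j]) {
            double dx = mi(x - wx[j], Lx);
            double dy = mi(y - wy[j], Ly);
            double dz = mi(z - wz[j], Lz);
            double d2 = dx*dx + dy*dy + dz*dz;
            if (d2 <= c2) {
              double d = std::sqrt(d2);
              if (d < out[r]) out[r] = d;
            }
          }
        }
      }
    }
  }
  return out;
}

// Net force and torque (about `center`) on a rigid nanoparticle in the field
// of a fixed fibril: per-fibril-bead LJ well depths `fib_eps` plus screened
// Coulomb between charged beads, minimum-image in the periodic box.
// [[Rcpp::export]]
List cpp_rigid_forces(const NumericMatrix& np, const NumericVector& np_q,
                      const NumericMatrix& fib, const NumericVector& fib_q,
                      const NumericVector& fib_eps,
                      double sigma, double rcut,
                      double ke, double lambda,
                      const NumericVector& box,
                      const NumericVector& center) {
  const int m = np.nrow(), nf = fib.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  const double rc2 = rcut * rcut;
  const double relec = 5.0 * lambda;
  bool elec = (ke != 0.0);
  double rmax = rcut;
  if (elec && relec > rmax) rmax = relec;
  const double rmax2 = rmax * rmax;
  double Fx = 0, Fy = 0, Fz = 0, Tx = 0, Ty = 0, Tz = 0;
  double mind2 = R_PosInf;

  for (int i = 0; i < m; ++i) {
    double ax = np(i,0) - center[0];
    double ay = np(i,1) - center[1];
    double az = np(i,2) - center[2];
    for (int j = 0; j < nf; ++j) {
      double dx = mi(np(i,0) - fib(j,0), Lx);
      double dy = mi(np(i,1) - fib(j,1), Ly);
      double dz = mi(np(i,2) - fib(j,2), Lz);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < mind2) mind2 = r2;
      if (r2 > rmax2 || r2 == 0.0) continue;
      double r = std::sqrt(r2);
      double fmag = 0.0;
      double e = fib_eps[j];
      if (e > 0 && r2 <= rc2) {
        double sr2 = sigma * sigma / r2;
        double sr6 = sr2 * sr2 * sr2;
        fmag += 24.0 * e * (2.0 * sr6 * sr6 - sr6) / r;
      }
      if (elec && np_q[i] != 0.0 && fib_q[j] != 0.0 && r <= relec) {
        double v = ke * np_q[i] * fib_q[j] * std::exp(-r / lambda) / r;
        fmag += v * (1.0 / r + 1.0 / lambda);
      }
      if (fmag != 0.0) {
        double fx = fmag * dx / r, fy = fmag * dy / r, fz = fmag * dz / r;
        Fx += fx; Fy += fy; Fz += fz;
        Tx += ay * fz - az * fy;
        Ty += az * fx - ax * fz;
        Tz += ax * fy - ay * fx;
      }
    }
  }
  return List::create(_["F"] = NumericVector::create(Fx, Fy, Fz),
                      _["tau"] = NumericVector::create(Tx, Ty, Tz),
                      _["min_dist"] = std::sqrt(mind2));
}

// Single-linkage cluster labels at a distance cutoff (union-find).
// [[Rcpp::export]]
IntegerVector cpp_cluster_labels(const NumericMatrix& pos, double cutoff) {
  const int n = pos.nrow();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i,0) - pos(j,0);
      double dy = pos(i,1) - pos(j,1);
      double dz = pos(i,2) - pos(j,2);
      if (dx*dx + dy*dy + dz*dz <= c2) {
        int ri = find(i), rj = find(j);
        if (ri != rj) parent[ri] = rj;
      }
    }
  }
  IntegerVector lab(n);
  std::vector<int> remap(n, -1);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (remap[r] == -1) remap[r] = k++;
    lab[i] = remap[r] + 1;
  }
  return lab;
}
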