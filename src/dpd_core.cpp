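// Core DPD engine: pair forces (conservative / dissipative / random),
// harmonic bonds, harmonic angles, cell-list neighbour search under full
// periodic boundaries, the Groot-Warren modified velocity-Verlet step, and
// the Irving-Kirkwood pressure tensor with straight-line slab apportionment.
// All quantities are in reduced DPD units (m = rc = kBT = 1 by default).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic counter-free RNG: xoshiro256++ seeded via splitmix64.
// One stream per run; draw order is fixed by the (deterministic) pair
// traversal order, so a seed reproduces a trajectory bitwise.
// ---------------------------------------------------------------------------
namespace {

struct Xoshiro {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;

  static uint64_t splitmix64(uint64_t& x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    has_spare = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1); never exactly 0 (needed for Box-Muller log)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // Marsaglia polar method (no trig calls)
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double g = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * g;
    has_spare = true;
    return u * g;
  }
};

inline double min_image(double d, double L, double hL) {
  if (d > hL) d -= L; else if (d < -hL) d += L;
  return d;
}

inline double wrap0L(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;  // guard against rounding at the upper edge
  if (x < 0) x = 0.0;
  return x;
}

// system snapshot in structure-of-arrays form
struct Sys {
  int n;
  std::vector<double> x, y, z;      // wrapped positions
  std::vector<double> vx, vy, vz;
  std::vector<double> fx, fy, fz;
  std::vector<int> sp;              // 0-based species codes
  double Lx, Ly, Lz;
};

struct FF {
  std::vector<double> a;  // ns x ns row-major repulsion matrix
  int ns;
  double rc, gamma, sigma;
  // bonded terms
  std::vector<int> b_i, b_j;          // bonds
  std::vector<int> t_i, t_j, t_k;     // angles, j = centre
  double ks, rs, ktheta, theta0;
};

struct EnergyAcc {
  double pair = 0.0, bond = 0.0, angle = 0.0;
  long n_overlap = 0;
};

// half-shell neighbour offsets (13) for the cell traversal
static const int HALF_OFF[13][3] = {
  {1,0,0}, {-1,1,0}, {0,1,0}, {1,1,0},
  {-1,-1,1}, {0,-1,1}, {1,-1,1},
  {-1,0,1}, {0,0,1}, {1,0,1},
  {-1,1,1}, {0,1,1}, {1,1,1}
};

// Cell list with counting sort, rebuilt every step. The neighbour-cell table
// (13 half-shell neighbours per cell plus their periodic image shifts) only
// depends on the box geometry and is built once and reused.
struct CellList {
  int ncx = -1, ncy = -1, ncz = -1, ncell = 0;
  std::vector<int> count, offset, beads, cell_of;
  std::vector<int> nbr;                       // ncell x 13 neighbour cells
  std::vector<double> shx, shy, shz;          // matching periodic shifts
  // cell-sorted working copies (cache-contiguous within a cell)
  std::vector<double> xs, ys, zs, vxs, vys, vzs, fxs, fys, fzs;
  std::vector<int> sps;

  void build_geometry(const Sys& s) {
    nbr.resize((size_t)ncell * 13);
    shx.resize((size_t)ncell * 13);
    shy.resize((size_t)ncell * 13);
    shz.resize((size_t)ncell * 13);
    for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          const size_t base = (size_t)((cz * ncy + cy) * ncx + cx) * 13;
          for (int o = 0; o < 13; ++o) {
            int nx = cx + HALF_OFF[o][0], ny = cy + HALF_OFF[o][1],
                nz = cz + HALF_OFF[o][2];
            double sx = 0, sy = 0, sz = 0;
            if (nx < 0) { nx += ncx; sx = -s.Lx; }
            else if (nx >= ncx) { nx -= ncx; sx = s.Lx; }
            if (ny < 0) { ny += ncy; sy = -s.Ly; }
            else if (ny >= ncy) { ny -= ncy; sy = s.Ly; }
            if (nz < 0) { nz += ncz; sz = -s.Lz; }
            else if (nz >= ncz) { nz -= ncz; sz = s.Lz; }
            nbr[base + o] = (nz * ncy + ny) * ncx + nx;
            // shift applies to the *neighbour* coordinates: the image of a
            // bead in neighbour cell nearest to cell c is r_j + shift
            shx[base + o] = sx; shy[base + o] = sy; shz[base + o] = sz;
          }
        }
  }

  bool build(const Sys& s, double rc) {
    const int wx = std::max(1, (int)std::floor(s.Lx / rc));
    const int wy = std::max(1, (int)std::floor(s.Ly / rc));
    const int wz = std::max(1, (int)std::floor(s.Lz / rc));
    if (wx < 3 || wy < 3 || wz < 3) return false;  // fall back to all-pairs
    if (wx != ncx || wy != ncy || wz != ncz) {
      ncx = wx; ncy = wy; ncz = wz;
      ncell = ncx * ncy * ncz;
      build_geometry(s);
    }
    count.assign(ncell, 0);
    offset.assign(ncell + 1, 0);
    beads.resize(s.n);
    cell_of.resize(s.n);
    const double ix = ncx / s.Lx, iy = ncy / s.Ly, iz = ncz / s.Lz;
    for (int i = 0; i < s.n; ++i) {
      int cx = (int)(s.x[i] * ix); if (cx >= ncx) cx = ncx - 1;
      int cy = (int)(s.y[i] * iy); if (cy >= ncy) cy = ncy - 1;
      int cz = (int)(s.z[i] * iz); if (cz >= ncz) cz = ncz - 1;
      int c = (cz * ncy + cy) * ncx + cx;
      cell_of[i] = c;
      ++count[c];
    }
    for (int c = 0; c < ncell; ++c) offset[c + 1] = offset[c] + count[c];
    std::vector<int> cur(offset.begin(), offset.end() - 1);
    for (int i = 0; i < s.n; ++i) beads[cur[cell_of[i]]++] = i;
    return true;
  }

  void gather(const Sys& s) {
    const size_t n = s.n;
    xs.resize(n); ys.resize(n); zs.resize(n);
    vxs.resize(n); vys.resize(n); vzs.resize(n);
    fxs.assign(n, 0.0); fys.assign(n, 0.0); fzs.assign(n, 0.0);
    sps.resize(n);
    for (size_t k = 0; k < n; ++k) {
      const int i = beads[k];
      xs[k] = s.x[i]; ys[k] = s.y[i]; zs[k] = s.z[i];
      vxs[k] = s.vx[i]; vys[k] = s.vy[i]; vzs[k] = s.vz[i];
      sps[k] = s.sp[i];
    }
  }

  void scatter_forces(Sys& s) const {
    for (size_t k = 0; k < beads.size(); ++k) {
      const int i = beads[k];
      s.fx[i] = fxs[k]; s.fy[i] = fys[k]; s.fz[i] = fzs[k];
    }
  }
};

struct ForceOpts {
  bool cons = true, diss = true, rand = true;
  double inv_sqrt_dt = 10.0;  // for the random force
};

// Pair kernel: accumulates forces on i and j and the pair energy.
// vel pointer selects which velocity array the dissipative force sees.
inline void pair_kernel(Sys& s, const FF& ff, const ForceOpts& op,
                        Xoshiro& rng, EnergyAcc& en,
                        int i, int j, double dx, double dy, double dz,
                        double r2) {
  const double rc2 = ff.rc * ff.rc;
  if (r2 >= rc2) return;
  double r = std::sqrt(r2);
  double ex, ey, ez;
  if (r >= 1e-12) {
    const double invr = 1.0 / r;
    ex = dx * invr; ey = dy * invr; ez = dz * invr;
  } else {
    // soft potential: overlaps are legal; direction undefined, use a
    // deterministic pseudo-random unit vector and the r -> 0 magnitude
    ++en.n_overlap;
    double gx = rng.norm(), gy = rng.norm(), gz = rng.norm();
    double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
    if (gn < 1e-12) { gx = 1; gy = 0; gz = 0; gn = 1; }
    ex = gx / gn; ey = gy / gn; ez = gz / gn;
    r = 0.0;
  }
  const double w = 1.0 - r / ff.rc;
  double f = 0.0;
  if (op.cons) {
    const double aij = ff.a[s.sp[i] * ff.ns + s.sp[j]];
    f += aij * w;
    en.pair += 0.5 * aij * ff.rc * w * w;
  }
  if (op.diss) {
    const double vdot = (s.vx[i] - s.vx[j]) * ex + (s.vy[i] - s.vy[j]) * ey +
                        (s.vz[i] - s.vz[j]) * ez;
    f -= ff.gamma * w * w * vdot;
  }
  if (op.rand) {
    f += ff.sigma * w * rng.norm() * op.inv_sqrt_dt;
  }
  s.fx[i] += f * ex; s.fy[i] += f * ey; s.fz[i] += f * ez;
  s.fx[j] -= f * ex; s.fy[j] -= f * ey; s.fz[j] -= f * ez;
}

void bonded_forces(Sys& s, const FF& ff, EnergyAcc& en) {
  const double hLx = s.Lx / 2, hLy = s.Ly / 2, hLz = s.Lz / 2;
  // harmonic bonds: F_i = ks (1 - r/rs) rhat_ij, U = (ks rs / 2)(1 - r/rs)^2
  for (size_t b = 0; b < ff.b_i.size(); ++b) {
    const int i = ff.b_i[b], j = ff.b_j[b];
    double dx = min_image(s.x[i] - s.x[j], s.Lx, hLx);
    double dy = min_image(s.y[i] - s.y[j], s.Ly, hLy);
    double dz = min_image(s.z[i] - s.z[j], s.Lz, hLz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) { ++en.n_overlap; continue; }  // capped: no defined direction
    const double q = 1.0 - r / ff.rs;
    const double f = ff.ks * q / r;  // scalar / r so we can use d directly
    s.fx[i] += f * dx; s.fy[i] += f * dy; s.fz[i] += f * dz;
    s.fx[j] -= f * dx; s.fy[j] -= f * dy; s.fz[j] -= f * dz;
    en.bond += 0.5 * ff.ks * ff.rs * q * q;
  }
  // harmonic angles: U = ktheta (theta - theta0)^2 on consecutive triples
  for (size_t t = 0; t < ff.t_i.size(); ++t) {
    const int i = ff.t_i[t], j = ff.t_j[t], k = ff.t_k[t];
    double ux = min_image(s.x[i] - s.x[j], s.Lx, hLx);
    double uy = min_image(s.y[i] - s.y[j], s.Ly, hLy);
    double uz = min_image(s.z[i] - s.z[j], s.Lz, hLz);
    double wx = min_image(s.x[k] - s.x[j], s.Lx, hLx);
    double wy = min_image(s.y[k] - s.y[j], s.Ly, hLy);
    double wz = min_image(s.z[k] - s.z[j], s.Lz, hLz);
    const double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    const double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
    if (nu < 1e-12 || nw < 1e-12) continue;
    double c = (ux * wx + uy * wy + uz * wz) / (nu * nw);
    c = std::max(-1.0, std::min(1.0, c));
    const double th = std::acos(c);
    const double dth = th - ff.theta0;
    en.angle += ff.ktheta * dth * dth;
    const double sth = std::sqrt(std::max(0.0, 1.0 - c * c));
    if (sth < 1e-8) continue;  // grad(cos theta) -> 0 here for theta0 = pi
    // F_a = (2 ktheta (th - th0) / sin th) * d(cos th)/d r_a
    const double coef = 2.0 * ff.ktheta * dth / sth;
    const double gi_x = (wx / nw - c * ux / nu) / nu;
    const double gi_y = (wy / nw - c * uy / nu) / nu;
    const double gi_z = (wz / nw - c * uz / nu) / nu;
    const double gk_x = (ux / nu - c * wx / nw) / nw;
    const double gk_y = (uy / nu - c * wy / nw) / nw;
    const double gk_z = (uz / nu - c * wz / nw) / nw;
    s.fx[i] += coef * gi_x; s.fy[i] += coef * gi_y; s.fz[i] += coef * gi_z;
    s.fx[k] += coef * gk_x; s.fy[k] += coef * gk_y; s.fz[k] += coef * gk_z;
    s.fx[j] -= coef * (gi_x + gk_x);
    s.fy[j] -= coef * (gi_y + gk_y);
    s.fz[j] -= coef * (gi_z + gk_z);
  }
}

// Full force evaluation (non-bonded + bonded). Returns energies.
EnergyAcc compute_forces(Sys& s, const FF& ff, const ForceOpts& op,
                         Xoshiro& rng, CellList& cl, bool use_cell) {
  std::fill(s.fx.begin(), s.fx.end(), 0.0);
  std::fill(s.fy.begin(), s.fy.end(), 0.0);
  std::fill(s.fz.begin(), s.fz.end(), 0.0);
  EnergyAcc en;
  const double hLx = s.Lx / 2, hLy = s.Ly / 2, hLz = s.Lz / 2;
  const double rc2 = ff.rc * ff.rc;

  bool cell_ok = use_cell && cl.build(s, ff.rc);
  if (cell_ok) {
    // cache-contiguous pass over cell-sorted copies of the coordinates;
    // forces are accumulated in sorted order and scattered back after
    cl.gather(s);
    const double inv_rc = 1.0 / ff.rc;
    const int ns = ff.ns;
    // inline pair kernel on the sorted arrays; accumulates the force on
    // bead a in registers (fax/fay/faz) and on b in the sorted arrays
    for (int c = 0; c < cl.ncell; ++c) {
      const int b0 = cl.offset[c], b1 = cl.offset[c + 1];
      const size_t base = (size_t)c * 13;
      for (int a = b0; a < b1; ++a) {
        const double xi = cl.xs[a], yi = cl.ys[a], zi = cl.zs[a];
        const double vxi = cl.vxs[a], vyi = cl.vys[a], vzi = cl.vzs[a];
        const double* arow = ff.a.data() + (size_t)cl.sps[a] * ns;
        double fax = 0.0, fay = 0.0, faz = 0.0;

        auto do_pair = [&](int b, double dx, double dy, double dz,
                           double r2) {
          double r = std::sqrt(r2);
          double ex, ey, ez;
          if (r >= 1e-12) {
            const double invr = 1.0 / r;
            ex = dx * invr; ey = dy * invr; ez = dz * invr;
          } else {
            ++en.n_overlap;
            double gx = rng.norm(), gy = rng.norm(), gz = rng.norm();
            double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
            if (gn < 1e-12) { gx = 1; gy = 0; gz = 0; gn = 1; }
            ex = gx / gn; ey = gy / gn; ez = gz / gn;
            r = 0.0;
          }
          const double w = 1.0 - r * inv_rc;
          double f = 0.0;
          if (op.cons) {
            const double aij = arow[cl.sps[b]];
            f += aij * w;
            en.pair += 0.5 * aij * ff.rc * w * w;
          }
          if (op.diss) {
            const double vdot = (vxi - cl.vxs[b]) * ex +
                                (vyi - cl.vys[b]) * ey +
                                (vzi - cl.vzs[b]) * ez;
            f -= ff.gamma * w * w * vdot;
          }
          if (op.rand) f += ff.sigma * w * rng.norm() * op.inv_sqrt_dt;
          fax += f * ex; fay += f * ey; faz += f * ez;
          cl.fxs[b] -= f * ex; cl.fys[b] -= f * ey; cl.fzs[b] -= f * ez;
        };

        // pairs within the cell (no image shift: cell edge <= L/3)
        for (int b = a + 1; b < b1; ++b) {
          const double dx = xi - cl.xs[b], dy = yi - cl.ys[b],
                       dz = zi - cl.zs[b];
          const double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < rc2) do_pair(b, dx, dy, dz, r2);
        }
        // half-shell neighbour cells with precomputed image shifts
        for (int o = 0; o < 13; ++o) {
          const int c2 = cl.nbr[base + o];
          const int d0 = cl.offset[c2], d1 = cl.offset[c2 + 1];
          if (d0 == d1) continue;
          const double xs_ = xi - cl.shx[base + o];
          const double ys_ = yi - cl.shy[base + o];
          const double zs_ = zi - cl.shz[base + o];
          for (int b = d0; b < d1; ++b) {
            const double dx = xs_ - cl.xs[b], dy = ys_ - cl.ys[b],
                         dz = zs_ - cl.zs[b];
            const double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < rc2) do_pair(b, dx, dy, dz, r2);
          }
        }
        cl.fxs[a] += fax; cl.fys[a] += fay; cl.fzs[a] += faz;
      }
    }
    cl.scatter_forces(s);
  } else {
    for (int i = 0; i < s.n; ++i)
      for (int j = i + 1; j < s.n; ++j) {
        double dx = min_image(s.x[i] - s.x[j], s.Lx, hLx);
        double dy = min_image(s.y[i] - s.y[j], s.Ly, hLy);
        double dz = min_image(s.z[i] - s.z[j], s.Lz, hLz);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2) pair_kernel(s, ff, op, rng, en, i, j, dx, dy, dz, r2);
      }
  }
  bonded_forces(s, ff, en);
  return en;
}

Sys sys_from_R(const NumericMatrix& pos, const NumericMatrix& vel,
               const IntegerVector& species, const NumericVector& box) {
  Sys s;
  s.n = pos.nrow();
  s.Lx = box[0]; s.Ly = box[1]; s.Lz = box[2];
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  s.vx.resize(s.n); s.vy.resize(s.n); s.vz.resize(s.n);
  s.fx.assign(s.n, 0.0); s.fy.assign(s.n, 0.0); s.fz.assign(s.n, 0.0);
  s.sp.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = wrap0L(pos(i, 0), s.Lx);
    s.y[i] = wrap0L(pos(i, 1), s.Ly);
    s.z[i] = wrap0L(pos(i, 2), s.Lz);
    s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
    s.sp[i] = species[i] - 1;
  }
  return s;
}

FF ff_from_R(const NumericMatrix& amat, double rc, double gamma, double sigma,
             const IntegerMatrix& bonds, double ks, double rs,
             const IntegerMatrix& angles, double ktheta, double theta0) {
  FF ff;
  ff.ns = amat.nrow();
  ff.a.resize(ff.ns * ff.ns);
  for (int i = 0; i < ff.ns; ++i)
    for (int j = 0; j < ff.ns; ++j) ff.a[i * ff.ns + j] = amat(i, j);
  ff.rc = rc; ff.gamma = gamma; ff.sigma = sigma;
  ff.ks = ks; ff.rs = rs; ff.ktheta = ktheta; ff.theta0 = theta0;
  for (int b = 0; b < bonds.nrow(); ++b) {
    ff.b_i.push_back(bonds(b, 0) - 1);
    ff.b_j.push_back(bonds(b, 1) - 1);
  }
  for (int t = 0; t < angles.nrow(); ++t) {
    ff.t_i.push_back(angles(t, 0) - 1);
    ff.t_j.push_back(angles(t, 1) - 1);
    ff.t_k.push_back(angles(t, 2) - 1);
  }
  return ff;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported: single force evaluation (used by tests and the R-level wrappers)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                NumericVector box, NumericMatrix amat, double rc, double gamma,
                double sigma, double dt, IntegerMatrix bonds, double ks,
                double rs, IntegerMatrix angles, double ktheta, double theta0,
                bool use_cell, bool incl_cons, bool incl_diss, bool incl_rand,
                double seed) {
  Sys s = sys_from_R(pos, vel, species, box);
  FF ff = ff_from_R(amat, rc, gamma, sigma, bonds, ks, rs, angles, ktheta, theta0);
  Xoshiro rng; rng.seed((uint64_t)seed);
  ForceOpts op; op.cons = incl_cons; op.diss = incl_diss; op.rand = incl_rand;
  op.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  CellList cl;
  EnergyAcc en = compute_forces(s, ff, op, rng, cl, use_cell);
  NumericMatrix forces(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    forces(i, 0) = s.fx[i]; forces(i, 1) = s.fy[i]; forces(i, 2) = s.fz[i];
  }
  return List::create(_["forces"] = forces, _["pair_energy"] = en.pair,
                      _["bond_energy"] = en.bond, _["angle_energy"] = en.angle,
                      _["n_overlap"] = (double)en.n_overlap);
}

// ---------------------------------------------------------------------------
// Exported: run n_steps of the modified velocity-Verlet scheme
//   r(t+dt)  = r + dt v + dt^2/2 f
//   vtil     = v + lambda dt f
//   f(t+dt)  = f(r(t+dt), vtil)       [fresh random draws]
//   v(t+dt)  = v + dt/2 (f(t) + f(t+dt))
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
             NumericVector box, NumericMatrix amat, double rc, double gamma,
             double sigma, IntegerMatrix bonds, double ks, double rs,
             IntegerMatrix angles, double ktheta, double theta0,
             int n_steps, double dt, double lambda, double t0,
             int energy_every, int frame_every, double seed,
             bool save_velocities) {
  Sys s = sys_from_R(pos, vel, species, box);
  FF ff = ff_from_R(amat, rc, gamma, sigma, bonds, ks, rs, angles, ktheta, theta0);
  Xoshiro rng; rng.seed((uint64_t)seed);
  ForceOpts op; op.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  CellList cl;
  const int n = s.n;

  std::vector<double> fx0(n), fy0(n), fz0(n);
  EnergyAcc en = compute_forces(s, ff, op, rng, cl, true);

  auto kinetic = [&]() {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += s.vx[i] * s.vx[i] + s.vy[i] * s.vy[i] + s.vz[i] * s.vz[i];
    return 0.5 * ke;
  };
  auto com_temperature = [&]() {
    double mx = 0, my = 0, mz = 0;
    for (int i = 0; i < n; ++i) { mx += s.vx[i]; my += s.vy[i]; mz += s.vz[i]; }
    mx /= n; my /= n; mz /= n;
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      double ax = s.vx[i] - mx, ay = s.vy[i] - my, az = s.vz[i] - mz;
      ke += ax * ax + ay * ay + az * az;
    }
    return n > 1 ? ke / (3.0 * (n - 1)) : 0.0;
  };

  const int n_erec = (energy_every > 0) ? n_steps / energy_every + 1 : 1;
  NumericMatrix elog(n_erec, 8);
  long overlap_total = en.n_overlap;
  int erow = 0;
  auto record_energy = [&](int step) {
    if (erow >= n_erec) return;
    const double ke = kinetic();
    elog(erow, 0) = step;
    elog(erow, 1) = t0 + step * dt;
    elog(erow, 2) = ke / n;
    elog(erow, 3) = en.pair / n;
    elog(erow, 4) = en.bond / n;
    elog(erow, 5) = en.angle / n;
    elog(erow, 6) = (ke + en.pair + en.bond + en.angle) / n;
    elog(erow, 7) = com_temperature();
    ++erow;
  };
  record_energy(0);

  List frames;
  auto record_frame = [&](int step) {
    NumericMatrix fpos(n, 3);
    for (int i = 0; i < n; ++i) {
      fpos(i, 0) = s.x[i]; fpos(i, 1) = s.y[i]; fpos(i, 2) = s.z[i];
    }
    List fr = List::create(_["positions"] = fpos,
                           _["time"] = t0 + step * dt, _["step"] = step);
    if (save_velocities) {
      NumericMatrix fvel(n, 3);
      for (int i = 0; i < n; ++i) {
        fvel(i, 0) = s.vx[i]; fvel(i, 1) = s.vy[i]; fvel(i, 2) = s.vz[i];
      }
      fr["velocities"] = fvel;
    }
    frames.push_back(fr);
  };

  for (int step = 1; step <= n_steps; ++step) {
    // position update + wrap; stash f(t)
    for (int i = 0; i < n; ++i) {
      fx0[i] = s.fx[i]; fy0[i] = s.fy[i]; fz0[i] = s.fz[i];
      s.x[i] = wrap0L(s.x[i] + dt * s.vx[i] + 0.5 * dt * dt * s.fx[i], s.Lx);
      s.y[i] = wrap0L(s.y[i] + dt * s.vy[i] + 0.5 * dt * dt * s.fy[i], s.Ly);
      s.z[i] = wrap0L(s.z[i] + dt * s.vz[i] + 0.5 * dt * dt * s.fz[i], s.Lz);
      // predicted velocity (the dissipative force sees this)
      s.vx[i] += lambda * dt * s.fx[i];
      s.vy[i] += lambda * dt * s.fy[i];
      s.vz[i] += lambda * dt * s.fz[i];
    }
    en = compute_forces(s, ff, op, rng, cl, true);
    overlap_total += en.n_overlap;
    // velocity correction: v(t+dt) = v(t) + dt/2 (f0 + f1)
    for (int i = 0; i < n; ++i) {
      s.vx[i] += -lambda * dt * fx0[i] + 0.5 * dt * (fx0[i] + s.fx[i]);
      s.vy[i] += -lambda * dt * fy0[i] + 0.5 * dt * (fy0[i] + s.fy[i]);
      s.vz[i] += -lambda * dt * fz0[i] + 0.5 * dt * (fz0[i] + s.fz[i]);
    }
    if (energy_every > 0 && step % energy_every == 0) {
      if (!std::isfinite(s.x[0]) || !std::isfinite(s.vx[0]))
        stop("non-finite coordinates at step %d: simulation diverged", step);
      record_energy(step);
    }
    if (frame_every > 0 && step % frame_every == 0) record_frame(step);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out_pos(n, 3), out_vel(n, 3), out_f(n, 3);
  for (int i = 0; i < n; ++i) {
    out_pos(i, 0) = s.x[i]; out_pos(i, 1) = s.y[i]; out_pos(i, 2) = s.z[i];
    out_vel(i, 0) = s.vx[i]; out_vel(i, 1) = s.vy[i]; out_vel(i, 2) = s.vz[i];
    out_f(i, 0) = s.fx[i]; out_f(i, 1) = s.fy[i]; out_f(i, 2) = s.fz[i];
  }
  colnames(elog) = CharacterVector::create("step", "time", "kinetic", "pair",
                                           "bond", "angle", "total",
                                           "temperature");
  return List::create(_["positions"] = out_pos, _["velocities"] = out_vel,
                      _["forces"] = out_f, _["energy_log"] = elog,
                      _["frames"] = frames, _["time"] = t0 + n_steps * dt,
                      _["n_overlap"] = (double)overlap_total);
}

// ---------------------------------------------------------------------------
// Irving-Kirkwood pressure tensor.
// p_aa = (1/V) [ sum_i m v_ia v_ia + sum_{i<j} F_ij,a r_ij,a ]
// Slab resolution along z: each pair term is spread over the slabs crossed by
// the straight minimum-image segment from j to i, in proportion to the length
// of the segment inside each slab; optionally restricted to a y-window
// (path-fraction inside the window). The kinetic term is binned at the bead.
// ---------------------------------------------------------------------------
namespace {
// t-intervals (subset of [0,1]) for which y(t) = y0 + t*dy lies in
// [w0, w1) modulo Ly; returns up to 3 disjoint intervals
int y_window_intervals(double y0, double dy, double Ly, double w0, double w1,
                       double tlo[3], double thi[3]) {
  int m = 0;
  for (int k = -1; k <= 1; ++k) {
    const double a = w0 + k * Ly, b = w1 + k * Ly;
    double t1, t2;
    if (std::fabs(dy) < 1e-14) {
      if (y0 >= a && y0 < b) { t1 = 0.0; t2 = 1.0; } else continue;
    } else {
      t1 = (a - y0) / dy; t2 = (b - y0) / dy;
      if (t1 > t2) std::swap(t1, t2);
      t1 = std::max(0.0, t1); t2 = std::min(1.0, t2);
      if (t2 <= t1) continue;
    }
    tlo[m] = t1; thi[m] = t2; ++m;
  }
  return m;
}
}  // namespace

// [[Rcpp::export]]
List cpp_pressure(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                  NumericVector box, NumericMatrix amat, double rc,
                  IntegerMatrix bonds, double ks, double rs,
                  IntegerMatrix angles, double ktheta, double theta0,
                  int n_slabs, double ywin0, double ywin1,
                  bool incl_diss, double gamma,
                  bool incl_rand, double sigma, double dt, double seed) {
  Sys s = sys_from_R(pos, vel, species, box);
  FF ff = ff_from_R(amat, rc, gamma, sigma, bonds, ks, rs, angles, ktheta, theta0);
  Xoshiro rng; rng.seed((uint64_t)seed);
  const double hLx = s.Lx / 2, hLy = s.Ly / 2, hLz = s.Lz / 2;
  const double rc2 = rc * rc;
  const bool use_ywin = (ywin1 > ywin0);
  const double h = s.Lz / n_slabs;
  const double inv_sqrt_dt = dt > 0 ? 1.0 / std::sqrt(dt) : 0.0;

  std::vector<double> sxx(n_slabs, 0.0), syy(n_slabs, 0.0), szz(n_slabs, 0.0);
  double wxx = 0, wyy = 0, wzz = 0;  // whole box, direct accumulation

  // spread one pair contribution (cxx, cyy, czz) along the segment
  // from (yj, zj) with displacement (dy, dz)
  auto add_pair_contrib = [&](double cxx, double cyy, double czz,
                              double yj, double zj, double dy, double dz) {
    wxx += cxx; wyy += cyy; wzz += czz;
    double tlo[3], thi[3];
    int nyint = 1; tlo[0] = 0.0; thi[0] = 1.0;
    if (use_ywin) nyint = y_window_intervals(yj, dy, s.Ly, ywin0, ywin1, tlo, thi);
    if (nyint == 0) return;
    // z breakpoints at slab boundaries crossed by z(t) = zj + t dz
    const double z1 = zj + dz;
    double tprev = 0.0;
    auto slab_of = [&](double zz) {
      int b = (int)std::floor(wrap0L(zz, s.Lz) / h);
      if (b >= n_slabs) b = n_slabs - 1;
      if (b < 0) b = 0;
      return b;
    };
    auto deposit = [&](double ta, double tb) {
      if (tb <= ta) return;
      // measure of [ta, tb] inside the y intervals
      double w = 0.0;
      for (int m = 0; m < nyint; ++m)
        w += std::max(0.0, std::min(tb, thi[m]) - std::max(ta, tlo[m]));
      if (w <= 0.0) return;
      const int b = slab_of(zj + 0.5 * (ta + tb) * dz);
      sxx[b] += cxx * w; syy[b] += cyy * w; szz[b] += czz * w;
    };
    if (std::fabs(dz) < 1e-14) {
      deposit(0.0, 1.0);
      return;
    }
    const int k0 = (int)std::floor(std::min(zj, z1) / h);
    const int k1 = (int)std::floor(std::max(zj, z1) / h);
    std::vector<double> tb;
    for (int k = k0 + 1; k <= k1; ++k) {
      const double t = (k * h - zj) / dz;
      if (t > 0.0 && t < 1.0) tb.push_back(t);
    }
    std::sort(tb.begin(), tb.end());
    for (double t : tb) { deposit(tprev, t); tprev = t; }
    deposit(tprev, 1.0);
  };

  // force on i from j, separation d = r_i - r_j (minimum image)
  auto pair_virial = [&](int i, int j, double dx, double dy, double dz,
                         double fx, double fy, double fz) {
    add_pair_contrib(fx * dx, fy * dy, fz * dz, s.y[j], s.z[j], dy, dz);
  };

  // non-bonded pairs
  CellList cl;
  bool cell_ok = cl.build(s, rc);
  auto handle_pair = [&](int i, int j) {
    double dx = min_image(s.x[i] - s.x[j], s.Lx, hLx);
    double dy = min_image(s.y[i] - s.y[j], s.Ly, hLy);
    double dz = min_image(s.z[i] - s.z[j], s.Lz, hLz);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return;
    const double r = std::sqrt(r2);
    if (r < 1e-12) return;  // overlap: no direction, no virial
    const double w = 1.0 - r / rc;
    double f = ff.a[s.sp[i] * ff.ns + s.sp[j]] * w;
    if (incl_diss) {
      const double ex = dx / r, ey = dy / r, ez = dz / r;
      const double vdot = (s.vx[i] - s.vx[j]) * ex + (s.vy[i] - s.vy[j]) * ey +
                          (s.vz[i] - s.vz[j]) * ez;
      f -= gamma * w * w * vdot;
    }
    if (incl_rand) f += sigma * w * rng.norm() * inv_sqrt_dt;
    const double fr = f / r;
    pair_virial(i, j, dx, dy, dz, fr * dx, fr * dy, fr * dz);
  };
  if (cell_ok) {
    for (int cz = 0; cz < cl.ncz; ++cz)
      for (int cy = 0; cy < cl.ncy; ++cy)
        for (int cx = 0; cx < cl.ncx; ++cx) {
          const int c = (cz * cl.ncy + cy) * cl.ncx + cx;
          const int b0 = cl.offset[c], b1 = cl.offset[c + 1];
          for (int a = b0; a < b1; ++a)
            for (int b = a + 1; b < b1; ++b)
              handle_pair(cl.beads[a], cl.beads[b]);
          for (int o = 0; o < 13; ++o) {
            int nx = cx + HALF_OFF[o][0], ny = cy + HALF_OFF[o][1],
                nz = cz + HALF_OFF[o][2];
            if (nx < 0) nx += cl.ncx; else if (nx >= cl.ncx) nx -= cl.ncx;
            if (ny < 0) ny += cl.ncy; else if (ny >= cl.ncy) ny -= cl.ncy;
            if (nz < 0) nz += cl.ncz; else if (nz >= cl.ncz) nz -= cl.ncz;
            const int c2 = (nz * cl.ncy + ny) * cl.ncx + nx;
            for (int a = b0; a < b1; ++a)
              for (int b = cl.offset[c2]; b < cl.offset[c2 + 1]; ++b)
                handle_pair(cl.beads[a], cl.beads[b]);
          }
        }
  } else {
    for (int i = 0; i < s.n; ++i)
      for (int j = i + 1; j < s.n; ++j) handle_pair(i, j);
  }

  // bonds
  for (size_t b = 0; b < ff.b_i.size(); ++b) {
    const int i = ff.b_i[b], j = ff.b_j[b];
    double dx = min_image(s.x[i] - s.x[j], s.Lx, hLx);
    double dy = min_image(s.y[i] - s.y[j], s.Ly, hLy);
    double dz = min_image(s.z[i] - s.z[j], s.Lz, hLz);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    const double f = ff.ks * (1.0 - r / ff.rs) / r;
    pair_virial(i, j, dx, dy, dz, f * dx, f * dy, f * dz);
  }
  // angles: decompose the 3-body term into the i-j and k-j legs
  for (size_t t = 0; t < ff.t_i.size(); ++t) {
    const int i = ff.t_i[t], j = ff.t_j[t], k = ff.t_k[t];
    double ux = min_image(s.x[i] - s.x[j], s.Lx, hLx);
    double uy = min_image(s.y[i] - s.y[j], s.Ly, hLy);
    double uz = min_image(s.z[i] - s.z[j], s.Lz, hLz);
    double wx_ = min_image(s.x[k] - s.x[j], s.Lx, hLx);
    double wy_ = min_image(s.y[k] - s.y[j], s.Ly, hLy);
    double wz_ = min_image(s.z[k] - s.z[j], s.Lz, hLz);
    const double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    const double nw = std::sqrt(wx_ * wx_ + wy_ * wy_ + wz_ * wz_);
    if (nu < 1e-12 || nw < 1e-12) continue;
    double c = (ux * wx_ + uy * wy_ + uz * wz_) / (nu * nw);
    c = std::max(-1.0, std::min(1.0, c));
    const double th = std::acos(c);
    const double sth = std::sqrt(std::max(0.0, 1.0 - c * c));
    if (sth < 1e-8) continue;
    const double coef = 2.0 * ff.ktheta * (th - ff.theta0) / sth;
    const double fi_x = coef * (wx_ / nw - c * ux / nu) / nu;
    const double fi_y = coef * (wy_ / nw - c * uy / nu) / nu;
    const double fi_z = coef * (wz_ / nw - c * uz / nu) / nu;
    const double fk_x = coef * (ux / nu - c * wx_ / nw) / nw;
    const double fk_y = coef * (uy / nu - c * wy_ / nw) / nw;
    const double fk_z = coef * (uz / nu - c * wz_ / nw) / nw;
    pair_virial(i, j, ux, uy, uz, fi_x, fi_y, fi_z);
    pair_virial(k, j, wx_, wy_, wz_, fk_x, fk_y, fk_z);
  }

  // kinetic term, binned at the bead position
  for (int i = 0; i < s.n; ++i) {
    if (use_ywin && !(s.y[i] >= ywin0 && s.y[i] < ywin1)) {
      wxx += s.vx[i] * s.vx[i]; wyy += s.vy[i] * s.vy[i]; wzz += s.vz[i] * s.vz[i];
      continue;
    }
    int b = (int)std::floor(s.z[i] / h);
    if (b >= n_slabs) b = n_slabs - 1;
    sxx[b] += s.vx[i] * s.vx[i];
    syy[b] += s.vy[i] * s.vy[i];
    szz[b] += s.vz[i] * s.vz[i];
    wxx += s.vx[i] * s.vx[i]; wyy += s.vy[i] * s.vy[i]; wzz += s.vz[i] * s.vz[i];
  }

  const double V = s.Lx * s.Ly * s.Lz;
  const double ywidth = use_ywin ? (ywin1 - ywin0) : s.Ly;
  const double slab_vol = s.Lx * ywidth * h;
  NumericMatrix slabs(n_slabs, 3);
  NumericVector z_mid(n_slabs);
  for (int b = 0; b < n_slabs; ++b) {
    slabs(b, 0) = sxx[b] / slab_vol;
    slabs(b, 1) = syy[b] / slab_vol;
    slabs(b, 2) = szz[b] / slab_vol;
    z_mid[b] = (b + 0.5) * h;
  }
  colnames(slabs) = CharacterVector::create("pxx", "pyy", "pzz");
  NumericVector whole = NumericVector::create(
      _["pxx"] = wxx / V, _["pyy"] = wyy / V, _["pzz"] = wzz / V);
  return List::create(_["whole"] = whole, _["slabs"] = slabs,
                      _["z_mid"] = z_mid, _["slab_volume"] = slab_vol);
}
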