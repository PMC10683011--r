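// DPD force and integration kernels.
//
// Units are reduced throughout: r_c = 1 (unless overridden), bead mass = 1,
// kT = 1.  Pairwise random numbers come from a counter-based hash keyed on
// (seed, step, min(i,j), max(i,j)) so theta_ij == theta_ji exactly and a run
// is reproducible regardless of pair iteration order or neighbour-search
// strategy.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Symmetric pair noise: uniform on [-sqrt(3), sqrt(3)], zero mean, unit
// variance (Groot & Warren showed uniform noise is as good as Gaussian here).
static inline double pair_theta(uint64_t seed, uint64_t step, int i, int j) {
  const int a = i < j ? i : j;
  const int b = i < j ? j : i;
  uint64_t h = splitmix64(((uint64_t)(uint32_t)a << 32) | (uint64_t)(uint32_t)b);
  h = splitmix64(h ^ splitmix64(step + 0x51ED270B7A14C2ULL));
  h = splitmix64(h ^ splitmix64(seed + 0x63D83F5E9ABD11ULL));
  const double u = (double)(h >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
  return (2.0 * u - 1.0) * 1.7320508075688772935;
}

// [[Rcpp::export]]
double pair_noise_cpp(double seed, double step, int i, int j) {
  return pair_theta((uint64_t)seed, (uint64_t)step, i, j);
}

static inline double min_image(double d, double box) {
  // box may be small; nearbyint handles both signs
  return d - box * std::nearbyint(d / box);
}

struct Forces {
  std::vector<double> fx, fy, fz;         // total
  double *cx, *cy, *cz;                   // optional split accumulators
  double *dx_, *dy_, *dz_;
  double *rx_, *ry_, *rz_;
  double virial_c;                        // sum F^C_ij . r_ij (incl. bonds)
  explicit Forces(int n)
      : fx(n, 0.0), fy(n, 0.0), fz(n, 0.0), cx(nullptr), cy(nullptr),
        cz(nullptr), dx_(nullptr), dy_(nullptr), dz_(nullptr), rx_(nullptr),
        ry_(nullptr), rz_(nullptr), virial_c(0.0) {}
};

struct System {
  int n;
  double box, rc, gamma, sigma, dt_isqrt;
  const double *amat;                      // nspecies x nspecies, col-major
  int nspecies;
  const int *species;                      // 0-based
};

static inline void pair_kernel(const System &S, uint64_t seed, uint64_t step,
                               int i, int j, double dx, double dy, double dz,
                               double r2, const double *vx, const double *vy,
                               const double *vz, Forces &F) {
  const double rc2 = S.rc * S.rc;
  if (r2 >= rc2 || r2 <= 0.0) return;
  const double r = std::sqrt(r2);
  const double w = 1.0 - r / S.rc;         // w^R; w^D = w^2
  const double ex = dx / r, ey = dy / r, ez = dz / r;

  const double aij = S.amat[S.species[i] + S.nspecies * S.species[j]];
  const double fc = aij * w;
  const double rdotv =
      ex * (vx[i] - vx[j]) + ey * (vy[i] - vy[j]) + ez * (vz[i] - vz[j]);
  const double fd = -S.gamma * w * w * rdotv;
  const double fr = S.sigma * w * pair_theta(seed, step, i, j) * S.dt_isqrt;

  const double ft = fc + fd + fr;
  F.fx[i] += ft * ex; F.fy[i] += ft * ey; F.fz[i] += ft * ez;
  F.fx[j] -= ft * ex; F.fy[j] -= ft * ey; F.fz[j] -= ft * ez;
  F.virial_c += fc * r;                    // F^C_ij . r_ij = fc * r

  if (F.cx) {
    F.cx[i] += fc * ex; F.cy[i] += fc * ey; F.cz[i] += fc * ez;
    F.cx[j] -= fc * ex; F.cy[j] -= fc * ey; F.cz[j] -= fc * ez;
    F.dx_[i] += fd * ex; F.dy_[i] += fd * ey; F.dz_[i] += fd * ez;
    F.dx_[j] -= fd * ex; F.dy_[j] -= fd * ey; F.dz_[j] -= fd * ez;
    F.rx_[i] += fr * ex; F.ry_[i] += fr * ey; F.rz_[i] += fr * ez;
    F.rx_[j] -= fr * ex; F.ry_[j] -= fr * ey; F.rz_[j] -= fr * ez;
  }
}

static void nonbonded_allpairs(const System &S, uint64_t seed, uint64_t step,
                               const double *x, const double *y,
                               const double *z, const double *vx,
                               const double *vy, const double *vz, Forces &F) {
  for (int i = 0; i < S.n; ++i) {
    for (int j = i + 1; j < S.n; ++j) {
      const double dx = min_image(x[i] - x[j], S.box);
      const double dy = min_image(y[i] - y[j], S.box);
      const double dz = min_image(z[i] - z[j], S.box);
      pair_kernel(S, seed, step, i, j, dx, dy, dz, dx * dx + dy * dy + dz * dz,
                  vx, vy, vz, F);
    }
  }
}

struct CellList {
  int nc;                 // cells per dimension
  double inv_edge;
  std::vector<int> head, nxt;
  void build(int n, double box, double rc, const double *x, const double *y,
             const double *z) {
    nc = (int)std::floor(box / rc);
    if (nc < 3) nc = 0;   // too few cells: caller falls back to all-pairs
    if (nc == 0) return;
    inv_edge = nc / box;
    head.assign(nc * nc * nc, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)(x[i] * inv_edge); if (cx >= nc) cx = nc - 1;
      int cy = (int)(y[i] * inv_edge); if (cy >= nc) cy = nc - 1;
      int cz = (int)(z[i] * inv_edge); if (cz >= nc) cz = nc - 1;
      const int c = cx + nc * (cy + nc * cz);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// Half stencil: self cell plus 13 forward neighbours.
static const int HALF_STENCIL[13][3] = {
    {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
    {-1, -1, 1}, {0, -1, 1}, {1, -1, 1},
    {-1, 0, 1}, {0, 0, 1}, {1, 0, 1},
    {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};

// Periodic images are handled through per-stencil coordinate shifts, so the
// hot pair loop needs no rounding: beads in adjacent cells are within two
// cell widths, and with >= 3 cells per dimension only the shifted image can
// fall inside the cutoff.
static void nonbonded_cells(const System &S, uint64_t seed, uint64_t step,
                            const double *x, const double *y, const double *z,
                            const double *vx, const double *vy,
                            const double *vz, CellList &cl, Forces &F) {
  const int nc = cl.nc;
  for (int czi = 0; czi < nc; ++czi)
    for (int cyi = 0; cyi < nc; ++cyi)
      for (int cxi = 0; cxi < nc; ++cxi) {
        const int c = cxi + nc * (cyi + nc * czi);
        // pairs within the cell
        for (int i = cl.head[c]; i >= 0; i = cl.nxt[i])
          for (int j = cl.nxt[i]; j >= 0; j = cl.nxt[j]) {
            const double dx = x[i] - x[j];
            const double dy = y[i] - y[j];
            const double dz = z[i] - z[j];
            pair_kernel(S, seed, step, i, j, dx, dy, dz,
                        dx * dx + dy * dy + dz * dz, vx, vy, vz, F);
          }
        // pairs with forward neighbour cells
        for (int s = 0; s < 13; ++s) {
          int nx = cxi + HALF_STENCIL[s][0];
          int ny = cyi + HALF_STENCIL[s][1];
          int nz = czi + HALF_STENCIL[s][2];
          double sx = 0, sy = 0, sz = 0;   // image shift of cell c2
          if (nx < 0) { nx += nc; sx = -S.box; }
          else if (nx >= nc) { nx -= nc; sx = S.box; }
          if (ny < 0) { ny += nc; sy = -S.box; }
          else if (ny >= nc) { ny -= nc; sy = S.box; }
          if (nz < 0) { nz += nc; sz = -S.box; }
          else if (nz >= nc) { nz -= nc; sz = S.box; }
          const int c2 = nx + nc * (ny + nc * nz);
          for (int i = cl.head[c]; i >= 0; i = cl.nxt[i]) {
            const double xi = x[i] - sx, yi = y[i] - sy, zi = z[i] - sz;
            for (int j = cl.head[c2]; j >= 0; j = cl.nxt[j]) {
              const double dx = xi - x[j];
              const double dy = yi - y[j];
              const double dz = zi - z[j];
              pair_kernel(S, seed, step, i, j, dx, dy, dz,
                          dx * dx + dy * dy + dz * dz, vx, vy, vz, F);
            }
          }
        }
      }
}

// Harmonic bonds: F = -k (r - r0) rhat on each partner, minimum image.
static void bond_forces_acc(int nb, const int *bi, const int *bj, double k,
                            double r0, double box, const double *x,
                            const double *y, const double *z, Forces &F,
                            double *bx, double *by, double *bz) {
  for (int b = 0; b < nb; ++b) {
    const int i = bi[b], j = bj[b];
    const double dx = min_image(x[i] - x[j], box);
    const double dy = min_image(y[i] - y[j], box);
    const double dz = min_image(z[i] - z[j], box);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0.0) continue;
    const double fmag = -k * (r - r0);    // along rhat from j to i
    const double fx = fmag * dx / r, fy = fmag * dy / r, fz = fmag * dz / r;
    F.fx[i] += fx; F.fy[i] += fy; F.fz[i] += fz;
    F.fx[j] -= fx; F.fy[j] -= fy; F.fz[j] -= fz;
    F.virial_c += fmag * r;
    if (bx) {
      bx[i] += fx; by[i] += fy; bz[i] += fz;
      bx[j] -= fx; by[j] -= fy; bz[j] -= fz;
    }
  }
}

static inline double wrap01(double v, double box) {
  v -= box * std::floor(v / box);
  if (v >= box) v -= box;   // guard rounding at the upper edge
  if (v < 0) v = 0;
  return v;
}

// One-shot force evaluation with the three non-bonded contributions and the
// bond contribution reported separately.  method: 0 = auto (cell list when the
// box admits >= 3 cells per dimension), 1 = force all-pairs, 2 = force cells.
// [[Rcpp::export]]
List dpd_forces_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector species0,
                    NumericMatrix amat, double gamma, double sigma, double rc,
                    double box, double dt, double seed, double step,
                    IntegerMatrix bonds0, double spring_k, double spring_r0,
                    int method) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = wrap01(pos(i, 0), box);
    y[i] = wrap01(pos(i, 1), box);
    z[i] = wrap01(pos(i, 2), box);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  System S{n, box, rc, gamma, sigma, 1.0 / std::sqrt(dt),
           REAL(amat), amat.nrow(), INTEGER(species0)};

  Forces F(n);
  NumericMatrix FC(n, 3), FD(n, 3), FR(n, 3), FB(n, 3);
  std::vector<double> cx(n, 0), cy(n, 0), cz(n, 0), dx(n, 0), dy(n, 0),
      dz(n, 0), rx(n, 0), ry(n, 0), rz(n, 0), bx(n, 0), by(n, 0), bz(n, 0);
  F.cx = cx.data(); F.cy = cy.data(); F.cz = cz.data();
  F.dx_ = dx.data(); F.dy_ = dy.data(); F.dz_ = dz.data();
  F.rx_ = rx.data(); F.ry_ = ry.data(); F.rz_ = rz.data();

  CellList cl;
  bool use_cells = (method != 1);
  if (use_cells) {
    cl.build(n, box, rc, x.data(), y.data(), z.data());
    if (cl.nc == 0) {
      if (method == 2) stop("box too small for a cell list (needs >= 3 r_c)");
      use_cells = false;
    }
  }
  if (use_cells)
    nonbonded_cells(S, (uint64_t)seed, (uint64_t)step, x.data(), y.data(),
                    z.data(), vx.data(), vy.data(), vz.data(), cl, F);
  else
    nonbonded_allpairs(S, (uint64_t)seed, (uint64_t)step, x.data(), y.data(),
                       z.data(), vx.data(), vy.data(), vz.data(), F);

  const int nb = bonds0.nrow();
  std::vector<int> bi(nb), bj(nb);
  for (int b = 0; b < nb; ++b) { bi[b] = bonds0(b, 0); bj[b] = bonds0(b, 1); }
  bond_forces_acc(nb, bi.data(), bj.data(), spring_k, spring_r0, box, x.data(),
                  y.data(), z.data(), F, bx.data(), by.data(), bz.data());

  NumericMatrix FT(n, 3);
  for (int i = 0; i < n; ++i) {
    FC(i, 0) = cx[i]; FC(i, 1) = cy[i]; FC(i, 2) = cz[i];
    FD(i, 0) = dx[i]; FD(i, 1) = dy[i]; FD(i, 2) = dz[i];
    FR(i, 0) = rx[i]; FR(i, 1) = ry[i]; FR(i, 2) = rz[i];
    FB(i, 0) = bx[i]; FB(i, 1) = by[i]; FB(i, 2) = bz[i];
    FT(i, 0) = F.fx[i]; FT(i, 1) = F.fy[i]; FT(i, 2) = F.fz[i];
  }
  return List::create(_["conservative"] = FC, _["dissipative"] = FD,
                      _["random"] = FR, _["bond"] = FB, _["total"] = FT,
                      _["virial"] = F.virial_c,
                      _["used_cell_list"] = use_cells);
}

// Groot-Warren modified velocity-Verlet run loop.
// [[Rcpp::export]]
List dpd_run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector species0,
                 NumericMatrix amat, double gamma, double sigma, double rc,
                 double box, IntegerMatrix bonds0, double spring_k,
                 double spring_r0, double dt, double lambda, int n_steps,
                 double seed, int thermo_interval, int traj_interval) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = wrap01(pos(i, 0), box);
    y[i] = wrap01(pos(i, 1), box);
    z[i] = wrap01(pos(i, 2), box);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  System S{n, box, rc, gamma, sigma, 1.0 / std::sqrt(dt),
           REAL(amat), amat.nrow(), INTEGER(species0)};
  const int nb = bonds0.nrow();
  std::vector<int> bi(nb), bj(nb);
  for (int b = 0; b < nb; ++b) { bi[b] = bonds0(b, 0); bj[b] = bonds0(b, 1); }

  CellList cl;
  cl.build(n, box, rc, x.data(), y.data(), z.data());
  const bool use_cells = cl.nc > 0;
  const double vol = box * box * box;
  const uint64_t sd = (uint64_t)seed;

  auto eval_forces = [&](uint64_t step, Forces &F) {
    if (use_cells) {
      cl.build(n, box, rc, x.data(), y.data(), z.data());
      nonbonded_cells(S, sd, step, x.data(), y.data(), z.data(), vx.data(),
                      vy.data(), vz.data(), cl, F);
    } else {
      nonbonded_allpairs(S, sd, step, x.data(), y.data(), z.data(), vx.data(),
                         vy.data(), vz.data(), F);
    }
    bond_forces_acc(nb, bi.data(), bj.data(), spring_k, spring_r0, box,
                    x.data(), y.data(), z.data(), F, nullptr, nullptr,
                    nullptr);
  };

  Forces F(n);
  eval_forces(0, F);

  const int n_thermo = thermo_interval > 0 ? n_steps / thermo_interval : 0;
  NumericMatrix thermo(n_thermo, 6);
  int it = 0;
  const int n_frames = traj_interval > 0 ? n_steps / traj_interval : 0;
  List frames(n_frames);
  IntegerVector frame_steps(n_frames);
  int ifr = 0;

  std::vector<double> vtx(n), vty(n), vtz(n);
  for (int step = 1; step <= n_steps; ++step) {
    // position update and lambda-predicted velocities
    for (int i = 0; i < n; ++i) {
      x[i] = wrap01(x[i] + dt * vx[i] + 0.5 * dt * dt * F.fx[i], box);
      y[i] = wrap01(y[i] + dt * vy[i] + 0.5 * dt * dt * F.fy[i], box);
      z[i] = wrap01(z[i] + dt * vz[i] + 0.5 * dt * dt * F.fz[i], box);
      vtx[i] = vx[i] + lambda * dt * F.fx[i];
      vty[i] = vy[i] + lambda * dt * F.fy[i];
      vtz[i] = vz[i] + lambda * dt * F.fz[i];
      // catch divergence before coordinates reach the cell binning
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(z[i]) || !std::isfinite(vtx[i]) ||
          !std::isfinite(vty[i]) || !std::isfinite(vtz[i]))
        stop("integration blew up (non-finite state) at step %d", step);
    }
    // forces at new positions with predicted velocities
    Forces F2(n);
    std::swap(vx, vtx); std::swap(vy, vty); std::swap(vz, vtz);
    eval_forces((uint64_t)step, F2);
    std::swap(vx, vtx); std::swap(vy, vty); std::swap(vz, vtz);
    // velocity correction
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * (F.fx[i] + F2.fx[i]);
      vy[i] += 0.5 * dt * (F.fy[i] + F2.fy[i]);
      vz[i] += 0.5 * dt * (F.fz[i] + F2.fz[i]);
      if (!std::isfinite(x[i]) || !std::isfinite(vx[i]) ||
          !std::isfinite(y[i]) || !std::isfinite(vy[i]) ||
          !std::isfinite(z[i]) || !std::isfinite(vz[i]))
        stop("integration blew up (non-finite state) at step %d", step);
    }
    F.fx.swap(F2.fx); F.fy.swap(F2.fy); F.fz.swap(F2.fz);
    F.virial_c = F2.virial_c;

    if (thermo_interval > 0 && step % thermo_interval == 0) {
      double ke = 0, px = 0, py = 0, pz = 0;
      for (int i = 0; i < n; ++i) {
        ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
        px += vx[i]; py += vy[i]; pz += vz[i];
      }
      const double kT = n > 1 ? ke / (3.0 * n - 3.0) : 0.0;
      thermo(it, 0) = step;
      thermo(it, 1) = kT;
      thermo(it, 2) = px; thermo(it, 3) = py; thermo(it, 4) = pz;
      thermo(it, 5) = n * kT / vol + F.virial_c / (3.0 * vol);
      ++it;
    }
    if (traj_interval > 0 && step % traj_interval == 0) {
      NumericMatrix P(n, 3), V(n, 3);
      for (int i = 0; i < n; ++i) {
        P(i, 0) = x[i]; P(i, 1) = y[i]; P(i, 2) = z[i];
        V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
      }
      frames[ifr] = List::create(_["positions"] = P, _["velocities"] = V);
      frame_steps[ifr] = step;
      ++ifr;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix P(n, 3), V(n, 3);
  for (int i = 0; i < n; ++i) {
    P(i, 0) = x[i]; P(i, 1) = y[i]; P(i, 2) = z[i];
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  return List::create(_["positions"] = P, _["velocities"] = V,
                      _["thermo"] = thermo, _["frames"] = frames,
                      _["frame_steps"] = frame_steps);
}

// Histogram of target beads around reference beads in shells of width dr,
// minimum image.  Returns raw pair counts per bin (not yet normalised).
// [[Rcpp::export]]
NumericVector rdf_counts_cpp(NumericMatrix pos, double box,
                             IntegerVector ref_idx0, IntegerVector tgt_idx0,
                             double dr, int nbin) {
  NumericVector counts(nbin);
  const double r_max = nbin * dr;
  const int nr = ref_idx0.size(), nt = tgt_idx0.size();
  for (int a = 0; a < nr; ++a) {
    const int i = ref_idx0[a];
    for (int b = 0; b < nt; ++b) {
      const int j = tgt_idx0[b];
      if (i == j) continue;
      const double dx = min_image(pos(i, 0) - pos(j, 0), box);
      const double dy = min_image(pos(i, 1) - pos(j, 1), box);
      const double dz = min_image(pos(i, 2) - pos(j, 2), box);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < r_max) {
        int k = (int)(r / dr);
        if (k >= nbin) k = nbin - 1;
        counts[k] += 1.0;
      }
    }
  }
  return counts;
}

// Contact pairs (i, j) within cutoff among the given subset, minimum image.
// Returns a 2-column matrix of 0-based indices into the subset.
// [[Rcpp::export]]
IntegerMatrix contact_pairs_cpp(NumericMatrix pos, double box,
                                IntegerVector idx0, double cutoff) {
  const int m = idx0.size();
  std::vector<int> pi, pj;
  const double c2 = cutoff * cutoff;
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) {
      const double dx = min_image(pos(idx0[a], 0) - pos(idx0[b], 0), box);
      const double dy = min_image(pos(idx0[a], 1) - pos(idx0[b], 1), box);
      const double dz = min_image(pos(idx0[a], 2) - pos(idx0[b], 2), box);
      if (dx * dx + dy * dy + dz * dz <= c2) {
        pi.push_back(a);
        pj.push_back(b);
      }
    }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k];
    out(k, 1) = pj[k];
  }
  return out;
}
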