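// Hot kernels for the surfel engine: uniform-grid fixed-radius neighbor
// search, pairwise force accumulation, and trilinear image sampling.
// Semantics mirror the R-level reference operations (f_dist_profile,
// pair_interaction, local_max_offset); tests assert the two routes agree.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---- uniform hash grid -----------------------------------------------------

// cell coordinates packed into one 64-bit key; 2^20 offset keeps floors of
// any realistic voxel coordinate positive
static inline int64_t cell_key(int ix, int iy, int iz) {
  const int64_t OFF = 1 << 20;
  return (((int64_t)(ix) + OFF) << 42) | (((int64_t)(iy) + OFF) << 21) |
         ((int64_t)(iz) + OFF);
}

struct UniformGrid {
  double cell;
  NumericMatrix pos;                       // snapshot, n x 3
  std::unordered_map<int64_t, std::vector<int>> cells;  // 0-based indices
};

// [[Rcpp::export]]
SEXP cpp_grid_build(NumericMatrix pos, double cell_size) {
  if (cell_size <= 0) stop("cell_size must be > 0");
  UniformGrid* g = new UniformGrid();
  g->cell = cell_size;
  g->pos = pos;
  int n = pos.nrow();
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c)
      if (!R_finite(pos(i, c)))
        stop("non-finite position for surfel at row %d", i + 1);
    int ix = (int)std::floor(pos(i, 0) / cell_size);
    int iy = (int)std::floor(pos(i, 1) / cell_size);
    int iz = (int)std::floor(pos(i, 2) / cell_size);
    g->cells[cell_key(ix, iy, iz)].push_back(i);
  }
  XPtr<UniformGrid> p(g, true);
  return p;
}

// [[Rcpp::export]]
IntegerMatrix cpp_grid_cells(SEXP grid) {
  // floor-cell of every point, row-aligned with the build positions
  XPtr<UniformGrid> g(grid);
  int n = g->pos.nrow();
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c)
      out(i, c) = (int)std::floor(g->pos(i, c) / g->cell);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_grid_query(SEXP grid, NumericVector center, double radius,
                             int exclude) {
  // exclude is a 1-based row index or 0 for none; closed ball (d <= radius)
  XPtr<UniformGrid> g(grid);
  if (radius > g->cell + 1e-12)
    stop("query radius (%g) exceeds grid cell size (%g)", radius, g->cell);
  double r2 = radius * radius;
  int cx = (int)std::floor(center[0] / g->cell);
  int cy = (int)std::floor(center[1] / g->cell);
  int cz = (int)std::floor(center[2] / g->cell);
  std::vector<int> hits;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        auto it = g->cells.find(cell_key(cx + dx, cy + dy, cz + dz));
        if (it == g->cells.end()) continue;
        for (int i : it->second) {
          if (i + 1 == exclude) continue;
          double a = g->pos(i, 0) - center[0];
          double b = g->pos(i, 1) - center[1];
          double c = g->pos(i, 2) - center[2];
          if (a * a + b * b + c * c <= r2) hits.push_back(i + 1);
        }
      }
  std::sort(hits.begin(), hits.end());
  return wrap(hits);
}

// [[Rcpp::export]]
List cpp_grid_pairs(SEXP grid, double radius) {
  // all unordered pairs (i < j, 1-based) with distance <= radius,
  // emitted in ascending (i, j) order
  XPtr<UniformGrid> g(grid);
  if (radius > g->cell + 1e-12)
    stop("pair radius (%g) exceeds grid cell size (%g)", radius, g->cell);
  double r2 = radius * radius;
  int n = g->pos.nrow();
  std::vector<int> vi, vj;
  std::vector<double> vd;
  std::vector<int> local;
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor(g->pos(i, 0) / g->cell);
    int cy = (int)std::floor(g->pos(i, 1) / g->cell);
    int cz = (int)std::floor(g->pos(i, 2) / g->cell);
    local.clear();
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = g->cells.find(cell_key(cx + dx, cy + dy, cz + dz));
          if (it == g->cells.end()) continue;
          for (int j : it->second)
            if (j > i) {
              double a = g->pos(j, 0) - g->pos(i, 0);
              double b = g->pos(j, 1) - g->pos(i, 1);
              double c = g->pos(j, 2) - g->pos(i, 2);
              if (a * a + b * b + c * c <= r2) local.push_back(j);
            }
        }
    std::sort(local.begin(), local.end());
    for (int j : local) {
      double a = g->pos(j, 0) - g->pos(i, 0);
      double b = g->pos(j, 1) - g->pos(i, 1);
      double c = g->pos(j, 2) - g->pos(i, 2);
      vi.push_back(i + 1);
      vj.push_back(j + 1);
      vd.push_back(std::sqrt(a * a + b * b + c * c));
    }
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj), _["d"] = wrap(vd));
}

// ---- pairwise forces -------------------------------------------------------

// distance-restoring profile: harmonic repulsion below the equilibrium
// distance, breakable-bond attraction above it (vanishes at 1 and at infinity)
static inline double fdist(double x, double w) {
  if (x < 1.0) return x - 1.0;
  double e = x - 1.0;
  return e * std::exp(-(e * e) / (w * w));
}

// [[Rcpp::export]]
List cpp_pair_forces(NumericMatrix pos, NumericMatrix nrm, IntegerVector pi,
                     IntegerVector pj, NumericVector pd, IntegerVector object,
                     IntegerVector state, double d0, double k_dist,
                     double k_plane, double k_tilt, double w) {
  // state codes: 0 active, 1 converged, 2 locked. Pairs where both ends are
  // locked contribute nothing (neither end will move); a locked surfel still
  // exerts forces on a non-locked partner. Cross-object pairs keep only the
  // harmonic repulsive branch of F_dist and are not neighbors for density.
  int n = pos.nrow(), m = pi.size();
  NumericMatrix F(n, 3), T(n, 3);
  IntegerVector count(n);          // same-object neighbor count
  IntegerVector active_nb(n);      // has a same-object neighbor not converged/locked
  for (int k = 0; k < m; ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    double d = pd[k];
    if (d <= 0) stop("coincident surfels %d and %d", i + 1, j + 1);
    bool same = object[i] == object[j];
    if (same) {
      count[i]++; count[j]++;
      if (state[j] == 0) active_nb[i] = 1;
      if (state[i] == 0) active_nb[j] = 1;
    }
    if (state[i] == 2 && state[j] == 2) continue;
    double ux = (pos(j, 0) - pos(i, 0)) / d;
    double uy = (pos(j, 1) - pos(i, 1)) / d;
    double uz = (pos(j, 2) - pos(i, 2)) / d;
    double x = d / d0;
    if (same) {
      double fd = k_dist * fdist(x, w);
      // F_plane on i along n_i, on j along n_j; u flips for the j <- i pair
      double s = ux * (nrm(i, 0) + nrm(j, 0)) + uy * (nrm(i, 1) + nrm(j, 1)) +
                 uz * (nrm(i, 2) + nrm(j, 2));
      // tilt increment relaxes n towards the pair plane (restoring sign:
      // the increment removes the component of n along u)
      double ti = -k_tilt * (nrm(i, 0) * ux + nrm(i, 1) * uy + nrm(i, 2) * uz);
      double tj = -k_tilt * (nrm(j, 0) * ux + nrm(j, 1) * uy + nrm(j, 2) * uz);
      F(i, 0) += fd * ux + k_plane * s * nrm(i, 0);
      F(i, 1) += fd * uy + k_plane * s * nrm(i, 1);
      F(i, 2) += fd * uz + k_plane * s * nrm(i, 2);
      F(j, 0) += -fd * ux - k_plane * s * nrm(j, 0);
      F(j, 1) += -fd * uy - k_plane * s * nrm(j, 1);
      F(j, 2) += -fd * uz - k_plane * s * nrm(j, 2);
      T(i, 0) += ti * ux; T(i, 1) += ti * uy; T(i, 2) += ti * uz;
      T(j, 0) += tj * ux; T(j, 1) += tj * uy; T(j, 2) += tj * uz;
    } else if (x < 1.0) {
      double fd = k_dist * (x - 1.0);  // repulsive branch only
      F(i, 0) += fd * ux; F(i, 1) += fd * uy; F(i, 2) += fd * uz;
      F(j, 0) -= fd * ux; F(j, 1) -= fd * uy; F(j, 2) -= fd * uz;
    }
  }
  return List::create(_["F"] = F, _["T"] = T, _["count"] = count,
                      _["active_nb"] = active_nb);
}

// ---- image sampling --------------------------------------------------------

static inline double trilin(const double* v, int nx, int ny, int nz, double x,
                            double y, double z, bool& outside) {
  // 0-based voxel-center coordinates; outside the [0, n-1] box -> outside
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    outside = true;
    return 0.0;
  }
  outside = false;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  #define V(a, b, c) v[(a) + (int64_t)nx * ((b) + (int64_t)ny * (c))]
  double c00 = V(i0, j0, k0) * (1 - fx) + V(i0 + 1, j0, k0) * fx;
  double c10 = V(i0, j0 + 1, k0) * (1 - fx) + V(i0 + 1, j0 + 1, k0) * fx;
  double c01 = V(i0, j0, k0 + 1) * (1 - fx) + V(i0 + 1, j0, k0 + 1) * fx;
  double c11 = V(i0, j0 + 1, k0 + 1) * (1 - fx) + V(i0 + 1, j0 + 1, k0 + 1) * fx;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = REAL(vol);
  int n = pts.nrow();
  NumericVector out(n);
  bool outside;
  for (int i = 0; i < n; ++i) {
    double val = trilin(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2), outside);
    out[i] = outside ? NA_REAL : val;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_profile_max(NumericVector vol, IntegerVector dim,
                              NumericMatrix pos, NumericMatrix nrm,
                              double band, double step, NumericVector spacing,
                              double flat_tol) {
  // For each surfel, sample the image along its normal at offsets
  // s in [-band, band] (physical units, spacing `step`) and return the
  // offset of the maximum sample. Plateaus of (near-)equal maxima return
  // the plateau centroid, so a surfel inside a thick bright shell reports
  // the shell centre-line. NA means no usable maximum (flat profile or
  // fully outside the volume). Out-of-volume samples rank below all
  // in-volume intensities.
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = REAL(vol);
  int n = pos.nrow();
  int half = (int)std::floor(band / step + 1e-9);
  int ns = 2 * half + 1;
  NumericVector out(n);
  std::vector<double> sval(ns), soff(ns);
  for (int i = 0; i < n; ++i) {
    // direction of unit physical length, expressed in voxel coordinates
    double ex = nrm(i, 0) * spacing[0];
    double ey = nrm(i, 1) * spacing[1];
    double ez = nrm(i, 2) * spacing[2];
    double en = std::sqrt(ex * ex + ey * ey + ez * ez);
    double dx = nrm(i, 0) / en, dy = nrm(i, 1) / en, dz = nrm(i, 2) / en;
    bool outside, any_in = false;
    double vmax = -1e300, vmin = 1e300;
    for (int k = 0; k < ns; ++k) {
      double s = (k - half) * step;
      double val = trilin(v, nx, ny, nz, pos(i, 0) + s * dx, pos(i, 1) + s * dy,
                          pos(i, 2) + s * dz, outside);
      if (outside) {
        sval[k] = NA_REAL;
      } else {
        sval[k] = val;
        any_in = true;
        if (val > vmax) vmax = val;
        if (val < vmin) vmin = val;
      }
      soff[k] = s;
    }
    if (!any_in || (vmax - vmin) < flat_tol) {
      out[i] = NA_REAL;
      continue;
    }
    double sum = 0;
    int cnt = 0;
    for (int k = 0; k < ns; ++k)
      if (!ISNA(sval[k]) && sval[k] >= vmax - 1e-9) {
        sum += soff[k];
        cnt++;
      }
    out[i] = sum / cnt;
  }
  return out;
}
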