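#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays in (z, y, x) order, column-major:
// linear index = z + nz * (y + ny * x), all 0-based here.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + (long long)ny * x);
}

// ---------------------------------------------------------------------------
// Sliding-window local statistic maps.
//
// Input intensities are integers in [0, nlevels-1]. Windows are cubes of
// half-width r_small (range, sd) and r_ent (entropy), clipped at the array
// border. Entropy is Shannon entropy in bits of the within-window histogram
// over nlevels; sd uses the n-1 denominator.
// [[Rcpp::export]]
List cpp_local_stat_maps(IntegerVector vox, IntegerVector dim,
                         int r_small, int r_ent, int nlevels) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector ent(n), rng(n), sdv(n);
  std::vector<int> hist(nlevels, 0);
  std::vector<int> touched;
  touched.reserve(512);

  const int* vp = INTEGER(vox);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        // range + sd window
        int z0 = std::max(0, z - r_small), z1 = std::min(nz - 1, z + r_small);
        int y0 = std::max(0, y - r_small), y1 = std::min(ny - 1, y + r_small);
        int x0 = std::max(0, x - r_small), x1 = std::min(nx - 1, x + r_small);
        int vmin = nlevels, vmax = -1, cnt = 0;
        double s = 0.0, s2 = 0.0;
        for (int xx = x0; xx <= x1; ++xx)
          for (int yy = y0; yy <= y1; ++yy) {
            const int* col = vp + nz * (yy + (long long)ny * xx);
            for (int zz = z0; zz <= z1; ++zz) {
              int v = col[zz];
              if (v < vmin) vmin = v;
              if (v > vmax) vmax = v;
              s += v; s2 += (double)v * v; ++cnt;
            }
          }
        R_xlen_t here = lin(z, y, x, nz, ny);
        rng[here] = vmax - vmin;
        double var = (cnt > 1) ? (s2 - s * s / cnt) / (cnt - 1) : 0.0;
        sdv[here] = var > 0 ? std::sqrt(var) : 0.0;

        // entropy window
        z0 = std::max(0, z - r_ent); z1 = std::min(nz - 1, z + r_ent);
        y0 = std::max(0, y - r_ent); y1 = std::min(ny - 1, y + r_ent);
        x0 = std::max(0, x - r_ent); x1 = std::min(nx - 1, x + r_ent);
        touched.clear();
        int m = 0;
        for (int xx = x0; xx <= x1; ++xx)
          for (int yy = y0; yy <= y1; ++yy) {
            const int* col = vp + nz * (yy + (long long)ny * xx);
            for (int zz = z0; zz <= z1; ++zz) {
              int v = col[zz];
              if (hist[v] == 0) touched.push_back(v);
              ++hist[v]; ++m;
            }
          }
        double H = 0.0;
        for (size_t t = 0; t < touched.size(); ++t) {
          double p = (double)hist[touched[t]] / m;
          H -= p * std::log2(p);
          hist[touched[t]] = 0;
        }
        ent[here] = H;
      }
    }
  }
  return List::create(_["entropy"] = ent, _["range"] = rng, _["sd"] = sdv);
}

// ---------------------------------------------------------------------------
// Gray-level co-occurrence counts for a single +offset step along one axis
// (0 = z, 1 = y, 2 = x). Only voxel pairs with both endpoints inside the ROI
// are counted. q holds levels in [0, nlevels-1]. Returns raw (asymmetric)
// counts; symmetrization/normalization is done by the caller.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector q, LogicalVector roi, IntegerVector dim,
                       int offset, int axis, int nlevels) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericMatrix counts(nlevels, nlevels);
  int dz = axis == 0 ? offset : 0;
  int dy = axis == 1 ? offset : 0;
  int dx = axis == 2 ? offset : 0;
  for (int x = 0; x < nx - dx; ++x)
    for (int y = 0; y < ny - dy; ++y)
      for (int z = 0; z < nz - dz; ++z) {
        R_xlen_t a = lin(z, y, x, nz, ny);
        R_xlen_t b = lin(z + dz, y + dy, x + dx, nz, ny);
        if (roi[a] && roi[b]) counts(q[a], q[b]) += 1.0;
      }
  return counts;
}

// ---------------------------------------------------------------------------
// Connected-component labeling of a binary volume, 6- or 26-connectivity,
// two-pass union-find. Labels are 1..K, background 0.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
  return i;
}
static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> parent;
  parent.push_back(0);  // background sentinel

  // previously-scanned neighbor offsets (scan order: z fastest, then y, x)
  std::vector<std::array<int,3>> nb;
  if (connectivity == 6) {
    nb = {{{-1,0,0}}, {{0,-1,0}}, {{0,0,-1}}};
  } else {
    for (int dx = -1; dx <= 0; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (dx == 0 && (dy > 0 || (dy == 0 && dz >= 0))) continue;
          nb.push_back({{dz, dy, dx}});
        }
  }

  int next = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t here = lin(z, y, x, nz, ny);
        if (!mask[here]) continue;
        int assigned = 0;
        for (size_t k = 0; k < nb.size(); ++k) {
          int zz = z + nb[k][0], yy = y + nb[k][1], xx = x + nb[k][2];
          if (zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx)
            continue;
          int l = lab[lin(zz, yy, xx, nz, ny)];
          if (l > 0) {
            if (assigned == 0) assigned = l;
            else uf_union(parent, assigned, l);
          }
        }
        if (assigned == 0) {
          assigned = ++next;
          parent.push_back(assigned);
        }
        lab[here] = assigned;
      }

  // flatten + relabel densely
  std::vector<int> remap(next + 1, 0);
  int k = 0;
  for (int i = 1; i <= next; ++i) {
    int r = uf_find(parent, i);
    if (remap[r] == 0) remap[r] = ++k;
    remap[i] = remap[r];
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (lab[i] > 0) lab[i] = remap[lab[i]];
  return lab;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (distance to nearest TRUE voxel),
// separable lower-envelope algorithm applied along z, y, x in turn.
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& zb) {
  int k = 0;
  v[0] = 0; zb[0] = -1e30; zb[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= zb[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q; zb[k] = s; zb[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double BIG = 1e20;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), out(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = d[lin(z, y, x, nz, ny)];
      dt1d(f, out, nz, v, zb);
      for (int z = 0; z < nz; ++z) d[lin(z, y, x, nz, ny)] = out[z];
    }
  // along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d[lin(z, y, x, nz, ny)];
      dt1d(f, out, ny, v, zb);
      for (int y = 0; y < ny; ++y) d[lin(z, y, x, nz, ny)] = out[y];
    }
  // along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = d[lin(z, y, x, nz, ny)];
      dt1d(f, out, nx, v, zb);
      for (int x = 0; x < nx; ++x) d[lin(z, y, x, nz, ny)] = out[x];
    }
  return d;
}
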