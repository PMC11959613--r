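#include <Rcpp.h>
#include <vector>
#include <queue>
#include <utility>
#include <cmath>
using namespace Rcpp;

// All volumes are R arrays with dim = (Z, Y, X); z is the fastest index.
static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
}

// 26-connected component labelling of a logical volume.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx; if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz; if (zz < 0 || zz >= nz) continue;
            R_xlen_t w = vidx(zz, yy, xx, nz, ny);
            if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), grid step `step`.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, double step) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY; zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double qq = q * step, s;
    for (;;) {
      double vv = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s > zb[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    zb[k] = s; zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * step;
    while (zb[k + 1] < qq) ++k;
    double vv = v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Euclidean distance (in units of `spacing`) from each foreground voxel to the
// nearest background voxel. Background voxels get 0.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector fg, IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? INF : 0.0;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = out[vidx(z, y, x, nz, ny)];
      f.resize(nz); d.resize(nz);
      dt1d(f, d, v, zb, spacing[0]);
      for (int z = 0; z < nz; ++z) out[vidx(z, y, x, nz, ny)] = d[z];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = out[vidx(z, y, x, nz, ny)];
      f.resize(ny); d.resize(ny);
      dt1d(f, d, v, zb, spacing[1]);
      for (int y = 0; y < ny; ++y) out[vidx(z, y, x, nz, ny)] = d[y];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = out[vidx(z, y, x, nz, ny)];
      f.resize(nx); d.resize(nx);
      dt1d(f, d, v, zb, spacing[2]);
      for (int x = 0; x < nx; ++x) out[vidx(z, y, x, nz, ny)] = d[x];
      f.resize(nmax); d.resize(nmax);
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}

// Local Shannon entropy (bits) of a quantized volume within an arbitrary
// neighbourhood (offsets: rows of (dz, dy, dx)), evaluated where mask is TRUE.
// Neighbourhoods are clipped at the volume border; voxels outside the mask
// still contribute to the histogram of an in-mask centre voxel.
// [[Rcpp::export]]
NumericVector cpp_entropy3d(IntegerVector img, LogicalVector mask,
                            IntegerVector dims, IntegerMatrix offsets, int nbins) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const int noff = offsets.nrow();
  NumericVector out(n, 0.0);
  std::vector<int> counts(nbins, 0);
  std::vector<int> touched; touched.reserve(noff);
  const double log2e = 1.0 / std::log(2.0);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int z = (int)(s % nz);
    int y = (int)((s / nz) % ny);
    int x = (int)(s / ((R_xlen_t)nz * ny));
    touched.clear();
    int tot = 0;
    for (int o = 0; o < noff; ++o) {
      int zz = z + offsets(o, 0); if (zz < 0 || zz >= nz) continue;
      int yy = y + offsets(o, 1); if (yy < 0 || yy >= ny) continue;
      int xx = x + offsets(o, 2); if (xx < 0 || xx >= nx) continue;
      int b = img[vidx(zz, yy, xx, nz, ny)];
      if (b < 0 || b >= nbins) continue;
      if (counts[b] == 0) touched.push_back(b);
      ++counts[b];
      ++tot;
    }
    double h = 0.0;
    for (size_t t = 0; t < touched.size(); ++t) {
      double p = (double)counts[touched[t]] / tot;
      h -= p * std::log(p) * log2e;
      counts[touched[t]] = 0;
    }
    out[s] = h;
  }
  out.attr("dim") = dims;
  return out;
}

// Marker-controlled watershed by immersion: flood the relief downhill from
// the seed labels, restricted to mask, 26-connected. Ties broken by
// insertion order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_watershed_flood(NumericVector relief, IntegerVector seeds,
                                  LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  typedef std::pair<double, std::pair<long long, R_xlen_t> > QE;
  std::priority_queue<QE> pq;   // max-heap on relief; FIFO tie-break
  long long counter = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push(QE(relief[i], std::make_pair(-(counter++), i)));
    }
  while (!pq.empty()) {
    R_xlen_t v = pq.top().second.second; pq.pop();
    int z = (int)(v % nz);
    int y = (int)((v / nz) % ny);
    int x = (int)(v / ((R_xlen_t)nz * ny));
    for (int dx = -1; dx <= 1; ++dx) {
      int xx = x + dx; if (xx < 0 || xx >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          R_xlen_t w = vidx(zz, yy, xx, nz, ny);
          if (!mask[w] || lab[w] != 0) continue;
          lab[w] = lab[v];
          pq.push(QE(relief[w], std::make_pair(-(counter++), w)));
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Translate a volume by (dz, dy, dx) voxels (content moves by +shift) with
// trilinear interpolation; out-of-range samples take `fill`.
// [[Rcpp::export]]
NumericVector cpp_shift3d(NumericVector vol, IntegerVector dims,
                          double dz, double dy, double dx, double fill) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out((R_xlen_t)nz * ny * nx);
  for (int x = 0; x < nx; ++x) {
    double sx = x - dx;
    int x0 = (int)std::floor(sx); double fx = sx - x0;
    for (int y = 0; y < ny; ++y) {
      double sy = y - dy;
      int y0 = (int)std::floor(sy); double fy = sy - y0;
      for (int z = 0; z < nz; ++z) {
        double sz = z - dz;
        int z0 = (int)std::floor(sz); double fz = sz - z0;
        double acc = 0.0;
        for (int cx = 0; cx <= 1; ++cx) {
          int xi = x0 + cx;
          double wx = cx ? fx : 1 - fx;
          if (wx == 0) continue;
          for (int cy = 0; cy <= 1; ++cy) {
            int yi = y0 + cy;
            double wy = cy ? fy : 1 - fy;
            if (wy == 0) continue;
            for (int cz = 0; cz <= 1; ++cz) {
              int zi = z0 + cz;
              double wz = cz ? fz : 1 - fz;
              if (wz == 0) continue;
              double val = (xi < 0 || xi >= nx || yi < 0 || yi >= ny ||
                            zi < 0 || zi >= nz)
                             ? fill
                             : vol[vidx(zi, yi, xi, nz, ny)];
              acc += wx * wy * wz * val;
            }
          }
        }
        out[vidx(z, y, x, nz, ny)] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
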