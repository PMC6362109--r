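// Low-level 3D voxel operations on R arrays stored in column-major order
// with dimensions (nz, ny, nx): linear index = z + nz*(y + ny*x), 0-based.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Off { int dz, dy, dx; };

// Neighborhood offsets for 6 (face), 18 (face+edge) or 26 (full) connectivity.
static std::vector<Off> conn_offsets(int connectivity) {
  std::vector<Off> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
}

// Seeded flood fill with the static-mode acceptance rule: a voxel joins the
// region when |gray(v) - gray(seed)| <= tol/2, it lies in the domain, and
// (if radius_vox >= 0) its center is within radius_vox voxel units of the
// seed center. Each seed grows independently; the union is returned.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim,
                              IntegerMatrix seeds, NumericVector tol,
                              NumericVector radius_vox, int connectivity,
                              LogicalVector domain) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<Off> off = conn_offsets(connectivity);
  LogicalVector out(n, false);
  std::vector<char> visited(n);

  for (int s = 0; s < seeds.nrow(); ++s) {
    const int sz = seeds(s, 0), sy = seeds(s, 1), sx = seeds(s, 2);
    const double half = tol[s % tol.size()] / 2.0;
    const double rv = radius_vox[s % radius_vox.size()];  // < 0 => unlimited
    const double r2 = rv < 0 ? -1.0 : rv * rv;
    const R_xlen_t si = lin(sz, sy, sx, nz, ny);
    if (!domain[si]) stop("seed (%d,%d,%d) lies outside the domain", sz, sy, sx);
    const double ref = vol[si];

    std::fill(visited.begin(), visited.end(), 0);
    std::queue<R_xlen_t> q;
    visited[si] = 1;
    out[si] = true;
    q.push(si);
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop();
      int x = (int)(i / ((R_xlen_t)nz * ny));
      int rem = (int)(i - (R_xlen_t)x * nz * ny);
      int y = rem / nz, z = rem % nz;
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k].dz, yy = y + off[k].dy, xx = x + off[k].dx;
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = lin(zz, yy, xx, nz, ny);
        if (visited[j] || !domain[j]) continue;
        visited[j] = 1;
        if (std::fabs(vol[j] - ref) > half) continue;
        if (r2 >= 0) {
          double dz = zz - sz, dy = yy - sy, dx = xx - sx;
          if (dz * dz + dy * dy + dx * dx > r2) continue;
        }
        out[j] = true;
        q.push(j);
      }
    }
  }
  return out;
}

static std::vector<Off> ball_offsets(double radius) {
  std::vector<Off> off;
  int r = (int)std::floor(radius);
  double r2 = radius * radius;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dz * dz + dy * dy + dx * dx <= r2) off.push_back({dz, dy, dx});
  return off;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate_ball(LogicalVector mask, IntegerVector dim,
                              double radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<Off> off = ball_offsets(radius);
  LogicalVector out(n, false);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (!mask[lin(z, y, x, nz, ny)]) continue;
        for (size_t k = 0; k < off.size(); ++k) {
          int zz = z + off[k].dz, yy = y + off[k].dy, xx = x + off[k].dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          out[lin(zz, yy, xx, nz, ny)] = true;
        }
      }
  return out;
}

// Erosion with out-of-grid treated as foreground (so the grid border does
// not erode masks that touch it).
// [[Rcpp::export]]
LogicalVector cpp_erode_ball(LogicalVector mask, IntegerVector dim,
                             double radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<Off> off = ball_offsets(radius);
  LogicalVector out(n, false);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lin(z, y, x, nz, ny);
        if (!mask[i]) continue;
        bool keep = true;
        for (size_t k = 0; k < off.size() && keep; ++k) {
          int zz = z + off[k].dz, yy = y + off[k].dy, xx = x + off[k].dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          if (!mask[lin(zz, yy, xx, nz, ny)]) keep = false;
        }
        out[i] = keep;
      }
  return out;
}

// Connected-component labels (1..k) over true voxels; 0 elsewhere.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<Off> off = conn_offsets(connectivity);
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++cur;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t j = q.front(); q.pop();
      int x = (int)(j / ((R_xlen_t)nz * ny));
      int rem = (int)(j - (R_xlen_t)x * nz * ny);
      int y = rem / nz, z = rem % nz;
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k].dz, yy = y + off[k].dy, xx = x + off[k].dx;
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t m = lin(zz, yy, xx, nz, ny);
        if (mask[m] && !lab[m]) { lab[m] = cur; q.push(m); }
      }
    }
  }
  return lab;
}

// Fill cavities: background voxels not 6-connected to the grid border
// become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<Off> off = conn_offsets(6);
  std::vector<char> outside(n, 0);
  std::queue<R_xlen_t> q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (z != 0 && z != nz - 1 && y != 0 && y != ny - 1 &&
            x != 0 && x != nx - 1) continue;
        R_xlen_t i = lin(z, y, x, nz, ny);
        if (!mask[i] && !outside[i]) { outside[i] = 1; q.push(i); }
      }
  while (!q.empty()) {
    R_xlen_t j = q.front(); q.pop();
    int x = (int)(j / ((R_xlen_t)nz * ny));
    int rem = (int)(j - (R_xlen_t)x * nz * ny);
    int y = rem / nz, z = rem % nz;
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k].dz, yy = y + off[k].dy, xx = x + off[k].dx;
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t m = lin(zz, yy, xx, nz, ny);
      if (!mask[m] && !outside[m]) { outside[m] = 1; q.push(m); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// Separable box-mean filter with edge clamping, one pass per axis.
// [[Rcpp::export]]
NumericVector cpp_box_filter(NumericVector vol, IntegerVector dim,
                             int radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const double w = 2 * radius + 1;
  // z axis
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double s = 0;
        for (int k = -radius; k <= radius; ++k) {
          int zz = std::min(std::max(z + k, 0), nz - 1);
          s += a[lin(zz, y, x, nz, ny)];
        }
        b[lin(z, y, x, nz, ny)] = s / w;
      }
  std::swap(a, b);
  // y axis
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double s = 0;
        for (int k = -radius; k <= radius; ++k) {
          int yy = std::min(std::max(y + k, 0), ny - 1);
          s += a[lin(z, yy, x, nz, ny)];
        }
        b[lin(z, y, x, nz, ny)] = s / w;
      }
  std::swap(a, b);
  // x axis
  NumericVector out(n);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double s = 0;
        for (int k = -radius; k <= radius; ++k) {
          int xx = std::min(std::max(x + k, 0), nx - 1);
          s += a[lin(z, y, xx, nz, ny)];
        }
        out[lin(z, y, x, nz, ny)] = s / w;
      }
  return out;
}
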