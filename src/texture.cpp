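#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Gray-level texture matrix builders. Input `levels` is a 3-D integer array
// (dim attribute set) holding quantized gray levels 1..ng inside the VOI and
// 0 outside; voxels outside the VOI never pair, never extend a run and never
// join a zone.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
IntegerMatrix cpp_glcm(IntegerVector levels, int ng, IntegerMatrix offsets) {
  IntegerVector dim = levels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerMatrix out(ng, ng);
  int nd = offsets.nrow();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        for (int d = 0; d < nd; ++d) {
          int x2 = x + offsets(d, 0), y2 = y + offsets(d, 1), z2 = z + offsets(d, 2);
          if (x2 < 0 || y2 < 0 || z2 < 0 || x2 >= nx || y2 >= ny || z2 >= nz) continue;
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (b == 0) continue;
          // count both (a,b) and (b,a): symmetric co-occurrence
          out(a - 1, b - 1)++;
          out(b - 1, a - 1)++;
        }
      }
  return out;
}

// Run-length counts for one direction; rows = gray level, cols = run length.
static std::vector<std::vector<double> > glrlm_one(const IntegerVector &levels,
                                                   int ng, int nx, int ny, int nz,
                                                   int dx, int dy, int dz) {
  std::vector<std::vector<double> > counts(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        // run starts here iff the previous voxel along -d is not the same level
        int xp = x - dx, yp = y - dy, zp = z - dz;
        if (xp >= 0 && yp >= 0 && zp >= 0 && xp < nx && yp < ny && zp < nz &&
            levels[idx3(xp, yp, zp, nx, ny)] == a)
          continue;
        int len = 1;
        int xc = x + dx, yc = y + dy, zc = z + dz;
        while (xc >= 0 && yc >= 0 && zc >= 0 && xc < nx && yc < ny && zc < nz &&
               levels[idx3(xc, yc, zc, nx, ny)] == a) {
          ++len;
          xc += dx; yc += dy; zc += dz;
        }
        if ((int)counts[a - 1].size() < len) counts[a - 1].resize(len, 0.0);
        counts[a - 1][len - 1] += 1.0;
      }
  return counts;
}

// [[Rcpp::export]]
List cpp_glrlm(IntegerVector levels, int ng, IntegerMatrix offsets) {
  IntegerVector dim = levels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nd = offsets.nrow();
  List out(nd);
  for (int d = 0; d < nd; ++d) {
    std::vector<std::vector<double> > c =
      glrlm_one(levels, ng, nx, ny, nz, offsets(d, 0), offsets(d, 1), offsets(d, 2));
    size_t rmax = 1;
    for (int i = 0; i < ng; ++i) rmax = std::max(rmax, c[i].size());
    NumericMatrix m(ng, (int)rmax);
    for (int i = 0; i < ng; ++i)
      for (size_t j = 0; j < c[i].size(); ++j) m(i, (int)j) = c[i][j];
    out[d] = m;
  }
  return out;
}

// Size-zone counts under 26-connectivity; rows = gray level, cols = zone size.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector levels, int ng) {
  IntegerVector dim = levels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::vector<double> > counts(ng);
  std::queue<int> q;
  for (int start = 0; start < n; ++start) {
    int a = levels[start];
    if (a == 0 || seen[start]) continue;
    int size = 0;
    seen[start] = 1;
    q.push(start);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (x2 < 0 || y2 < 0 || z2 < 0 || x2 >= nx || y2 >= ny || z2 >= nz) continue;
            int w = idx3(x2, y2, z2, nx, ny);
            if (!seen[w] && levels[w] == a) { seen[w] = 1; q.push(w); }
          }
    }
    if ((int)counts[a - 1].size() < size) counts[a - 1].resize(size, 0.0);
    counts[a - 1][size - 1] += 1.0;
  }
  size_t zmax = 1;
  for (int i = 0; i < ng; ++i) zmax = std::max(zmax, counts[i].size());
  NumericMatrix m(ng, (int)zmax);
  for (int i = 0; i < ng; ++i)
    for (size_t j = 0; j < counts[i].size(); ++j) m(i, (int)j) = counts[i][j];
  return m;
}

// Neighbourhood gray-tone differences restricted to in-mask 26-neighbours:
// s[i] accumulates |i - mean(neighbour levels)| over voxels of level i that
// have at least one in-mask neighbour; n[i] counts those voxels.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, int ng) {
  IntegerVector dim = levels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector s(ng), cnt(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0; int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || y2 < 0 || z2 < 0 || x2 >= nx || y2 >= ny || z2 >= nz) continue;
              int b = levels[idx3(x2, y2, z2, nx, ny)];
              if (b == 0) continue;
              sum += b; ++k;
            }
        if (k == 0) continue; // isolated voxel: no neighbourhood, excluded
        s[a - 1] += std::fabs((double)a - sum / k);
        cnt[a - 1] += 1.0;
      }
  return List::create(Named("s") = s, Named("n") = cnt);
}

// Separable Gaussian smoothing with reflected edges; kernel truncated at 3 sigma.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector x, double sigma) {
  IntegerVector dim = x.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if (sigma <= 0) return clone(x);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += kern[i + r];
  }
  for (double &k : kern) k /= ksum;
  NumericVector a = clone(x), b(x.size());
  b.attr("dim") = dim;
  int dims[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    int n = dims[axis];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int xx = 0; xx < nx; ++xx) {
          int pos = (axis == 0) ? xx : (axis == 1 ? y : z);
          double acc = 0.0;
          for (int i = -r; i <= r; ++i) {
            int p = pos + i;
            if (p < 0) p = -p - 1;           // reflect
            if (p >= n) p = 2 * n - p - 1;
            int xi = xx, yi = y, zi = z;
            if (axis == 0) xi = p; else if (axis == 1) yi = p; else zi = p;
            acc += kern[i + r] * a[idx3(xi, yi, zi, nx, ny)];
          }
          b[idx3(xx, y, z, nx, ny)] = acc;
        }
    std::copy(b.begin(), b.end(), a.begin());
  }
  a.attr("dim") = dim;
  return a;
}
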