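#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 26-neighbourhood offsets, generated once
static void neighbours26(std::vector<int>& dx, std::vector<int>& dy,
                         std::vector<int>& dz, std::vector<double>& w) {
  dx.clear(); dy.clear(); dz.clear(); w.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
        w.push_back(std::sqrt((double)(a * a + b * b + c * c)));
      }
}

// Label 26-connected components of a binary mask (column-major x,y,z array).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz; std::vector<double> w;
  neighbours26(dx, dy, dz, w);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (size_t k = 0; k < dx.size(); ++k) {
        int X = x + dx[k], Y = y + dy[k], Z = z + dz[k];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        R_xlen_t u = (R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X;
        if (mask[u] && lab[u] == 0) { lab[u] = next; q.push(u); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Seeded region growing with a running regional mean: a voxel joins the
// region if |intensity - running mean| <= tol and it is 26-adjacent to an
// accepted voxel. FIFO order makes the result deterministic.
// seeds: 0-based linear indices.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dims,
                              IntegerVector seeds, double tol) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector acc(n, false);
  std::vector<char> seen(n, 0);
  std::vector<int> dx, dy, dz; std::vector<double> w;
  neighbours26(dx, dy, dz, w);
  double seed_mean = 0.0;
  for (int i = 0; i < seeds.size(); ++i) seed_mean += vol[seeds[i]];
  seed_mean /= seeds.size();
  double sum = 0.0; R_xlen_t cnt = 0;
  std::queue<R_xlen_t> q;
  for (int i = 0; i < seeds.size(); ++i) {
    R_xlen_t s = seeds[i];
    if (seen[s]) continue;
    seen[s] = 1;
    if (std::fabs(vol[s] - seed_mean) <= tol) {
      acc[s] = true; sum += vol[s]; ++cnt; q.push(s);
    }
  }
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
    double mean = sum / cnt;
    for (size_t k = 0; k < dx.size(); ++k) {
      int X = x + dx[k], Y = y + dy[k], Z = z + dz[k];
      if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
      R_xlen_t u = (R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X;
      if (seen[u]) continue;
      seen[u] = 1;
      if (std::fabs(vol[u] - mean) <= tol) {
        acc[u] = true; sum += vol[u]; ++cnt; q.push(u);
      }
    }
  }
  return acc;
}

// Two-pass 26-neighbourhood chamfer distance transform: distance (mm) from
// each mask voxel to the nearest background voxel. Outside the array is not
// treated as background. h = voxel edge in mm.
// [[Rcpp::export]]
NumericVector cpp_chamfer_dt(LogicalVector mask, IntegerVector dims, double h) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  const double big = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? big : 0.0;
  const double w1 = h, w2 = h * std::sqrt(2.0), w3 = h * std::sqrt(3.0);
  // forward pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (d[v] == 0.0) continue;
        double best = d[v];
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              if (c > 0) continue;
              if (c == 0 && (b > 0 || (b == 0 && a >= 0))) continue;
              int X = x + a, Y = y + b, Z = z + c;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0) continue;
              R_xlen_t u = (R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X;
              int m = a * a + b * b + c * c;
              double wgt = (m == 1) ? w1 : (m == 2 ? w2 : w3);
              if (d[u] + wgt < best) best = d[u] + wgt;
            }
        d[v] = best;
      }
  // backward pass
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        R_xlen_t v = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (d[v] == 0.0) continue;
        double best = d[v];
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              if (c < 0) continue;
              if (c == 0 && (b < 0 || (b == 0 && a <= 0))) continue;
              int X = x + a, Y = y + b, Z = z + c;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z >= nz) continue;
              R_xlen_t u = (R_xlen_t)Z * nx * ny + (R_xlen_t)Y * nx + X;
              int m = a * a + b * b + c * c;
              double wgt = (m == 1) ? w1 : (m == 2 ? w2 : w3);
              if (d[u] + wgt < best) best = d[u] + wgt;
            }
        d[v] = best;
      }
  return d;
}
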