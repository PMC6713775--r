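#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static inline long idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long)ny * k);
}

// 13 unique 3D lattice directions at Chebyshev distance 1
static const int NDIR = 13;
static const int DIRS[NDIR][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};

// levels: integer grey levels 1..ng inside the ROI, 0 outside.
// Returns the average over directions of per-direction-normalised symmetric
// co-occurrence matrices (directions with no pairs are skipped).
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix acc(ng, ng);
  std::vector<double> mat((long)ng * ng);
  int used = 0;
  for (int d = 0; d < NDIR; ++d) {
    std::fill(mat.begin(), mat.end(), 0.0);
    double tot = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = levels[idx3(i, j, k, nx, ny)];
          if (a == 0) continue;
          int ii = i + DIRS[d][0], jj = j + DIRS[d][1], kk = k + DIRS[d][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          int b = levels[idx3(ii, jj, kk, nx, ny)];
          if (b == 0) continue;
          mat[(a - 1) + (long)ng * (b - 1)] += 1;   // symmetric: count both orders
          mat[(b - 1) + (long)ng * (a - 1)] += 1;
          tot += 2;
        }
    if (tot == 0) continue;
    ++used;
    for (int a = 0; a < ng; ++a)
      for (int b = 0; b < ng; ++b)
        acc(a, b) += mat[a + (long)ng * b] / tot;
  }
  if (used > 0)
    for (int a = 0; a < ng; ++a)
      for (int b = 0; b < ng; ++b) acc(a, b) /= used;
  return acc;
}

// Run-length matrix averaged (arithmetic mean of counts) over 13 directions.
// Columns = run length 1..max_len.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxdim = std::max(nx, std::max(ny, nz));
  int maxlen = maxdim;   // a run cannot exceed the longest grid edge... except diagonals: bounded by maxdim
  NumericMatrix acc(ng, maxlen);
  for (int d = 0; d < NDIR; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = levels[idx3(i, j, k, nx, ny)];
          if (a == 0) continue;
          // run starts here iff predecessor is outside grid/ROI or different level
          int pi = i - dx, pj = j - dy, pk = k - dz;
          if (pi >= 0 && pj >= 0 && pk >= 0 && pi < nx && pj < ny && pk < nz &&
              levels[idx3(pi, pj, pk, nx, ny)] == a)
            continue;
          int len = 1;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          while (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz &&
                 levels[idx3(ii, jj, kk, nx, ny)] == a) {
            ++len; ii += dx; jj += dy; kk += dz;
          }
          if (len > maxlen) len = maxlen;
          acc(a - 1, len - 1) += 1.0;
        }
  }
  for (int a = 0; a < ng; ++a)
    for (int l = 0; l < maxlen; ++l) acc(a, l) /= NDIR;
  return acc;
}

// Size-zone matrix: zones are 26-connected equal-level components.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int,long>> zones;   // (level, size)
  std::vector<long> stack;
  long maxsize = 1;
  for (long s = 0; s < n; ++s) {
    if (levels[s] == 0 || seen[s]) continue;
    int lev = levels[s];
    long size = 0;
    stack.clear(); stack.push_back(s); seen[s] = 1;
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      ++size;
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((long)nx * ny));
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int ii = i + dx, jj = j + dy, kk = k + dz;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            long w = idx3(ii, jj, kk, nx, ny);
            if (!seen[w] && levels[w] == lev) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zones.push_back({lev, size});
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix Z(ng, (int)maxsize);
  for (auto& z : zones) Z(z.first - 1, (int)z.second - 1) += 1.0;
  return Z;
}

// Neighbourhood grey tone difference matrix over the 26-neighbourhood.
// Returns ng x 2: column 0 = s_i (summed absolute differences from the
// neighbourhood mean), column 1 = n_i (number of contributing voxels).
// Voxels with no in-ROI neighbour do not contribute.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix M(ng, 2);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int a = levels[idx3(i, j, k, nx, ny)];
        if (a == 0) continue;
        double sum = 0; int cnt = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (!dx && !dy && !dz) continue;
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
              int b = levels[idx3(ii, jj, kk, nx, ny)];
              if (b == 0) continue;
              sum += b; ++cnt;
            }
        if (cnt == 0) continue;
        M(a - 1, 0) += std::fabs(a - sum / cnt);
        M(a - 1, 1) += 1;
      }
  return M;
}
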