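#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Hilditch crossing number of the 8-neighbourhood p (clockwise from north);
// == 1 iff the pixel is 8-simple (deletable without changing topology).
static inline int crossing_number(const int p[8]) {
  int b[10];
  for (int k = 0; k < 8; ++k) b[k] = 1 - p[k];
  b[8] = b[0]; b[9] = b[1];
  int X = 0;
  for (int k = 0; k < 4; ++k)
    X += b[2 * k] - b[2 * k] * b[2 * k + 1] * b[2 * k + 2];
  return X;
}

// Guo-Hall two-subiteration parallel thinning of a 2D binary image.
// Chosen over Zhang-Suen, whose parallel deletions can erase 2-pixel-wide
// diagonal strokes (and 2x2 blocks) entirely. Returns an 8-connected
// unit-width skeleton; idempotent on its own output.
// [[Rcpp::export(name = ".thin2d_cpp")]]
LogicalMatrix thin2d_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> img(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[i + (size_t)j * nr] = mask(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> int {
    if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
    return img[i + (size_t)j * nr];
  };

  bool changed = true;
  std::vector<std::pair<int,int> > kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[i + (size_t)j * nr]) continue;
          int p2 = at(i-1,j), p3 = at(i-1,j+1), p4 = at(i,j+1),
              p5 = at(i+1,j+1), p6 = at(i+1,j), p7 = at(i+1,j-1),
              p8 = at(i,j-1), p9 = at(i-1,j-1);
          int C = ((!p2 && (p3 || p4)) ? 1 : 0) +
                  ((!p4 && (p5 || p6)) ? 1 : 0) +
                  ((!p6 && (p7 || p8)) ? 1 : 0) +
                  ((!p8 && (p9 || p2)) ? 1 : 0);
          int N1 = ((p9 || p2) ? 1 : 0) + ((p3 || p4) ? 1 : 0) +
                   ((p5 || p6) ? 1 : 0) + ((p7 || p8) ? 1 : 0);
          int N2 = ((p2 || p3) ? 1 : 0) + ((p4 || p5) ? 1 : 0) +
                   ((p6 || p7) ? 1 : 0) + ((p8 || p9) ? 1 : 0);
          int N = N1 < N2 ? N1 : N2;
          int m = step == 0 ? ((p6 || p7 || !p9) && p8)
                            : ((p2 || p3 || !p5) && p4);
          if (C == 1 && N >= 2 && N <= 3 && !m)
            kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        img[kill[k].first + (size_t)kill[k].second * nr] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[i + (size_t)j * nr] != 0;
  return out;
}

// Sequential removal of redundant (8-simple, non-endpoint) pixels left by
// parallel thinning -- staircase corners whose removal preserves topology.
// Simplicity via the Hilditch crossing number (== 1 for deletable pixels).
// [[Rcpp::export(name = ".thin_cleanup_cpp")]]
LogicalMatrix thin_cleanup_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> img(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[i + (size_t)j * nr] = mask(i, j) ? 1 : 0;
  auto at = [&](int i, int j) -> int {
    if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
    return img[i + (size_t)j * nr];
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!img[i + (size_t)j * nr]) continue;
        // clockwise from north: p[0..7] = N, NE, E, SE, S, SW, W, NW
        int p[8] = { at(i-1,j), at(i-1,j+1), at(i,j+1), at(i+1,j+1),
                     at(i+1,j), at(i+1,j-1), at(i,j-1), at(i-1,j-1) };
        int B = 0;
        for (int k = 0; k < 8; ++k) B += p[k];
        if (B < 2) continue;  // endpoints and isolated pixels stay
        int b[10];
        for (int k = 0; k < 8; ++k) b[k] = 1 - p[k];
        b[8] = b[0]; b[9] = b[1];
        int X = 0;
        for (int k = 0; k < 4; ++k)
          X += b[2 * k] - b[2 * k] * b[2 * k + 1] * b[2 * k + 2];
        if (X == 1) {
          img[i + (size_t)j * nr] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[i + (size_t)j * nr] != 0;
  return out;
}

// Connected-component labelling of a 2D binary image, connectivity 4 or 8.
// Labels assigned in column-major scan order of the first pixel reached.
// [[Rcpp::export(name = ".label2d_cpp")]]
IntegerMatrix label2d_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dx4[4] = {-1, 1, 0, 0}, dy4[4] = {0, 0, -1, 1};
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1}, dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dx = connectivity == 4 ? dx4 : dx8;
  const int *dy = connectivity == 4 ? dy4 : dy8;
  int nd = connectivity == 4 ? 4 : 8, next = 0;
  std::queue<std::pair<int,int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> c = q.front(); q.pop();
        for (int k = 0; k < nd; ++k) {
          int ni = c.first + dx[k], nj = c.second + dy[k];
          if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            q.push(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  return lab;
}

static inline int idx3(int i, int j, int k, int nr, int nc) {
  return i + nr * (j + nc * k);
}

// Count 26-connected foreground components within the 3x3x3 neighbourhood
// (centre excluded) -- T26 of the Malandain-Bertrand simple-point test.
static int t26(const std::vector<int>& nb) {
  // nb: 27 values, centre index 13 ignored
  int comp = 0;
  std::vector<int> seen(27, 0);
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comp;
    std::queue<int> q; q.push(s); seen[s] = 1;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int ci = c % 3, cj = (c / 3) % 3, ck = c / 9;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj, nk = ck + dk;
            if (ni < 0 || nj < 0 || nk < 0 || ni > 2 || nj > 2 || nk > 2) continue;
            int s2 = ni + 3 * nj + 9 * nk;
            if (s2 == 13 || !nb[s2] || seen[s2]) continue;
            seen[s2] = 1; q.push(s2);
          }
    }
  }
  return comp;
}

// T6: 6-connected background components in N18 that are 6-adjacent to centre.
static int t6(const std::vector<int>& nb) {
  // restrict to the 18-neighbourhood (exclude the 8 corners and centre)
  auto in18 = [](int s) {
    int i = s % 3 - 1, j = (s / 3) % 3 - 1, k = s / 9 - 1;
    int a = std::abs(i) + std::abs(j) + std::abs(k);
    return a >= 1 && a <= 2;
  };
  std::vector<int> seen(27, 0);
  int comp = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18(s) || nb[s] || seen[s]) continue;
    // seed only from 6-neighbours of the centre
    int i = s % 3 - 1, j = (s / 3) % 3 - 1, k = s / 9 - 1;
    if (std::abs(i) + std::abs(j) + std::abs(k) != 1) continue;
    ++comp;
    std::queue<int> q; q.push(s); seen[s] = 1;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int ci = c % 3 - 1, cj = (c / 3) % 3 - 1, ck = c / 9 - 1;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int t = 0; t < 6; ++t) {
        int ni = ci + d6[t][0], nj = cj + d6[t][1], nk = ck + d6[t][2];
        if (ni < -1 || nj < -1 || nk < -1 || ni > 1 || nj > 1 || nk > 1) continue;
        int s2 = (ni + 1) + 3 * (nj + 1) + 9 * (nk + 1);
        if (!in18(s2) || nb[s2] || seen[s2]) continue;
        seen[s2] = 1; q.push(s2);
      }
    }
  }
  return comp;
}

// Sequential 3D thinning by simple-point removal (26-connectivity foreground,
// 6-connectivity background); voxels with <=1 foreground 26-neighbour are
// preserved as curve endpoints. Deterministic scan order.
// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector vol, IntegerVector dims) {
  int nr = dims[0], nc = dims[1], nz = dims[2];
  std::vector<int> img(vol.size());
  for (R_xlen_t s = 0; s < vol.size(); ++s) img[s] = vol[s] ? 1 : 0;
  auto at = [&](int i, int j, int k) -> int {
    if (i < 0 || j < 0 || k < 0 || i >= nr || j >= nc || k >= nz) return 0;
    return img[idx3(i, j, k, nr, nc)];
  };
  bool changed = true;
  std::vector<int> nb(27);
  while (changed) {
    changed = false;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!img[idx3(i, j, k, nr, nc)]) continue;
          int n26 = 0, border = 0;
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                int v = at(i + di, j + dj, k + dk);
                nb[(di + 1) + 3 * (dj + 1) + 9 * (dk + 1)] = v;
                if (di || dj || dk) n26 += v;
              }
          if (!at(i-1,j,k) || !at(i+1,j,k) || !at(i,j-1,k) ||
              !at(i,j+1,k) || !at(i,j,k-1) || !at(i,j,k+1)) border = 1;
          if (!border || n26 <= 1) continue;
          if (t26(nb) == 1 && t6(nb) == 1) {
            img[idx3(i, j, k, nr, nc)] = 0;
            changed = true;
          }
        }
  }
  LogicalVector out(vol.size());
  for (R_xlen_t s = 0; s < vol.size(); ++s) out[s] = img[s] != 0;
  out.attr("dim") = dims;
  return out;
}
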