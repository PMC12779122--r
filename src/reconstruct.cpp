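#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation (8-connected),
// Vincent's fast-hybrid algorithm: one forward raster scan, one backward
// scan that seeds a FIFO queue, then queue-driven propagation.
// marker must satisfy marker <= mask element-wise; both are row-major R
// matrices (column-major storage, indexed [i + j*nr]).

static inline double max_plus_fwd(const NumericVector &m, int i, int j,
                                  int nr, int nc) {
  double v = m[i + j * nr];
  if (i > 0)            v = std::max(v, m[(i - 1) + j * nr]);
  if (j > 0)            v = std::max(v, m[i + (j - 1) * nr]);
  if (i > 0 && j > 0)   v = std::max(v, m[(i - 1) + (j - 1) * nr]);
  if (i < nr - 1 && j > 0) v = std::max(v, m[(i + 1) + (j - 1) * nr]);
  return v;
}

static inline double max_plus_bwd(const NumericVector &m, int i, int j,
                                  int nr, int nc) {
  double v = m[i + j * nr];
  if (i < nr - 1)            v = std::max(v, m[(i + 1) + j * nr]);
  if (j < nc - 1)            v = std::max(v, m[i + (j + 1) * nr]);
  if (i < nr - 1 && j < nc - 1) v = std::max(v, m[(i + 1) + (j + 1) * nr]);
  if (i > 0 && j < nc - 1)   v = std::max(v, m[(i - 1) + (j + 1) * nr]);
  return v;
}

// [[Rcpp::export(name = ".reconstruct_dilation")]]
NumericMatrix reconstruct_dilation(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericVector m = clone(NumericVector(marker));
  NumericVector g(mask);
  for (int k = 0; k < nr * nc; ++k)
    if (m[k] > g[k]) stop("marker exceeds mask");

  // forward raster scan
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      m[i + j * nr] = std::min(max_plus_fwd(m, i, j, nr, nc), g[i + j * nr]);

  // backward raster scan + queue seeding
  std::queue<int> fifo;
  for (int j = nc - 1; j >= 0; --j)
    for (int i = nr - 1; i >= 0; --i) {
      int p = i + j * nr;
      m[p] = std::min(max_plus_bwd(m, i, j, nr, nc), g[p]);
      // seed if some backward-neighbour could still grow
      const int di[4] = {1, 0, 1, -1};
      const int dj[4] = {0, 1, 1, 1};
      for (int t = 0; t < 4; ++t) {
        int ii = i + di[t], jj = j + dj[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int q = ii + jj * nr;
        if (m[q] < m[p] && m[q] < g[q]) { fifo.push(p); break; }
      }
    }

  // propagation
  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int i = p % nr, j = p / nr;
    for (int t = 0; t < 8; ++t) {
      int ii = i + di8[t], jj = j + dj8[t];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int q = ii + jj * nr;
      if (m[q] < m[p] && g[q] != m[q]) {
        m[q] = std::min(m[p], g[q]);
        fifo.push(q);
      }
    }
  }

  NumericMatrix out(nr, nc);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
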