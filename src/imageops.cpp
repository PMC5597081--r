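// Low-level image primitives shared by the 2D/3D quantification modules.
// All matrices are R column-major; coordinates elsewhere in the package are
// 0-based (row, col).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Two-pass union-find connected-component labelling of a logical matrix.
// conn = 4 or 8.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".cpp_label2d")]]
IntegerMatrix cpp_label2d(const LogicalMatrix& mask, int conn = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      int neigh[4][2] = {{i - 1, j}, {i, j - 1}, {i - 1, j - 1}, {i + 1, j - 1}};
      int nn = (conn == 8) ? 4 : 2;
      std::vector<int> seen;
      for (int k = 0; k < nn; ++k) {
        int ii = neigh[k][0], jj = neigh[k][1];
        if (ii < 0 || jj < 0 || ii >= nr) continue;
        int l = lab(ii, jj);
        if (l > 0) {
          seen.push_back(l);
          if (best == 0 || l < best) best = l;
        }
      }
      if (best == 0) {
        lab(i, j) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(i, j) = best;
        for (size_t k = 0; k < seen.size(); ++k) uf_union(parent, best, seen[k]);
      }
    }
  }
  // relabel consecutively
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int l = 1; l < next; ++l) {
    int r = uf_find(parent, l);
    if (remap[r] == 0) remap[r] = ++out;
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) lab(i, j) = remap[uf_find(parent, lab(i, j))];
  return lab;
}

// 3D labelling on a flattened array with dims (nr, nc, nz); conn = 6 or 26.
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(const LogicalVector& mask, int nr, int nc, int nz,
                          int conn = 26) {
  IntegerVector lab(mask.size(), 0);
  std::vector<int> parent(1, 0);
  int next = 1;
  auto idx = [&](int i, int j, int k) { return i + nr * (j + nc * k); };
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!mask[idx(i, j, k)]) continue;
        int best = 0;
        std::vector<int> seen;
        // neighbours already visited in scan order (dk,dj,di lexicographic <0)
        for (int dk = -1; dk <= 0; ++dk) {
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
              if (conn == 6 && (std::abs(di) + std::abs(dj) + std::abs(dk)) != 1)
                continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nr || jj >= nc) continue;
              int l = lab[idx(ii, jj, kk)];
              if (l > 0) {
                seen.push_back(l);
                if (best == 0 || l < best) best = l;
              }
            }
          }
        }
        if (best == 0) {
          lab[idx(i, j, k)] = next;
          parent.push_back(next);
          ++next;
        } else {
          lab[idx(i, j, k)] = best;
          for (size_t s = 0; s < seen.size(); ++s) uf_union(parent, best, seen[s]);
        }
      }
    }
  }
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int l = 1; l < next; ++l) {
    int r = uf_find(parent, l);
    if (remap[r] == 0) remap[r] = ++out;
  }
  for (R_xlen_t p = 0; p < lab.size(); ++p)
    if (lab[p] > 0) lab[p] = remap[uf_find(parent, lab[p])];
  return lab;
}

// 3-4 chamfer distance transform: distance (in ~pixels, /3) from each TRUE
// pixel to the nearest FALSE pixel.
// [[Rcpp::export(name = ".cpp_chamfer")]]
NumericMatrix cpp_chamfer(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e15;
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) d(i, j) = mask(i, j) ? BIG : 0.0;
  // forward pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i > 0) v = std::min(v, d(i - 1, j) + 3.0);
      if (j > 0) v = std::min(v, d(i, j - 1) + 3.0);
      if (i > 0 && j > 0) v = std::min(v, d(i - 1, j - 1) + 4.0);
      if (i < nr - 1 && j > 0) v = std::min(v, d(i + 1, j - 1) + 4.0);
      d(i, j) = v;
    }
  }
  // backward pass
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i < nr - 1) v = std::min(v, d(i + 1, j) + 3.0);
      if (j < nc - 1) v = std::min(v, d(i, j + 1) + 3.0);
      if (i < nr - 1 && j < nc - 1) v = std::min(v, d(i + 1, j + 1) + 4.0);
      if (i > 0 && j < nc - 1) v = std::min(v, d(i - 1, j + 1) + 4.0);
      d(i, j) = v;
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) d(i, j) /= 3.0;
  return d;
}

// Marker-based watershed by priority flooding of an elevation map restricted
// to `mask`.  Lower elevation floods first (pass -distance to split blobs at
// distance maxima).  Markers: integer matrix, 0 = unlabelled.
struct QNode {
  double elev;
  long order;
  int i, j, lab;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;                      // FIFO tie-break
  }
};

// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerMatrix cpp_watershed(const NumericMatrix& elev, const LogicalMatrix& mask,
                            const IntegerMatrix& markers) {
  const int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  long order = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        pq.push(QNode{elev(i, j), order++, i, j, markers(i, j)});
      }
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    QNode n = pq.top();
    pq.pop();
    for (int k = 0; k < 8; ++k) {
      int ii = n.i + di[k], jj = n.j + dj[k];
      if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
      if (!mask(ii, jj) || lab(ii, jj) > 0) continue;
      lab(ii, jj) = n.lab;
      pq.push(QNode{std::max(elev(ii, jj), n.elev), order++, ii, jj, n.lab});
    }
  }
  return lab;
}

// Multi-source BFS label propagation: every TRUE pixel of `mask` gets the
// label of the geodesically nearest seed (seeded cell identification).
// [[Rcpp::export(name = ".cpp_propagate")]]
IntegerMatrix cpp_propagate(const IntegerMatrix& seeds, const LogicalMatrix& mask) {
  const int nr = seeds.nrow(), nc = seeds.ncol();
  IntegerMatrix lab(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0) {
        lab(i, j) = seeds(i, j);
        q.push(std::make_pair(i, j));
      }
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int k = 0; k < 8; ++k) {
      int ii = p.first + di[k], jj = p.second + dj[k];
      if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
      if (!mask(ii, jj) || lab(ii, jj) > 0) continue;
      lab(ii, jj) = lab(p.first, p.second);
      q.push(std::make_pair(ii, jj));
    }
  }
  return lab;
}

// Exact median of a win x win window (clamped at borders) evaluated on a
// regular grid of points; the R side interpolates back to full resolution.
// [[Rcpp::export(name = ".cpp_grid_median")]]
NumericMatrix cpp_grid_median(const NumericMatrix& img, int halfwin,
                              const IntegerVector& grid_i,
                              const IntegerVector& grid_j) {
  const int nr = img.nrow(), nc = img.ncol();
  const int gi = grid_i.size(), gj = grid_j.size();
  NumericMatrix out(gi, gj);
  std::vector<double> buf;
  buf.reserve((2 * halfwin + 1) * (size_t)(2 * halfwin + 1));
  for (int b = 0; b < gj; ++b) {
    int jc = grid_j[b];
    int j0 = std::max(0, jc - halfwin), j1 = std::min(nc - 1, jc + halfwin);
    for (int a = 0; a < gi; ++a) {
      int ic = grid_i[a];
      int i0 = std::max(0, ic - halfwin), i1 = std::min(nr - 1, ic + halfwin);
      buf.clear();
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) buf.push_back(img(i, j));
      size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (buf.size() % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m);
        med = 0.5 * (med + lo);
      }
      out(a, b) = med;
    }
  }
  return out;
}

// Median of the window pixels at or below `cutoff` (median of all pixels if
// none qualify): a robust background estimator for illumination correction
// when bright objects cover a large image fraction.
// [[Rcpp::export(name = ".cpp_grid_masked_median")]]
NumericMatrix cpp_grid_masked_median(const NumericMatrix& img, int halfwin,
                                     const IntegerVector& grid_i,
                                     const IntegerVector& grid_j,
                                     double cutoff) {
  const int nr = img.nrow(), nc = img.ncol();
  const int gi = grid_i.size(), gj = grid_j.size();
  NumericMatrix out(gi, gj);
  std::vector<double> buf;
  for (int b = 0; b < gj; ++b) {
    int jc = grid_j[b];
    int j0 = std::max(0, jc - halfwin), j1 = std::min(nc - 1, jc + halfwin);
    for (int a = 0; a < gi; ++a) {
      int ic = grid_i[a];
      int i0 = std::max(0, ic - halfwin), i1 = std::min(nr - 1, ic + halfwin);
      buf.clear();
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          if (img(i, j) <= cutoff) buf.push_back(img(i, j));
      if (buf.empty())
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) buf.push_back(img(i, j));
      size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (buf.size() % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m);
        med = 0.5 * (med + lo);
      }
      out(a, b) = med;
    }
  }
  return out;
}

// Square maximum filter (radius r, chebyshev) used for distance-map peaks.
// [[Rcpp::export(name = ".cpp_maxfilter")]]
NumericMatrix cpp_maxfilter(const NumericMatrix& img, int r) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // horizontal then vertical pass (separable for square footprint)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = img(i, j);
      for (int k = std::max(0, i - r); k <= std::min(nr - 1, i + r); ++k)
        m = std::max(m, img(k, j));
      tmp(i, j) = m;
    }
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = tmp(i, j);
      for (int k = std::max(0, j - r); k <= std::min(nc - 1, j + r); ++k)
        m = std::max(m, tmp(i, k));
      out(i, j) = m;
    }
  }
  return out;
}
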