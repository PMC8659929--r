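#include <Rcpp.h>
#include <queue>
#include <limits>
using namespace Rcpp;

// Flat (binary footprint) grayscale erosion/dilation.
//
// Border convention: out-of-image samples are ignored, which is equivalent
// to padding with +Inf for erosion and -Inf for dilation, so openings and
// closings do not invent border artifacts.
//
// `fp` is a logical footprint matrix with odd dimensions; its center is the
// origin. Dilation uses the reflected footprint (for the symmetric shapes
// used here the reflection is the identity, but the code does not rely on
// that).

static inline void footprint_offsets(const LogicalMatrix& fp,
                                     std::vector<int>& dr,
                                     std::vector<int>& dc,
                                     bool reflect) {
  int cr = (fp.nrow() - 1) / 2, cc = (fp.ncol() - 1) / 2;
  for (int j = 0; j < fp.ncol(); ++j)
    for (int i = 0; i < fp.nrow(); ++i)
      if (fp(i, j)) {
        int a = i - cr, b = j - cc;
        if (reflect) { a = -a; b = -b; }
        dr.push_back(a);
        dc.push_back(b);
      }
}

// [[Rcpp::export(name = ".erode_cpp")]]
NumericMatrix erode_cpp(NumericMatrix f, LogicalMatrix fp) {
  std::vector<int> dr, dc;
  footprint_offsets(fp, dr, dc, false);
  int nr = f.nrow(), nc = f.ncol(), K = dr.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        int rr = r + dr[k], cc2 = c + dc[k];
        if (rr >= 0 && rr < nr && cc2 >= 0 && cc2 < nc) {
          double v = f(rr, cc2);
          if (v < m) m = v;
        }
      }
      out(r, c) = m;
    }
  return out;
}

// [[Rcpp::export(name = ".dilate_cpp")]]
NumericMatrix dilate_cpp(NumericMatrix f, LogicalMatrix fp) {
  std::vector<int> dr, dc;
  footprint_offsets(fp, dr, dc, true);
  int nr = f.nrow(), nc = f.ncol(), K = dr.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        int rr = r + dr[k], cc2 = c + dc[k];
        if (rr >= 0 && rr < nr && cc2 >= 0 && cc2 < nc) {
          double v = f(rr, cc2);
          if (v > m) m = v;
        }
      }
      out(r, c) = m;
    }
  return out;
}

// Grayscale morphological reconstruction by geodesic dilation,
// 8-connectivity, computed to the exact fixed point with Vincent's hybrid
// algorithm (one forward raster sweep, one backward sweep, then FIFO
// propagation). marker must satisfy marker <= mask (enforced in R).
// [[Rcpp::export(name = ".reconstruct_cpp")]]
NumericMatrix reconstruct_cpp(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J = clone(marker);

  // 8-neighbourhood split consistent with the column-major sweeps:
  // N+ holds the neighbours already visited in the forward sweep,
  // N- those already visited in the backward sweep
  const int nplus_r[4] = {-1, 1, 0, -1};
  const int nplus_c[4] = {-1, -1, -1, 0};
  const int nminus_r[4] = {1, -1, 0, 1};
  const int nminus_c[4] = {1, 1, 1, 0};

  // forward sweep in column-major raster order (R storage order)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + nplus_r[k], cc = c + nplus_c[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > m)
          m = J(rr, cc);
      }
      J(r, c) = std::min(m, mask(r, c));
    }

  std::queue<std::pair<int, int> > fifo;
  // backward sweep + queue seeding
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      double m = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + nminus_r[k], cc = c + nminus_c[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > m)
          m = J(rr, cc);
      }
      J(r, c) = std::min(m, mask(r, c));
      for (int k = 0; k < 4; ++k) {
        int rr = r + nminus_r[k], cc = c + nminus_c[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
            J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(std::make_pair(r, c));
          break;
        }
      }
    }

  const int all_r[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int all_c[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    std::pair<int, int> p = fifo.front();
    fifo.pop();
    int r = p.first, c = p.second;
    for (int k = 0; k < 8; ++k) {
      int rr = r + all_r[k], cc = c + all_c[k];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) {
        if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
          J(rr, cc) = std::min(J(r, c), mask(rr, cc));
          fifo.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return J;
}
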