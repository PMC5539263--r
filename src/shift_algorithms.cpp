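#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// A pixel pair matches only when both carry a real gray level (>= 0) and the
// levels are equal. Negative values are monochrome-mask sentinels and never
// match anything, including themselves.
static inline bool px_match(int a, int b) { return a == b && a >= 0; }

// Overlay semantics: the comparison window is min(rows) x min(cols), the
// shift space max(rows) x max(cols). In each dimension the larger image (the
// first one on ties) is indexed cyclically by the shift, the other directly:
// at shift d, window position i pairs wrapped[(i + d) mod n] with direct[i].
// So for equal sizes a shift by one row pairs the first row of the first
// image with the last row of the second, and a cropped detail of a larger
// image is superimposed on its source exactly at the crop-origin shift,
// whichever argument order is used.
struct Geom {
  int mw, nw;          // comparison window
  int M, N;            // shift space
  bool wrapA_r, wrapA_c;  // does A (vs B) wrap in rows / cols
  int wr, wc;          // extent of the wrapped image per dimension
};

static Geom geometry(const IntegerMatrix& A, const IntegerMatrix& B) {
  Geom g;
  g.mw = std::min(A.nrow(), B.nrow());
  g.nw = std::min(A.ncol(), B.ncol());
  g.M  = std::max(A.nrow(), B.nrow());
  g.N  = std::max(A.ncol(), B.ncol());
  g.wrapA_r = A.nrow() >= B.nrow();
  g.wrapA_c = A.ncol() >= B.ncol();
  g.wr = g.wrapA_r ? A.nrow() : B.nrow();
  g.wc = g.wrapA_c ? A.ncol() : B.ncol();
  return g;
}

// Paired index maps for one shift component: ia / ib are the row (or column)
// indices of A and B at window positions 0..n-1.
static void index_maps(int n, int d, bool wrapA, int wrapped_extent,
                       std::vector<int>& ia, std::vector<int>& ib) {
  int w = d % wrapped_extent;
  for (int i = 0; i < n; ++i) {
    ia[i] = wrapA ? w : i;
    ib[i] = wrapA ? i : w;
    if (++w == wrapped_extent) w = 0;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_pixelwise_grid(IntegerMatrix A, IntegerMatrix B) {
  Geom g = geometry(A, B);
  IntegerMatrix out(g.M, g.N);
  std::vector<int> ar(g.mw), br(g.mw), ac(g.nw), bc(g.nw);
  for (int dj = 0; dj < g.N; ++dj) {
    index_maps(g.nw, dj, g.wrapA_c, g.wc, ac, bc);
    for (int di = 0; di < g.M; ++di) {
      index_maps(g.mw, di, g.wrapA_r, g.wr, ar, br);
      int cnt = 0;
      for (int j = 0; j < g.nw; ++j)
        for (int i = 0; i < g.mw; ++i)
          if (px_match(A(ar[i], ac[j]), B(br[i], bc[j]))) ++cnt;
      out(di, dj) = cnt;
    }
  }
  return out;
}

// Fill eq[i + j*mw] with the pixel-match indicator of one shift.
static void overlay_eq(const IntegerMatrix& A, const IntegerMatrix& B,
                       const Geom& g,
                       const std::vector<int>& ar, const std::vector<int>& br,
                       const std::vector<int>& ac, const std::vector<int>& bc,
                       std::vector<unsigned char>& eq) {
  for (int j = 0; j < g.nw; ++j) {
    unsigned char* col = &eq[(size_t)j * g.mw];
    for (int i = 0; i < g.mw; ++i)
      col[i] = px_match(A(ar[i], ac[j]), B(br[i], bc[j])) ? 1 : 0;
  }
}

// Count anchors whose full 3x3 block matches; optionally accumulate the
// anchor positions into loc (localization matrix over the window).
static int count_nn(const std::vector<unsigned char>& eq, const Geom& g,
                    IntegerMatrix* loc) {
  int cnt = 0;
  for (int j = 0; j + 2 < g.nw; ++j) {
    const unsigned char* c0 = &eq[(size_t)j * g.mw];
    const unsigned char* c1 = c0 + g.mw;
    const unsigned char* c2 = c1 + g.mw;
    for (int i = 0; i + 2 < g.mw; ++i) {
      if (c0[i] && c0[i + 1] && c0[i + 2] &&
          c1[i] && c1[i + 1] && c1[i + 2] &&
          c2[i] && c2[i + 1] && c2[i + 2]) {
        ++cnt;
        if (loc) (*loc)(i, j) += 1;
      }
    }
  }
  return cnt;
}

// [[Rcpp::export]]
IntegerMatrix cpp_nn_grid(IntegerMatrix A, IntegerMatrix B) {
  Geom g = geometry(A, B);
  if (g.mw < 3 || g.nw < 3)
    stop("comparison window must be at least 3x3 for the nearest-neighbor algorithm");
  IntegerMatrix out(g.M, g.N);
  std::vector<int> ar(g.mw), br(g.mw), ac(g.nw), bc(g.nw);
  std::vector<unsigned char> eq((size_t)g.mw * g.nw);
  for (int dj = 0; dj < g.N; ++dj) {
    index_maps(g.nw, dj, g.wrapA_c, g.wc, ac, bc);
    for (int di = 0; di < g.M; ++di) {
      index_maps(g.mw, di, g.wrapA_r, g.wr, ar, br);
      overlay_eq(A, B, g, ar, br, ac, bc, eq);
      out(di, dj) = count_nn(eq, g, nullptr);
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_localization_nn(IntegerMatrix A, IntegerMatrix B) {
  Geom g = geometry(A, B);
  if (g.mw < 3 || g.nw < 3)
    stop("comparison window must be at least 3x3 for the nearest-neighbor algorithm");
  IntegerMatrix loc(g.mw, g.nw);
  std::vector<int> ar(g.mw), br(g.mw), ac(g.nw), bc(g.nw);
  std::vector<unsigned char> eq((size_t)g.mw * g.nw);
  for (int dj = 0; dj < g.N; ++dj) {
    index_maps(g.nw, dj, g.wrapA_c, g.wc, ac, bc);
    for (int di = 0; di < g.M; ++di) {
      index_maps(g.mw, di, g.wrapA_r, g.wr, ar, br);
      overlay_eq(A, B, g, ar, br, ac, bc, eq);
      count_nn(eq, g, &loc);
    }
  }
  return loc;
}

// Per-shift difference image (A minus overlaid B) into d.
static void overlay_diff(const IntegerMatrix& A, const IntegerMatrix& B,
                         const Geom& g,
                         const std::vector<int>& ar, const std::vector<int>& br,
                         const std::vector<int>& ac, const std::vector<int>& bc,
                         std::vector<double>& d) {
  for (int j = 0; j < g.nw; ++j) {
    double* col = &d[(size_t)j * g.mw];
    for (int i = 0; i < g.mw; ++i)
      col[i] = (double)A(ar[i], ac[j]) - (double)B(br[i], bc[j]);
  }
}

// Anchor k (0-based) is admissible at shift component d iff the wrapped
// image's three indices (k+d .. k+d+2) mod wrapped_extent are consecutive,
// i.e. the 3x3 block does not cross the cyclic seam. The directly indexed
// image's blocks are contiguous automatically (the window never exceeds it).
// Seam-crossing blocks juxtapose opposite image edges -- their variance is
// noise -- and skipping them makes the variance statistic exactly symmetric
// under mirroring a shift.
static void valid_anchors(int n_anchor, int d, int wrapped_extent,
                          std::vector<unsigned char>& valid) {
  for (int k = 0; k < n_anchor; ++k)
    valid[k] = ((k + d) % wrapped_extent) <= wrapped_extent - 3 ? 1 : 0;
}

// Population variance of the nine differences in each admissible 3x3 block,
// via column-triple running sums of d and d^2. If loc/cut are given, anchors
// with variance < cut are counted into loc.
static double var_pass(const std::vector<double>& d, const Geom& g,
                       const std::vector<unsigned char>& valid_r,
                       const std::vector<unsigned char>& valid_c,
                       IntegerMatrix* loc, double cut,
                       std::vector<double>& s1, std::vector<double>& s2) {
  const int mr = g.mw - 2;  // anchor rows
  for (int j = 0; j < g.nw; ++j) {
    const double* col = &d[(size_t)j * g.mw];
    double* t1 = &s1[(size_t)j * mr];
    double* t2 = &s2[(size_t)j * mr];
    for (int i = 0; i < mr; ++i) {
      double a = col[i], b = col[i + 1], c = col[i + 2];
      t1[i] = a + b + c;
      t2[i] = a * a + b * b + c * c;
    }
  }
  double total = 0.0;
  for (int j = 0; j + 2 < g.nw; ++j) {
    if (!valid_c[j]) continue;
    const double* u1 = &s1[(size_t)j * mr];
    const double* v1 = u1 + mr;
    const double* w1 = v1 + mr;
    const double* u2 = &s2[(size_t)j * mr];
    const double* v2 = u2 + mr;
    const double* w2 = v2 + mr;
    for (int i = 0; i < mr; ++i) {
      if (!valid_r[i]) continue;
      double sum = u1[i] + v1[i] + w1[i];
      double sumsq = u2[i] + v2[i] + w2[i];
      double mean = sum / 9.0;
      double var = sumsq / 9.0 - mean * mean;
      if (var < 0) var = 0;  // guard against rounding
      total += var;
      if (loc && var < cut) (*loc)(i, j) += 1;
    }
  }
  return total;
}

static void check_no_sentinel(const IntegerMatrix& X, const char* who) {
  for (R_xlen_t k = 0; k < X.size(); ++k)
    if (X[k] < 0)
      stop("%s: masked (sentinel) pixels present; the variance algorithm does not "
           "work for images with monochrome areas - use the pixel-wise or "
           "nearest-neighbor algorithm instead", who);
}

// [[Rcpp::export]]
NumericMatrix cpp_variance_grid(IntegerMatrix A, IntegerMatrix B) {
  Geom g = geometry(A, B);
  if (g.mw < 3 || g.nw < 3)
    stop("comparison window must be at least 3x3 for the variance algorithm");
  check_no_sentinel(A, "variance_shift_sums");
  check_no_sentinel(B, "variance_shift_sums");
  NumericMatrix out(g.M, g.N);
  std::vector<int> ar(g.mw), br(g.mw), ac(g.nw), bc(g.nw);
  std::vector<double> d((size_t)g.mw * g.nw);
  std::vector<double> s1((size_t)(g.mw - 2) * g.nw), s2((size_t)(g.mw - 2) * g.nw);
  std::vector<unsigned char> vr(g.mw - 2), vc(g.nw - 2);
  for (int dj = 0; dj < g.N; ++dj) {
    index_maps(g.nw, dj, g.wrapA_c, g.wc, ac, bc);
    valid_anchors(g.nw - 2, dj, g.wc, vc);
    for (int di = 0; di < g.M; ++di) {
      index_maps(g.mw, di, g.wrapA_r, g.wr, ar, br);
      valid_anchors(g.mw - 2, di, g.wr, vr);
      overlay_diff(A, B, g, ar, br, ac, bc, d);
      out(di, dj) = var_pass(d, g, vr, vc, nullptr, 0.0, s1, s2);
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_localization_variance(IntegerMatrix A, IntegerMatrix B,
                                        double cutpoint) {
  Geom g = geometry(A, B);
  if (g.mw < 3 || g.nw < 3)
    stop("comparison window must be at least 3x3 for the variance algorithm");
  check_no_sentinel(A, "localization_variance");
  check_no_sentinel(B, "localization_variance");
  IntegerMatrix loc(g.mw, g.nw);
  std::vector<int> ar(g.mw), br(g.mw), ac(g.nw), bc(g.nw);
  std::vector<double> d((size_t)g.mw * g.nw);
  std::vector<double> s1((size_t)(g.mw - 2) * g.nw), s2((size_t)(g.mw - 2) * g.nw);
  std::vector<unsigned char> vr(g.mw - 2), vc(g.nw - 2);
  for (int dj = 0; dj < g.N; ++dj) {
    index_maps(g.nw, dj, g.wrapA_c, g.wc, ac, bc);
    valid_anchors(g.nw - 2, dj, g.wc, vc);
    for (int di = 0; di < g.M; ++di) {
      index_maps(g.mw, di, g.wrapA_r, g.wr, ar, br);
      valid_anchors(g.mw - 2, di, g.wr, vr);
      overlay_diff(A, B, g, ar, br, ac, bc, d);
      var_pass(d, g, vr, vc, &loc, cutpoint, s1, s2);
    }
  }
  return loc;
}

// Exact template search: every top-left position where the h x w block
// anchored (0-based) at (r0, c0) recurs. Plain value equality; the template
// always matches itself.
// [[Rcpp::export]]
IntegerMatrix cpp_block_search(IntegerMatrix img, int r0, int c0, int h, int w) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<std::pair<int, int> > hits;
  for (int c = 0; c + w <= nc; ++c)
    for (int r = 0; r + h <= nr; ++r) {
      bool ok = true;
      for (int j = 0; j < w && ok; ++j)
        for (int i = 0; i < h; ++i)
          if (img(r + i, c + j) != img(r0 + i, c0 + j)) { ok = false; break; }
      if (ok) hits.push_back(std::make_pair(r, c));
    }
  // row-major order of positions
  std::sort(hits.begin(), hits.end());
  IntegerMatrix out((int)hits.size(), 2);
  for (size_t k = 0; k < hits.size(); ++k) {
    out(k, 0) = hits[k].first;
    out(k, 1) = hits[k].second;
  }
  return out;
}
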