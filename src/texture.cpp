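#include <Rcpp.h>
using namespace Rcpp;

// Pair-count accumulation for a single-direction gray-level co-occurrence
// matrix. `img` holds quantized levels in [0, Q-1]; the offset (dr, dc) is in
// (row, col) steps with rows increasing downwards. Counts are NOT symmetrized.
// [[Rcpp::export(name = ".glcm_counts")]]
NumericMatrix glcm_counts(IntegerMatrix img, int dr, int dc, int Q) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(Q, Q);
  for (int r = 0; r < nr; ++r) {
    int r2 = r + dr;
    if (r2 < 0 || r2 >= nr) continue;
    for (int c = 0; c < nc; ++c) {
      int c2 = c + dc;
      if (c2 < 0 || c2 >= nc) continue;
      out(img(r, c), img(r2, c2)) += 1.0;
    }
  }
  return out;
}

// Maximal-run counts for a gray-level run-length matrix along direction
// (dr, dc). Every pixel lies on exactly one line of the direction; lines are
// walked from their boundary start cells. Returns a Q x max_run count matrix
// where column j holds runs of length j+1 (max_run = longest possible line).
// [[Rcpp::export(name = ".glrlm_counts")]]
NumericMatrix glrlm_counts(IntegerMatrix img, int dr, int dc, int Q) {
  int nr = img.nrow(), nc = img.ncol();
  int max_run = std::max(nr, nc);
  NumericMatrix out(Q, max_run);
  for (int r0 = 0; r0 < nr; ++r0) {
    for (int c0 = 0; c0 < nc; ++c0) {
      // start cell: predecessor along (dr, dc) falls outside the image
      int rp = r0 - dr, cp = c0 - dc;
      if (rp >= 0 && rp < nr && cp >= 0 && cp < nc) continue;
      int r = r0, c = c0;
      int g = img(r, c), len = 0;
      while (r >= 0 && r < nr && c >= 0 && c < nc) {
        int v = img(r, c);
        if (v == g) {
          ++len;
        } else {
          out(g, len - 1) += 1.0;
          g = v;
          len = 1;
        }
        r += dr;
        c += dc;
      }
      out(g, len - 1) += 1.0;
    }
  }
  return out;
}

// 256-bin histogram of classic radius-1 8-neighbour LBP codes over interior
// pixels. Bit k set when neighbour k >= centre; neighbour order starts east
// and proceeds counter-clockwise (E, NE, N, NW, W, SW, S, SE) with "north"
// one row up.
// [[Rcpp::export(name = ".lbp_hist")]]
IntegerVector lbp_hist(IntegerMatrix img) {
  static const int DR[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int DC[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  int nr = img.nrow(), nc = img.ncol();
  IntegerVector h(256);
  for (int r = 1; r < nr - 1; ++r) {
    for (int c = 1; c < nc - 1; ++c) {
      int ctr = img(r, c), code = 0;
      for (int k = 0; k < 8; ++k) {
        if (img(r + DR[k], c + DC[k]) >= ctr) code |= (1 << k);
      }
      ++h[code];
    }
  }
  return h;
}
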