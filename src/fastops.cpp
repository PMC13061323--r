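#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Label connected components of a logical matrix with an explicit work
// stack (grids can be large; recursion is not an option). Background and NA
// cells get label 0. connectivity is 4 (edge neighbours) or 8 (edges +
// diagonals).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) != TRUE || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int rr = cr + dr8[k], cck = cc + dc8[k];
          if (rr < 0 || rr >= nr || cck < 0 || cck >= nc) continue;
          if (mask(rr, cck) == TRUE && lab(rr, cck) == 0) {
            lab(rr, cck) = next;
            stack.push_back(rr + cck * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Per-row median ignoring NA; rows with no finite value give NA. Even counts
// average the two central order statistics.
// [[Rcpp::export(name = ".row_medians_cpp")]]
NumericVector row_medians_cpp(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nr);
  std::vector<double> buf;
  buf.reserve(nc);
  for (int r = 0; r < nr; ++r) {
    buf.clear();
    for (int c = 0; c < nc; ++c) {
      double v = x(r, c);
      if (!ISNAN(v)) buf.push_back(v);
    }
    const int n = (int) buf.size();
    if (n == 0) { out[r] = NA_REAL; continue; }
    int mid = n / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double hi = buf[mid];
    if (n % 2 == 1) {
      out[r] = hi;
    } else {
      double lo = *std::max_element(buf.begin(), buf.begin() + mid);
      out[r] = (lo + hi) / 2.0;
    }
  }
  return out;
}
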