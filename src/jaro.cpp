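#include <Rcpp.h>
using namespace Rcpp;

// Standard Jaro similarity: match window floor(max(la, lb)/2) - 1,
// transpositions counted as half the out-of-order matched characters.
static double jaro_pair(const std::string &a, const std::string &b) {
  const int la = a.size(), lb = b.size();
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  const int win = std::max(std::max(la, lb) / 2 - 1, 0);
  std::vector<bool> am(la, false), bm(lb, false);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    const int lo = std::max(0, i - win);
    const int hi = std::min(lb - 1, i + win);
    for (int j = lo; j <= hi; ++j) {
      if (!bm[j] && a[i] == b[j]) {
        am[i] = true;
        bm[j] = true;
        ++m;
        break;
      }
    }
  }
  if (m == 0) return 0.0;
  int k = 0, t2 = 0;
  for (int i = 0; i < la; ++i) {
    if (!am[i]) continue;
    while (!bm[k]) ++k;
    if (a[i] != b[k]) ++t2;
    ++k;
  }
  const double t = t2 / 2.0;
  return ((double)m / la + (double)m / lb + (m - t) / m) / 3.0;
}

// [[Rcpp::export]]
NumericVector jaro_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("length mismatch");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) {
      out[i] = NA_REAL;
    } else {
      out[i] = jaro_pair(as<std::string>(a[i]), as<std::string>(b[i]));
    }
  }
  return out;
}
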