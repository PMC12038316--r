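#include <Rcpp.h>
using namespace Rcpp;

// Reflective index (1-based, whole-sample mirror about the edge, edge not
// duplicated): 0 -> 2, -1 -> 3, n+1 -> n-1. Valid for |overshoot| < n.
static inline int reflect1(int s, int n) {
  if (s < 1) return 2 - s;
  if (s > n) return 2 * n - s;
  return s;
}

// Signed linear Gabor responses at sampled positions.
//
// Computes R(p) = sum_d K(d) I(p - d) with reflective border handling,
// where K is the kernel `kid[t]` centred on (krow[t], kcol[t]).  Only image
// pixels inside the bounding box [bb_rmin..bb_rmax] x [bb_cmin..bb_cmax]
// contribute: pixels outside it are treated as zero.  Passing the full image
// extent gives the plain convolution; passing a probe crop's extent gives the
// exact response to that crop placed on a zero background.
//
// [[Rcpp::export]]
NumericVector gabor_responses_at(const NumericMatrix& img, const List& kernels,
                                 const IntegerVector& krow,
                                 const IntegerVector& kcol,
                                 const IntegerVector& kid, const int bb_rmin,
                                 const int bb_rmax, const int bb_cmin,
                                 const int bb_cmax) {
  const int nr = img.nrow(), nc = img.ncol();
  const int npts = krow.size();
  const int nk = kernels.size();
  std::vector<NumericMatrix> ker(nk);
  std::vector<int> half(nk);
  for (int k = 0; k < nk; ++k) {
    ker[k] = as<NumericMatrix>(kernels[k]);
    half[k] = (ker[k].nrow() - 1) / 2;
  }
  NumericVector out(npts);
  for (int t = 0; t < npts; ++t) {
    const int pr = krow[t], pc = kcol[t];
    const int k = kid[t] - 1;
    const int h = half[k];
    const NumericMatrix& K = ker[k];
    double acc = 0.0;
    const bool interior =
        pr - h >= 1 && pr + h <= nr && pc - h >= 1 && pc + h <= nc;
    if (interior) {
      // source s = p - d must lie in the bbox: restrict offset ranges
      int dr_lo = std::max(-h, pr - bb_rmax), dr_hi = std::min(h, pr - bb_rmin);
      int dc_lo = std::max(-h, pc - bb_cmax), dc_hi = std::min(h, pc - bb_cmin);
      if (dr_lo > dr_hi || dc_lo > dc_hi) {
        out[t] = 0.0;
        continue;
      }
      for (int dc = dc_lo; dc <= dc_hi; ++dc) {
        const int sc = pc - dc;
        const double* icol = &img(0, sc - 1);
        const double* kcolp = &K(0, dc + h);
        for (int dr = dr_lo; dr <= dr_hi; ++dr) {
          acc += kcolp[dr + h] * icol[pr - dr - 1];
        }
      }
    } else {
      for (int dc = -h; dc <= h; ++dc) {
        const int sc = reflect1(pc - dc, nc);
        if (sc < bb_cmin || sc > bb_cmax) continue;
        const double* icol = &img(0, sc - 1);
        const double* kcolp = &K(0, dc + h);
        for (int dr = -h; dr <= h; ++dr) {
          const int sr = reflect1(pr - dr, nr);
          if (sr < bb_rmin || sr > bb_rmax) continue;
          acc += kcolp[dr + h] * icol[sr - 1];
        }
      }
    }
    out[t] = acc;
  }
  return out;
}
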