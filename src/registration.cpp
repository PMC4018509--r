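#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pull-back resampling of a 2D image under a rigid transform.
// The forward map sends a source point p to Rot(theta, center)(p - center)
// + center + (dx, dy); each output pixel q is filled by sampling the input
// at the inverse image of q. Coordinates are 0-based with x along columns
// and y along rows; theta is in radians. Out-of-bounds samples receive
// pad, or NaN when pad_na is true (callers use NaN to mark pixels that
// must not enter the joint histogram).
// [[Rcpp::export(name = ".cpp_rigid_resample")]]
NumericMatrix cpp_rigid_resample(const NumericMatrix& img, double dx,
                                 double dy, double theta, double cx,
                                 double cy, bool nearest, double pad,
                                 bool pad_na) {
  const int M = img.nrow(), N = img.ncol();
  NumericMatrix out(M, N);
  const double ct = std::cos(theta), st = std::sin(theta);
  const double padval = pad_na ? NA_REAL : pad;
  for (int c = 0; c < N; ++c) {
    const double xc = c - cx - dx;
    for (int r = 0; r < M; ++r) {
      const double yc = r - cy - dy;
      // inverse rotation (by -theta) about the center
      const double sx = ct * xc + st * yc + cx;
      const double sy = -st * xc + ct * yc + cy;
      if (nearest) {
        const long ic = std::lround(sx), ir = std::lround(sy);
        out(r, c) = (ir >= 0 && ir < M && ic >= 0 && ic < N)
                        ? img(ir, ic)
                        : padval;
      } else {
        const int c0 = (int)std::floor(sx), r0 = (int)std::floor(sy);
        if (r0 < 0 || r0 >= M - 1 || c0 < 0 || c0 >= N - 1) {
          // allow exact top/left border hits
          if (sx >= 0 && sx <= N - 1 && sy >= 0 && sy <= M - 1) {
            const int cc = (c0 == N - 1) ? c0 - 1 : std::max(c0, 0);
            const int rr = (r0 == M - 1) ? r0 - 1 : std::max(r0, 0);
            const double fx = sx - cc, fy = sy - rr;
            out(r, c) = (1 - fy) * ((1 - fx) * img(rr, cc) +
                                    fx * img(rr, cc + 1)) +
                        fy * ((1 - fx) * img(rr + 1, cc) +
                              fx * img(rr + 1, cc + 1));
          } else {
            out(r, c) = padval;
          }
        } else {
          const double fx = sx - c0, fy = sy - r0;
          out(r, c) = (1 - fy) * ((1 - fx) * img(r0, c0) +
                                  fx * img(r0, c0 + 1)) +
                      fy * ((1 - fx) * img(r0 + 1, c0) +
                            fx * img(r0 + 1, c0 + 1));
        }
      }
    }
  }
  return out;
}

// Joint gray-value histogram counts over B x B equal-width bins spanning
// (a_lo, a_hi) x (b_lo, b_hi). Pixel pairs where either value is NaN are
// skipped (out-of-bounds samples of the transformed floating image).
// Values outside the stated range are clamped into the edge bins, so the
// ranges can be frozen once per registration.
// [[Rcpp::export(name = ".cpp_joint_hist")]]
List cpp_joint_hist(const NumericMatrix& a, const NumericMatrix& b, int B,
                    double a_lo, double a_hi, double b_lo, double b_hi) {
  if (a.nrow() != b.nrow() || a.ncol() != b.ncol())
    stop("images must have the same shape");
  const double wa = (a_hi > a_lo) ? B / (a_hi - a_lo) : 0.0;
  const double wb = (b_hi > b_lo) ? B / (b_hi - b_lo) : 0.0;
  IntegerMatrix counts(B, B);
  const R_xlen_t n = a.size();
  R_xlen_t used = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double av = a[i], bv = b[i];
    if (ISNAN(av) || ISNAN(bv)) continue;
    int ia = (int)((av - a_lo) * wa);
    int ib = (int)((bv - b_lo) * wb);
    if (ia < 0) ia = 0; else if (ia >= B) ia = B - 1;
    if (ib < 0) ib = 0; else if (ib >= B) ib = B - 1;
    ++counts(ia, ib);
    ++used;
  }
  return List::create(_["counts"] = counts, _["n"] = (double)used);
}
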