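#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

// mirror-without-repeat reflection: -1 -> 1, n -> n-2
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// 2-D correlation with reflective borders; kernel has odd dimensions
// [[Rcpp::export(name = ".conv2_reflect")]]
NumericMatrix conv2_reflect(const NumericMatrix& x, const NumericMatrix& k) {
  const int nr = x.nrow(), nc = x.ncol();
  const int kr = k.nrow(), kc = k.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int j = 0; j < kc; ++j) {
        const int cc = refl(c + j - hc, nc);
        for (int i = 0; i < kr; ++i) {
          acc += k(i, j) * x(refl(r + i - hr, nr), cc);
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// blur-and-decimate in one pass: out(y,x) = sum_ij k(i,j) x(2y+i-h, 2x+j-h)
// [[Rcpp::export(name = ".reduce_cpp")]]
NumericMatrix reduce_cpp(const NumericMatrix& x, const NumericMatrix& k) {
  const int nr = x.nrow(), nc = x.ncol();
  const int onr = (nr + 1) / 2, onc = (nc + 1) / 2;
  const int kr = k.nrow(), kc = k.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(onr, onc);
  for (int c = 0; c < onc; ++c) {
    for (int r = 0; r < onr; ++r) {
      double acc = 0.0;
      for (int j = 0; j < kc; ++j) {
        const int cc = refl(2 * c + j - hc, nc);
        for (int i = 0; i < kr; ++i) {
          acc += k(i, j) * x(refl(2 * r + i - hr, nr), cc);
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".bilateral_cpp")]]
NumericMatrix bilateral_cpp(const NumericMatrix& x, int diameter,
                            double sigma_intensity, double sigma_spatial) {
  const int nr = x.nrow(), nc = x.ncol();
  const int h = diameter / 2;
  NumericMatrix out(nr, nc);
  // spatial weights are fixed over the window
  NumericMatrix sw(diameter, diameter);
  const double s2 = 2.0 * sigma_spatial * sigma_spatial;
  for (int j = 0; j < diameter; ++j)
    for (int i = 0; i < diameter; ++i)
      sw(i, j) = std::exp(-(double)((i - h) * (i - h) + (j - h) * (j - h)) / s2);
  const double r2 = 2.0 * sigma_intensity * sigma_intensity;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double centre = x(r, c);
      double num = 0.0, den = 0.0;
      for (int j = 0; j < diameter; ++j) {
        const int cc = refl(c + j - h, nc);
        for (int i = 0; i < diameter; ++i) {
          const double v = x(refl(r + i - h, nr), cc);
          const double d = v - centre;
          const double w = sw(i, j) * std::exp(-(d * d) / r2);
          num += w * v;
          den += w;
        }
      }
      out(r, c) = num / den;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".median_cpp")]]
NumericMatrix median_cpp(const NumericMatrix& x, int ksize) {
  const int nr = x.nrow(), nc = x.ncol();
  const int h = ksize / 2;
  const int win = ksize * ksize;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(win);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = 0;
      for (int j = -h; j <= h; ++j) {
        const int cc = refl(c + j, nc);
        for (int i = -h; i <= h; ++i) buf[idx++] = x(refl(r + i, nr), cc);
      }
      std::nth_element(buf.begin(), buf.begin() + win / 2, buf.end());
      double med = buf[win / 2];
      // window size is odd*odd = odd, so the middle element is the median
      out(r, c) = med;
    }
  }
  return out;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// exact Euclidean distance (pixels) to the nearest TRUE cell
// [[Rcpp::export(name = ".edt_cpp")]]
NumericMatrix edt_cpp(const LogicalMatrix& seeds) {
  const int nr = seeds.nrow(), nc = seeds.ncol();
  const double INF = 1e18;
  NumericMatrix d2(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) d2(r, c) = seeds(r, c) ? 0.0 : INF;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {           // columns
    for (int r = 0; r < nr; ++r) f[r] = d2(r, c);
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) d2(r, c) = d[r];
  }
  for (int r = 0; r < nr; ++r) {           // rows
    for (int c = 0; c < nc; ++c) f[c] = d2(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) d2(r, c) = std::sqrt(d[c]);
  }
  return d2;
}

// periodized analysis along rows: x is nr x nc with nc even
static void dwt_rows(const NumericMatrix& x, const NumericVector& h,
                     const NumericVector& g, NumericMatrix& lo,
                     NumericMatrix& hi) {
  const int nr = x.nrow(), nc = x.ncol(), L = h.size(), half = nc / 2;
  for (int r = 0; r < nr; ++r) {
    for (int k = 0; k < half; ++k) {
      double a = 0.0, d = 0.0;
      for (int m = 0; m < L; ++m) {
        const double v = x(r, (2 * k + m) % nc);
        a += h[m] * v;
        d += g[m] * v;
      }
      lo(r, k) = a;
      hi(r, k) = d;
    }
  }
}

// adjoint synthesis along rows
static void idwt_rows(const NumericMatrix& lo, const NumericMatrix& hi,
                      const NumericVector& h, const NumericVector& g,
                      NumericMatrix& out) {
  const int nr = lo.nrow(), half = lo.ncol(), nc = out.ncol(), L = h.size();
  std::fill(out.begin(), out.end(), 0.0);
  for (int r = 0; r < nr; ++r) {
    for (int k = 0; k < half; ++k) {
      const double a = lo(r, k), d = hi(r, k);
      for (int m = 0; m < L; ++m) {
        const int c = (2 * k + m) % nc;
        out(r, c) += a * h[m] + d * g[m];
      }
    }
  }
}

static NumericMatrix transpose_nm(const NumericMatrix& x) {
  NumericMatrix t(x.ncol(), x.nrow());
  for (int c = 0; c < x.ncol(); ++c)
    for (int r = 0; r < x.nrow(); ++r) t(c, r) = x(r, c);
  return t;
}

// one separable 2-D analysis step on an even-dimension plane;
// returns LL, LH (lo rows / hi cols), HL (hi rows / lo cols), HH
// [[Rcpp::export(name = ".dwt2_per_cpp")]]
List dwt2_per_cpp(const NumericMatrix& x, const NumericVector& h,
                  const NumericVector& g) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix rlo(nr, nc / 2), rhi(nr, nc / 2);
  dwt_rows(x, h, g, rlo, rhi);             // along columns of each row
  NumericMatrix tlo = transpose_nm(rlo), thi = transpose_nm(rhi);
  NumericMatrix ll(nc / 2, nr / 2), hl(nc / 2, nr / 2);
  NumericMatrix lh(nc / 2, nr / 2), hh(nc / 2, nr / 2);
  dwt_rows(tlo, h, g, ll, hl);             // along rows (transposed)
  dwt_rows(thi, h, g, lh, hh);
  return List::create(_["LL"] = transpose_nm(ll), _["LH"] = transpose_nm(lh),
                      _["HL"] = transpose_nm(hl), _["HH"] = transpose_nm(hh));
}

// inverse of dwt2_per_cpp
// [[Rcpp::export(name = ".idwt2_per_cpp")]]
NumericMatrix idwt2_per_cpp(const NumericMatrix& ll, const NumericMatrix& lh,
                            const NumericMatrix& hl, const NumericMatrix& hh,
                            const NumericVector& h, const NumericVector& g) {
  const int hr = ll.nrow(), hc = ll.ncol();
  NumericMatrix tlo(hc, 2 * hr), thi(hc, 2 * hr);
  idwt_rows(transpose_nm(ll), transpose_nm(hl), h, g, tlo);
  idwt_rows(transpose_nm(lh), transpose_nm(hh), h, g, thi);
  NumericMatrix out(2 * hr, 2 * hc);
  idwt_rows(transpose_nm(tlo), transpose_nm(thi), h, g, out);
  return out;
}
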