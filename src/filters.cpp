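#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int clampi(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }

// 3x3x3 median filter with edge replication.
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector x, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(x.size());
  std::vector<double> buf(27);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int m = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          const int kk = clampi(k + dk, nz);
          for (int dj = -1; dj <= 1; ++dj) {
            const int jj = clampi(j + dj, ny);
            for (int di = -1; di <= 1; ++di) {
              const int ii = clampi(i + di, nx);
              buf[m++] = x[ii + (size_t)nx * (jj + (size_t)ny * kk)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + 13, buf.end());
        out[i + (size_t)nx * (j + (size_t)ny * k)] = buf[13];
      }
    }
  }
  return out;
}

static void gauss_kernel(double sigma, std::vector<double>& k) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  k.assign(2 * r + 1, 0.0);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
}

// one separable pass along a given axis (0, 1, 2), replicate boundary
static void smooth_axis(std::vector<double>& v, int nx, int ny, int nz,
                        const std::vector<double>& ker, int axis) {
  const int r = ((int)ker.size() - 1) / 2;
  std::vector<double> line;
  const int n[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int na = n[axis];
  line.resize(na);
  // iterate over all lines perpendicular to axis
  const int b1 = axis == 0 ? 1 : 0;
  const int b2 = axis == 2 ? 1 : 2;
  for (int q = 0; q < n[b2]; ++q) {
    for (int p = 0; p < n[b1]; ++p) {
      const size_t base = stride[b1] * p + stride[b2] * q;
      for (int t = 0; t < na; ++t) line[t] = v[base + stride[axis] * t];
      for (int t = 0; t < na; ++t) {
        double acc = 0.0;
        for (int u = -r; u <= r; ++u) acc += ker[u + r] * line[clampi(t + u, na)];
        v[base + stride[axis] * t] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector x, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(x.begin(), x.end());
  std::vector<double> ker;
  gauss_kernel(sigma, ker);
  smooth_axis(v, nx, ny, nz, ker, 0);
  smooth_axis(v, nx, ny, nz, ker, 1);
  smooth_axis(v, nx, ny, nz, ker, 2);
  return NumericVector(v.begin(), v.end());
}

// eigenvalues of a symmetric 3x3 matrix (analytic), sorted by |.| ascending
static inline void eig3sym(double a11, double a12, double a13,
                           double a22, double a23, double a33, double* w) {
  const double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  double e1, e2, e3;
  if (p1 == 0.0) {
    e1 = a11; e2 = a22; e3 = a33;
  } else {
    const double q = (a11 + a22 + a33) / 3.0;
    const double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
    const double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    const double c11 = b11 / p, c12 = a12 / p, c13 = a13 / p;
    const double c22 = b22 / p, c23 = a23 / p, c33 = b33 / p;
    double r = 0.5 * (c11 * (c22 * c33 - c23 * c23)
                      - c12 * (c12 * c33 - c23 * c13)
                      + c13 * (c12 * c23 - c22 * c13));
    r = std::max(-1.0, std::min(1.0, r));
    const double phi = std::acos(r) / 3.0;
    e1 = q + 2.0 * p * std::cos(phi);
    e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    e2 = 3.0 * q - e1 - e3;
  }
  // sort by absolute value
  double v[3] = {e1, e2, e3};
  if (std::fabs(v[0]) > std::fabs(v[1])) std::swap(v[0], v[1]);
  if (std::fabs(v[1]) > std::fabs(v[2])) std::swap(v[1], v[2]);
  if (std::fabs(v[0]) > std::fabs(v[1])) std::swap(v[0], v[1]);
  w[0] = v[0]; w[1] = v[1]; w[2] = v[2];
}

// Frangi vesselness at a single scale (bright tubes on dark background).
// sigma in voxels; Hessian from central differences of the Gaussian-smoothed
// volume, scale-normalized by sigma^2; c set to c_frac times the maximum
// Frobenius norm of the Hessian over the volume.
// [[Rcpp::export]]
NumericVector cpp_frangi_scale(NumericVector x, IntegerVector dim, double sigma,
                               double alpha, double beta, double c_frac) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<double> s(x.begin(), x.end());
  std::vector<double> ker;
  gauss_kernel(sigma, ker);
  smooth_axis(s, nx, ny, nz, ker, 0);
  smooth_axis(s, nx, ny, nz, ker, 1);
  smooth_axis(s, nx, ny, nz, ker, 2);

  std::vector<double> l1(n), l2(n), l3(n);
  const double s2 = sigma * sigma;
  double max_frob2 = 0.0;

  for (int k = 0; k < nz; ++k) {
    const int km = clampi(k - 1, nz), kp = clampi(k + 1, nz);
    for (int j = 0; j < ny; ++j) {
      const int jm = clampi(j - 1, ny), jp = clampi(j + 1, ny);
      for (int i = 0; i < nx; ++i) {
        const int im = clampi(i - 1, nx), ip = clampi(i + 1, nx);
        #define S(a, b, c) s[(a) + (size_t)nx * ((b) + (size_t)ny * (c))]
        const double c0 = S(i, j, k);
        const double hxx = S(ip, j, k) - 2.0 * c0 + S(im, j, k);
        const double hyy = S(i, jp, k) - 2.0 * c0 + S(i, jm, k);
        const double hzz = S(i, j, kp) - 2.0 * c0 + S(i, j, km);
        const double hxy = 0.25 * (S(ip, jp, k) - S(ip, jm, k) - S(im, jp, k) + S(im, jm, k));
        const double hxz = 0.25 * (S(ip, j, kp) - S(ip, j, km) - S(im, j, kp) + S(im, j, km));
        const double hyz = 0.25 * (S(i, jp, kp) - S(i, jp, km) - S(i, jm, kp) + S(i, jm, km));
        #undef S
        double w[3];
        eig3sym(s2 * hxx, s2 * hxy, s2 * hxz, s2 * hyy, s2 * hyz, s2 * hzz, w);
        const size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
        l1[idx] = w[0]; l2[idx] = w[1]; l3[idx] = w[2];
        const double f2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
        if (f2 > max_frob2) max_frob2 = f2;
      }
    }
  }

  const double c = c_frac * std::sqrt(max_frob2);
  NumericVector out(n);
  if (c <= 0.0) return out;  // flat volume: zero response
  const double ia2 = 1.0 / (2.0 * alpha * alpha);
  const double ib2 = 1.0 / (2.0 * beta * beta);
  const double ic2 = 1.0 / (2.0 * c * c);
  for (size_t idx = 0; idx < n; ++idx) {
    const double e2 = l2[idx], e3 = l3[idx];
    if (e2 >= 0.0 || e3 >= 0.0) { out[idx] = 0.0; continue; }
    const double a2 = std::fabs(e2), a3 = std::fabs(e3);
    const double ra = a2 / a3;
    const double rb = std::fabs(l1[idx]) / std::sqrt(a2 * a3);
    const double ss = l1[idx] * l1[idx] + e2 * e2 + e3 * e3;
    out[idx] = (1.0 - std::exp(-ra * ra * ia2)) * std::exp(-rb * rb * ib2)
               * (1.0 - std::exp(-ss * ic2));
  }
  return out;
}
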