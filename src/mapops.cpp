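// Analytic Gaussian overlaps, rasterization and local cross-correlation.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3x3 symmetric inverse and determinant. Returns false when det <= tiny.
static bool inv3(const double S[6], double inv[6], double &det) {
  // packed order: xx, yy, zz, xy, xz, yz
  const double a = S[0], b = S[3], c = S[4];
  const double d = S[1], e = S[5], f = S[2];
  // matrix [[a,b,c],[b,d,e],[c,e,f]]
  const double A = d * f - e * e;
  const double B = c * e - b * f;
  const double C = b * e - c * d;
  det = a * A + b * B + c * C;
  if (!(det > 1e-300)) return false;
  const double id = 1.0 / det;
  inv[0] = A * id;            // xx
  inv[3] = B * id;            // xy
  inv[4] = C * id;            // xz
  inv[1] = (a * f - c * c) * id; // yy
  inv[5] = (b * c - a * e) * id; // yz
  inv[2] = (a * d - b * b) * id; // zz
  return true;
}

static void pack_cov(const double *sig, int k, double S[6]) {
  // sig is 3x3xK column-major
  const double *m = sig + 9 * k;
  S[0] = m[0]; S[1] = m[4]; S[2] = m[8];
  S[3] = m[1]; S[4] = m[2]; S[5] = m[5];
}

static const double TWO_PI_M32 = 0.06349363593424097; // (2*pi)^(-3/2)

// [[Rcpp::export]]
NumericMatrix cpp_overlap_matrix(NumericVector wa, NumericMatrix mua,
                                 NumericVector siga, NumericVector wb,
                                 NumericMatrix mub, NumericVector sigb) {
  const int Ka = wa.size(), Kb = wb.size();
  NumericMatrix out(Ka, Kb);
  double Sa[6], Sb[6], S[6], inv[6], det;
  for (int i = 0; i < Ka; ++i) {
    pack_cov(REAL(siga), i, Sa);
    for (int j = 0; j < Kb; ++j) {
      pack_cov(REAL(sigb), j, Sb);
      for (int t = 0; t < 6; ++t) S[t] = Sa[t] + Sb[t];
      if (!inv3(S, inv, det))
        stop("degenerate summed covariance for pair (%d, %d)", i + 1, j + 1);
      const double dx = mua(i, 0) - mub(j, 0);
      const double dy = mua(i, 1) - mub(j, 1);
      const double dz = mua(i, 2) - mub(j, 2);
      const double q = inv[0] * dx * dx + inv[1] * dy * dy + inv[2] * dz * dz +
                       2.0 * (inv[3] * dx * dy + inv[4] * dx * dz +
                              inv[5] * dy * dz);
      out(i, j) = wa[i] * wb[j] * TWO_PI_M32 / std::sqrt(det) *
                  std::exp(-0.5 * q);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rasterize(NumericVector w, NumericMatrix mu,
                            NumericVector sigma, IntegerVector dims,
                            NumericVector voxel, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(Dimension(nx, ny, nz));
  const int K = w.size();
  double S[6], inv[6], det;
  for (int k = 0; k < K; ++k) {
    pack_cov(REAL(sigma), k, S);
    if (!inv3(S, inv, det)) stop("degenerate covariance in rasterize");
    const double pref = w[k] * TWO_PI_M32 / std::sqrt(det);
    const double sd = std::sqrt(std::max(S[0], std::max(S[1], S[2])));
    const double r = 8.0 * sd;
    int lo[3], hi[3];
    for (int a = 0; a < 3; ++a) {
      lo[a] = (int)std::floor((mu(k, a) - r - origin[a]) / voxel[a]);
      hi[a] = (int)std::ceil((mu(k, a) + r - origin[a]) / voxel[a]);
      if (lo[a] < 0) lo[a] = 0;
      if (hi[a] > dims[a] - 1) hi[a] = dims[a] - 1;
    }
    for (int iz = lo[2]; iz <= hi[2]; ++iz) {
      const double dz = origin[2] + iz * voxel[2] - mu(k, 2);
      for (int iy = lo[1]; iy <= hi[1]; ++iy) {
        const double dy = origin[1] + iy * voxel[1] - mu(k, 1);
        for (int ix = lo[0]; ix <= hi[0]; ++ix) {
          const double dx = origin[0] + ix * voxel[0] - mu(k, 0);
          const double q = inv[0] * dx * dx + inv[1] * dy * dy +
                           inv[2] * dz * dz +
                           2.0 * (inv[3] * dx * dy + inv[4] * dx * dz +
                                  inv[5] * dy * dz);
          out[ix + nx * (iy + ny * iz)] += pref * std::exp(-0.5 * q);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_local_cc(NumericVector a, NumericVector b, int window) {
  IntegerVector dims = a.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int h = window / 2;
  NumericVector out(Dimension(nx, ny, nz));
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const int x0 = std::max(0, ix - h), x1 = std::min(nx - 1, ix + h);
        const int y0 = std::max(0, iy - h), y1 = std::min(ny - 1, iy + h);
        const int z0 = std::max(0, iz - h), z1 = std::min(nz - 1, iz + h);
        double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
        int n = 0;
        for (int z = z0; z <= z1; ++z)
          for (int y = y0; y <= y1; ++y)
            for (int x = x0; x <= x1; ++x) {
              const double va = a[x + nx * (y + ny * z)];
              const double vb = b[x + nx * (y + ny * z)];
              sa += va; sb += vb; saa += va * va; sbb += vb * vb;
              sab += va * vb; ++n;
            }
        const double ca = n * saa - sa * sa;
        const double cb = n * sbb - sb * sb;
        const double scale = std::max(saa, 1e-300) * n;
        if (ca <= 1e-14 * scale || cb <= 1e-14 * (n * std::max(sbb, 1e-300)))
          out[ix + nx * (iy + ny * iz)] = NA_REAL;
        else
          out[ix + nx * (iy + ny * iz)] =
              (n * sab - sa * sb) / std::sqrt(ca * cb);
      }
  return out;
}
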