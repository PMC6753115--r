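#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Nonlocal-means denoising. d = mean squared patch difference; weight
// exp(-d / h2); the centre voxel always participates with weight 1.
// [[Rcpp::export(name = ".pg_nlm")]]
NumericVector pg_nlm(NumericVector vol, IntegerVector dim,
                     int patch_radius, int search_radius, double h2) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int pr = patch_radius, sr = search_radius;
  double psz = std::pow(2.0 * pr + 1.0, 3);
  const double* v = REAL(vol);
  NumericVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = dim;

  std::vector<R_xlen_t> offs;
  for (int dk = -pr; dk <= pr; ++dk)
    for (int dj = -pr; dj <= pr; ++dj)
      for (int di = -pr; di <= pr; ++di)
        offs.push_back((R_xlen_t)di + (R_xlen_t)nx * ((R_xlen_t)dj + (R_xlen_t)ny * dk));

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double wsum = 0.0, acc = 0.0;
        bool c_int = i >= pr + sr && i < nx - pr - sr && j >= pr + sr &&
                     j < ny - pr - sr && k >= pr + sr && k < nz - pr - sr;
        for (int dk = -sr; dk <= sr; ++dk) {
          int uk = k + dk; if (uk < 0 || uk >= nz) continue;
          for (int dj = -sr; dj <= sr; ++dj) {
            int uj = j + dj; if (uj < 0 || uj >= ny) continue;
            for (int di = -sr; di <= sr; ++di) {
              int ui = i + di; if (ui < 0 || ui >= nx) continue;
              double d = 0.0;
              if (c_int) {
                const double* a = v + lin(i, j, k, nx, ny);
                const double* b = v + lin(ui, uj, uk, nx, ny);
                for (size_t t = 0; t < offs.size(); ++t) {
                  double diff = a[offs[t]] - b[offs[t]];
                  d += diff * diff;
                }
                double w = (di == 0 && dj == 0 && dk == 0)
                             ? 1.0 : std::exp(-(d / psz) / h2);
                wsum += w;
                acc += w * v[lin(ui, uj, uk, nx, ny)];
                continue;
              }
              for (int pk = -pr; pk <= pr; ++pk) {
                int ak = clampi(k + pk, 0, nz - 1);
                int bk = clampi(uk + pk, 0, nz - 1);
                for (int pj = -pr; pj <= pr; ++pj) {
                  int aj = clampi(j + pj, 0, ny - 1);
                  int bj = clampi(uj + pj, 0, ny - 1);
                  for (int pi = -pr; pi <= pr; ++pi) {
                    int ai = clampi(i + pi, 0, nx - 1);
                    int bi = clampi(ui + pi, 0, nx - 1);
                    double diff = v[lin(ai, aj, ak, nx, ny)] -
                                  v[lin(bi, bj, bk, nx, ny)];
                    d += diff * diff;
                  }
                }
              }
              double w = (di == 0 && dj == 0 && dk == 0)
                           ? 1.0 : std::exp(-(d / psz) / h2);
              wsum += w;
              acc += w * v[lin(ui, uj, uk, nx, ny)];
            }
          }
        }
        out[lin(i, j, k, nx, ny)] = acc / wsum;
      }
  return out;
}

// Resample `vol` onto an output grid. A is a 4x4 homogeneous matrix taking
// output-grid world coordinates (mm, origin at the grid centre) to input
// world coordinates. Trilinear interpolation, or nearest-neighbour when
// `nearest`; points sampling outside the input grid get `fill`.
// [[Rcpp::export(name = ".pg_resample")]]
NumericVector pg_resample(NumericVector vol, IntegerVector dim,
                          NumericMatrix A, IntegerVector out_dim,
                          double vox_in, double vox_out,
                          bool nearest, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  const double* v = REAL(vol);
  NumericVector out((R_xlen_t)ox * oy * oz);
  out.attr("dim") = out_dim;
  double cxo = (ox - 1) / 2.0, cyo = (oy - 1) / 2.0, czo = (oz - 1) / 2.0;
  double cxi = (nx - 1) / 2.0, cyi = (ny - 1) / 2.0, czi = (nz - 1) / 2.0;

  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double wx = (i - cxo) * vox_out;
        double wy = (j - cyo) * vox_out;
        double wz = (k - czo) * vox_out;
        double px = A(0, 0) * wx + A(0, 1) * wy + A(0, 2) * wz + A(0, 3);
        double py = A(1, 0) * wx + A(1, 1) * wy + A(1, 2) * wz + A(1, 3);
        double pz = A(2, 0) * wx + A(2, 1) * wy + A(2, 2) * wz + A(2, 3);
        double fx = px / vox_in + cxi;
        double fy = py / vox_in + cyi;
        double fz = pz / vox_in + czi;
        double val;
        if (nearest) {
          int ii = (int)std::lround(fx), jj = (int)std::lround(fy),
              kk = (int)std::lround(fz);
          val = (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                  ? fill : v[lin(ii, jj, kk, nx, ny)];
        } else {
          int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
              k0 = (int)std::floor(fz);
          if (i0 < 0 || i0 + 1 >= nx || j0 < 0 || j0 + 1 >= ny ||
              k0 < 0 || k0 + 1 >= nz) {
            val = fill;
          } else {
            double ax = fx - i0, ay = fy - j0, az = fz - k0;
            double c00 = v[lin(i0, j0, k0, nx, ny)] * (1 - ax) +
                         v[lin(i0 + 1, j0, k0, nx, ny)] * ax;
            double c10 = v[lin(i0, j0 + 1, k0, nx, ny)] * (1 - ax) +
                         v[lin(i0 + 1, j0 + 1, k0, nx, ny)] * ax;
            double c01 = v[lin(i0, j0, k0 + 1, nx, ny)] * (1 - ax) +
                         v[lin(i0 + 1, j0, k0 + 1, nx, ny)] * ax;
            double c11 = v[lin(i0, j0 + 1, k0 + 1, nx, ny)] * (1 - ax) +
                         v[lin(i0 + 1, j0 + 1, k0 + 1, nx, ny)] * ax;
            double c0 = c00 * (1 - ay) + c10 * ay;
            double c1 = c01 * (1 - ay) + c11 * ay;
            val = c0 * (1 - az) + c1 * az;
          }
        }
        out[lin(i, j, k, ox, oy)] = val;
      }
  return out;
}
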