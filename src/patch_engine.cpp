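#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Column-major 3D indexing helpers. All voxel indices here are 0-based.
static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Sum of squared differences between the patch centred at (si,sj,sk) in
// `sub` and the patch centred at (ti,tj,tk) in `tmp`. Out-of-grid patch
// voxels use replicate (clamp-to-edge) padding, in both volumes.
// `offs` holds the precomputed linear offsets of a fully interior patch;
// when both patches are interior the clamping is skipped.
static double patch_ssd_fast(const double* sub, const double* tmp,
                             R_xlen_t sq, R_xlen_t uq,
                             const std::vector<R_xlen_t>& offs) {
  double d = 0.0;
  const double* a = sub + sq;
  const double* b = tmp + uq;
  for (size_t t = 0; t < offs.size(); ++t) {
    double diff = a[offs[t]] - b[offs[t]];
    d += diff * diff;
  }
  return d;
}

static double patch_ssd(const double* sub, const double* tmp,
                        int nx, int ny, int nz,
                        int si, int sj, int sk,
                        int ti, int tj, int tk, int pr) {
  double d = 0.0;
  for (int dk = -pr; dk <= pr; ++dk) {
    int ks = clampi(sk + dk, 0, nz - 1);
    int kt = clampi(tk + dk, 0, nz - 1);
    for (int dj = -pr; dj <= pr; ++dj) {
      int js = clampi(sj + dj, 0, ny - 1);
      int jt = clampi(tj + dj, 0, ny - 1);
      for (int di = -pr; di <= pr; ++di) {
        int is = clampi(si + di, 0, nx - 1);
        int it = clampi(ti + di, 0, nx - 1);
        double diff = sub[lin(is, js, ks, nx, ny)] - tmp[lin(it, jt, kt, nx, ny)];
        d += diff * diff;
      }
    }
  }
  return d;
}

// Separable box sums with replicate padding: per-voxel patch sum and sum of
// squares, used by the mean/variance preselection test.
static void box_moments(const double* v, int nx, int ny, int nz, int pr,
                        std::vector<double>& psum, std::vector<double>& psum2) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(n), a2(n), b(n), b2(n);
  for (R_xlen_t t = 0; t < n; ++t) { a[t] = v[t]; a2[t] = v[t] * v[t]; }
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0, s2 = 0;
        for (int d = -pr; d <= pr; ++d) {
          R_xlen_t t = lin(clampi(i + d, 0, nx - 1), j, k, nx, ny);
          s += a[t]; s2 += a2[t];
        }
        b[lin(i, j, k, nx, ny)] = s; b2[lin(i, j, k, nx, ny)] = s2;
      }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        double s = 0, s2 = 0;
        for (int d = -pr; d <= pr; ++d) {
          R_xlen_t t = lin(i, clampi(j + d, 0, ny - 1), k, nx, ny);
          s += b[t]; s2 += b2[t];
        }
        a[lin(i, j, k, nx, ny)] = s; a2[lin(i, j, k, nx, ny)] = s2;
      }
  // z pass
  psum.resize(n); psum2.resize(n);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      for (int k = 0; k < nz; ++k) {
        double s = 0, s2 = 0;
        for (int d = -pr; d <= pr; ++d) {
          R_xlen_t t = lin(i, j, clampi(k + d, 0, nz - 1), nx, ny);
          s += a[t]; s2 += a2[t];
        }
        psum[lin(i, j, k, nx, ny)] = s; psum2[lin(i, j, k, nx, ny)] = s2;
      }
}

static inline bool ratio_ok(double a, double b, double thr) {
  // Accept when a/b lies in [thr, 1/thr]; both-near-zero passes, a sign
  // disagreement or one-sided zero fails.
  const double eps = 1e-12;
  if (std::fabs(a) <= eps && std::fabs(b) <= eps) return true;
  if (a * b <= 0.0) return false;
  double r = a / b;
  return r >= thr && r <= 1.0 / thr;
}

// Grade a set of voxels of `subject` against a template library.
// voxels: m x 3 matrix of 1-based (i,j,k). Returns per-voxel fused label,
// grading value, total weight, minimum candidate distance, candidate count
// and a preselection-fallback flag.
// [[Rcpp::export(name = ".pg_grade_voxels")]]
List pg_grade_voxels(NumericVector subject, IntegerVector dim,
                     List tmpl_intensity, List tmpl_labels,
                     IntegerVector group_tags, IntegerMatrix voxels,
                     int patch_radius, int search_radius,
                     bool preselect, double presel_thresh,
                     double eps_scale) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nt = tmpl_intensity.size();
  int m = voxels.nrow();
  int pr = patch_radius, sr = search_radius;
  int psz = (2 * pr + 1); psz = psz * psz * psz;
  double eps = eps_scale * (double)psz;

  const double* sub = REAL(subject);
  std::vector<const double*> tv(nt);
  std::vector<const int*> lv(nt);
  for (int t = 0; t < nt; ++t) {
    NumericVector ti = tmpl_intensity[t];
    IntegerVector tl = tmpl_labels[t];
    tv[t] = REAL(ti); lv[t] = INTEGER(tl);
  }

  std::vector<double> smean, svar;
  std::vector<std::vector<double> > tmean(nt), tvar(nt);
  if (preselect) {
    std::vector<double> s1, s2;
    box_moments(sub, nx, ny, nz, pr, s1, s2);
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    smean.resize(n); svar.resize(n);
    for (R_xlen_t q = 0; q < n; ++q) {
      smean[q] = s1[q] / psz;
      svar[q] = s2[q] / psz - smean[q] * smean[q];
      if (svar[q] < 0) svar[q] = 0;
    }
    for (int t = 0; t < nt; ++t) {
      box_moments(tv[t], nx, ny, nz, pr, s1, s2);
      tmean[t].resize(n); tvar[t].resize(n);
      for (R_xlen_t q = 0; q < n; ++q) {
        tmean[t][q] = s1[q] / psz;
        tvar[t][q] = s2[q] / psz - tmean[t][q] * tmean[t][q];
        if (tvar[t][q] < 0) tvar[t][q] = 0;
      }
    }
  }

  IntegerVector out_label(m), out_ncand(m);
  NumericVector out_grading(m), out_wtot(m), out_dmin(m);
  LogicalVector out_fallback(m);

  std::vector<double> cd; std::vector<int> clab, ctag;
  cd.reserve(1024); clab.reserve(1024); ctag.reserve(1024);

  std::vector<R_xlen_t> offs;
  offs.reserve((size_t)psz);
  for (int dk = -pr; dk <= pr; ++dk)
    for (int dj = -pr; dj <= pr; ++dj)
      for (int di = -pr; di <= pr; ++di)
        offs.push_back(lin(di + pr, dj + pr, dk + pr, nx, ny) -
                       lin(pr, pr, pr, nx, ny));

  for (int q = 0; q < m; ++q) {
    int vi = voxels(q, 0) - 1, vj = voxels(q, 1) - 1, vk = voxels(q, 2) - 1;
    if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz)
      stop("voxel index out of bounds");
    bool fell_back = false;
    bool s_interior = vi >= pr && vi < nx - pr && vj >= pr && vj < ny - pr &&
                      vk >= pr && vk < nz - pr;
    for (int pass = 0; pass < 2; ++pass) {
      bool use_presel = preselect && pass == 0;
      cd.clear(); clab.clear(); ctag.clear();
      R_xlen_t sq = lin(vi, vj, vk, nx, ny);
      for (int t = 0; t < nt; ++t) {
        for (int dk = -sr; dk <= sr; ++dk) {
          int uk = vk + dk; if (uk < 0 || uk >= nz) continue;
          for (int dj = -sr; dj <= sr; ++dj) {
            int uj = vj + dj; if (uj < 0 || uj >= ny) continue;
            for (int di = -sr; di <= sr; ++di) {
              int ui = vi + di; if (ui < 0 || ui >= nx) continue;
              R_xlen_t uq = lin(ui, uj, uk, nx, ny);
              if (use_presel) {
                if (!ratio_ok(smean[sq], tmean[t][uq], presel_thresh)) continue;
                if (!ratio_ok(svar[sq], tvar[t][uq], presel_thresh)) continue;
              }
              bool u_interior = ui >= pr && ui < nx - pr && uj >= pr &&
                                uj < ny - pr && uk >= pr && uk < nz - pr;
              double d = (s_interior && u_interior)
                ? patch_ssd_fast(sub, tv[t], sq, uq, offs)
                : patch_ssd(sub, tv[t], nx, ny, nz,
                            vi, vj, vk, ui, uj, uk, pr);
              cd.push_back(d);
              clab.push_back(lv[t][uq]);
              ctag.push_back(group_tags[t]);
            }
          }
        }
      }
      if (!cd.empty()) break;
      // No candidate survived preselection: retry exhaustively.
      fell_back = true;
    }
    if (cd.empty()) stop("no candidate patches at voxel (empty search window)");

    double dmin = cd[0];
    for (size_t c = 1; c < cd.size(); ++c) if (cd[c] < dmin) dmin = cd[c];
    double h2 = dmin + eps;

    // label votes over a small dense range of codes
    int lmin = clab[0], lmax = clab[0];
    for (size_t c = 1; c < clab.size(); ++c) {
      if (clab[c] < lmin) lmin = clab[c];
      if (clab[c] > lmax) lmax = clab[c];
    }
    std::vector<double> votes(lmax - lmin + 1, 0.0);
    double wtot = 0.0, gsum = 0.0;
    for (size_t c = 0; c < cd.size(); ++c) {
      double w = std::exp(-cd[c] / h2);
      votes[clab[c] - lmin] += w;
      wtot += w;
      gsum += w * (double)ctag[c];
    }
    int best = 0;
    for (size_t l = 1; l < votes.size(); ++l)
      if (votes[l] > votes[best]) best = (int)l;   // ties: lowest code wins
    out_label[q] = best + lmin;
    out_grading[q] = gsum / wtot;
    out_wtot[q] = wtot;
    out_dmin[q] = dmin;
    out_ncand[q] = (int)cd.size();
    out_fallback[q] = fell_back;
  }

  return List::create(_["label"] = out_label, _["grading"] = out_grading,
                      _["total_weight"] = out_wtot, _["min_dist"] = out_dmin,
                      _["n_candidates"] = out_ncand,
                      _["fallback"] = out_fallback);
}

// Binary dilation of a mask by a cube of half-width r.
// [[Rcpp::export(name = ".pg_dilate_cube")]]
LogicalVector pg_dilate_cube(LogicalVector mask, IntegerVector dim, int r) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int* in = LOGICAL(mask);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!in[lin(i, j, k, nx, ny)]) continue;
        for (int dk = -r; dk <= r; ++dk) {
          int kk = k + dk; if (kk < 0 || kk >= nz) continue;
          for (int dj = -r; dj <= r; ++dj) {
            int jj = j + dj; if (jj < 0 || jj >= ny) continue;
            for (int di = -r; di <= r; ++di) {
              int ii = i + di; if (ii < 0 || ii >= nx) continue;
              out[lin(ii, jj, kk, nx, ny)] = TRUE;
            }
          }
        }
      }
  return out;
}
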