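#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Bilinear sample at continuous 0-based voxel coordinates (u, v).
static inline double bilin(const NumericMatrix &img, double u, double v,
                           bool &inside) {
  int nx = img.nrow(), ny = img.ncol();
  if (u < 0.0 || v < 0.0 || u > nx - 1.0 || v > ny - 1.0) {
    inside = false;
    return 0.0;
  }
  inside = true;
  int i0 = (int)std::floor(u), j0 = (int)std::floor(v);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  double fu = u - i0, fv = v - j0;
  return img(i0, j0) * (1 - fu) * (1 - fv) + img(i0 + 1, j0) * fu * (1 - fv) +
         img(i0, j0 + 1) * (1 - fu) * fv + img(i0 + 1, j0 + 1) * fu * fv;
}

// Resample a 2D section under a rigid map T(x) = R(x - c) + c + t acting on
// physical coordinates; out(x) = img(T(x)). Mask is sampled nearest-neighbour.
// [[Rcpp::export]]
List cpp_resample_rigid2d(NumericMatrix img, LogicalMatrix mask, double tx,
                          double ty, double theta_rad, double cx, double cy,
                          double dx, double dy) {
  int nx = img.nrow(), ny = img.ncol();
  NumericMatrix out(nx, ny);
  LogicalMatrix omask(nx, ny);
  double ct = std::cos(theta_rad), st = std::sin(theta_rad);
  bool use_mask = mask.nrow() == nx && mask.ncol() == ny;
  for (int j = 0; j < ny; j++) {
    double y = j * dy - cy;
    for (int i = 0; i < nx; i++) {
      double x = i * dx - cx;
      double px = ct * x - st * y + cx + tx;
      double py = st * x + ct * y + cy + ty;
      double u = px / dx, v = py / dy;
      bool inside;
      out(i, j) = bilin(img, u, v, inside);
      bool m = inside;
      if (inside && use_mask) {
        int iu = (int)std::lround(u), iv = (int)std::lround(v);
        if (iu < 0) iu = 0;
        if (iu > nx - 1) iu = nx - 1;
        if (iv < 0) iv = 0;
        if (iv > ny - 1) iv = ny - 1;
        m = mask(iu, iv);
      }
      omask(i, j) = m;
      if (!m) out(i, j) = out(i, j) * (inside ? 1.0 : 0.0);
    }
  }
  return List::create(_["pixels"] = out, _["mask"] = omask);
}

static inline double trilin(const NumericVector &vol, int nx, int ny, int nz,
                            double u, double v, double w, bool &inside) {
  if (u < 0.0 || v < 0.0 || w < 0.0 || u > nx - 1.0 || v > ny - 1.0 ||
      w > nz - 1.0) {
    inside = false;
    return 0.0;
  }
  inside = true;
  int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  if (nz == 1) k0 = 0;
  double fu = u - i0, fv = v - j0, fw = (nz == 1) ? 0.0 : w - k0;
  int k1 = (nz == 1) ? k0 : k0 + 1;
  size_t sxy = (size_t)nx * ny;
  const double *p = REAL(vol);
  size_t b00 = i0 + (size_t)nx * j0 + sxy * k0;
  size_t b01 = i0 + (size_t)nx * j0 + sxy * k1;
  double c000 = p[b00], c100 = p[b00 + 1];
  double c010 = p[b00 + nx], c110 = p[b00 + nx + 1];
  double c001 = p[b01], c101 = p[b01 + 1];
  double c011 = p[b01 + nx], c111 = p[b01 + nx + 1];
  double c00 = c000 * (1 - fu) + c100 * fu;
  double c10 = c010 * (1 - fu) + c110 * fu;
  double c01 = c001 * (1 - fu) + c101 * fu;
  double c11 = c011 * (1 - fu) + c111 * fu;
  double c0 = c00 * (1 - fv) + c10 * fv;
  double c1 = c01 * (1 - fv) + c11 * fv;
  return c0 * (1 - fw) + c1 * fw;
}

// Backward-map resampling of a 3D volume onto a reference grid.
// Total map T(x) = A (x - c) + c + t + D(x), physical coordinates;
// out(x) = vol(T(x)). disp is a (prod(dim_out) x 3) matrix or empty.
// [[Rcpp::export]]
List cpp_resample_3d(NumericVector vol, LogicalVector mask,
                     IntegerVector dim_in, NumericVector spacing_in,
                     NumericVector origin_in, NumericVector mat,
                     NumericVector trans, NumericVector center,
                     IntegerVector dim_out, NumericVector spacing_out,
                     NumericVector origin_out, NumericMatrix disp) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  size_t n_out = (size_t)ox * oy * oz;
  NumericVector out(n_out);
  LogicalVector omask(n_out);
  bool use_mask = (size_t)mask.size() == (size_t)nx * ny * nz;
  bool use_disp = (size_t)disp.nrow() == n_out;
  const int *mk = use_mask ? LOGICAL(mask) : nullptr;
  double a11 = mat[0], a21 = mat[1], a31 = mat[2];
  double a12 = mat[3], a22 = mat[4], a32 = mat[5];
  double a13 = mat[6], a23 = mat[7], a33 = mat[8];
  size_t idx = 0;
  for (int k = 0; k < oz; k++) {
    double z = origin_out[2] + k * spacing_out[2] - center[2];
    for (int j = 0; j < oy; j++) {
      double y = origin_out[1] + j * spacing_out[1] - center[1];
      for (int i = 0; i < ox; i++, idx++) {
        double x = origin_out[0] + i * spacing_out[0] - center[0];
        double px = a11 * x + a12 * y + a13 * z + center[0] + trans[0];
        double py = a21 * x + a22 * y + a23 * z + center[1] + trans[1];
        double pz = a31 * x + a32 * y + a33 * z + center[2] + trans[2];
        if (use_disp) {
          px += disp(idx, 0);
          py += disp(idx, 1);
          pz += disp(idx, 2);
        }
        double u = (px - origin_in[0]) / spacing_in[0];
        double v = (py - origin_in[1]) / spacing_in[1];
        double w = (pz - origin_in[2]) / spacing_in[2];
        bool inside;
        out[idx] = trilin(vol, nx, ny, nz, u, v, w, inside);
        bool m = inside;
        if (inside && use_mask) {
          int iu = (int)std::lround(u), iv = (int)std::lround(v),
              iw = (int)std::lround(w);
          if (iu < 0) iu = 0;
          if (iu > nx - 1) iu = nx - 1;
          if (iv < 0) iv = 0;
          if (iv > ny - 1) iv = ny - 1;
          if (iw < 0) iw = 0;
          if (iw > nz - 1) iw = nz - 1;
          m = mk[iu + (size_t)nx * iv + (size_t)nx * ny * iw];
        }
        omask[idx] = m;
      }
    }
  }
  out.attr("dim") = dim_out;
  omask.attr("dim") = dim_out;
  return List::create(_["voxels"] = out, _["mask"] = omask);
}

// Connected-component labelling by breadth-first search. dim may have a
// third component of 1 for 2D input. Full-neighbourhood connectivity
// (8 in 2D, 26 in 3D); labels assigned in scan order, so deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_cc(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int *m = LOGICAL(mask);
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; s++) {
    if (!m[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t cur = q.front();
      q.pop();
      int k = cur / ((size_t)nx * ny);
      size_t r = cur % ((size_t)nx * ny);
      int j = r / nx, i = r % nx;
      for (int dk = -1; dk <= 1; dk++) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; dj++) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; di++) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            size_t t = ii + (size_t)nx * jj + (size_t)nx * ny * kk;
            if (m[t] && !lab[t]) {
              lab[t] = next;
              q.push(t);
            }
          }
        }
      }
    }
  }
  if (dim.size() > 2)
    lab.attr("dim") = dim;
  else
    lab.attr("dim") = IntegerVector::create(nx, ny);
  return lab;
}

// Fused resample + masked NCC for the 2D rigid cost: fixed vs moving
// resampled under T. Metric region = fixed_mask (if non-empty) & moving
// field of view. Returns NCC, or NA if the region is degenerate.
// [[Rcpp::export]]
double cpp_ncc_rigid2d(NumericMatrix fixed, LogicalMatrix fixed_mask,
                       NumericMatrix moving, double tx, double ty,
                       double theta_rad, double cx, double cy, double dx,
                       double dy) {
  int nx = fixed.nrow(), ny = fixed.ncol();
  bool use_mask = fixed_mask.nrow() == nx && fixed_mask.ncol() == ny;
  double ct = std::cos(theta_rad), st = std::sin(theta_rad);
  double n = 0, sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  for (int j = 0; j < ny; j++) {
    double y = j * dy - cy;
    for (int i = 0; i < nx; i++) {
      if (use_mask && !fixed_mask(i, j)) continue;
      double x = i * dx - cx;
      double u = (ct * x - st * y + cx + tx) / dx;
      double v = (st * x + ct * y + cy + ty) / dy;
      bool inside;
      // out-of-field reads as background 0, keeping the metric region
      // fixed: no overlap-selection bias, cost continuous in T
      double b = bilin(moving, u, v, inside);
      double a = fixed(i, j);
      n += 1; sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
    }
  }
  if (n < 16) return NA_REAL;
  double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  if (va <= 0 || vb <= 0) return NA_REAL;
  return (sab - sa * sb / n) / std::sqrt(va * vb);
}

// Fused resample + masked NCC for the 3D affine (+ optional dense
// displacement) cost. Metric region = fixed_mask & moving field of view.
// [[Rcpp::export]]
double cpp_ncc_affine3d(NumericVector fixed, LogicalVector fixed_mask,
                        IntegerVector dim_f, NumericVector spacing_f,
                        NumericVector origin_f, NumericVector moving,
                        IntegerVector dim_m, NumericVector spacing_m,
                        NumericVector origin_m, NumericVector mat,
                        NumericVector trans, NumericVector center,
                        NumericMatrix disp) {
  int fx = dim_f[0], fy = dim_f[1], fz = dim_f[2];
  int mx = dim_m[0], my = dim_m[1], mz = dim_m[2];
  size_t n_f = (size_t)fx * fy * fz;
  bool use_mask = (size_t)fixed_mask.size() == n_f;
  bool use_disp = (size_t)disp.nrow() == n_f;
  const int *mk = use_mask ? LOGICAL(fixed_mask) : nullptr;
  double a11 = mat[0], a21 = mat[1], a31 = mat[2];
  double a12 = mat[3], a22 = mat[4], a32 = mat[5];
  double a13 = mat[6], a23 = mat[7], a33 = mat[8];
  double n = 0, sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  size_t idx = 0;
  for (int k = 0; k < fz; k++) {
    double z = origin_f[2] + k * spacing_f[2] - center[2];
    for (int j = 0; j < fy; j++) {
      double y = origin_f[1] + j * spacing_f[1] - center[1];
      for (int i = 0; i < fx; i++, idx++) {
        if (use_mask && !mk[idx]) continue;
        double x = origin_f[0] + i * spacing_f[0] - center[0];
        double px = a11 * x + a12 * y + a13 * z + center[0] + trans[0];
        double py = a21 * x + a22 * y + a23 * z + center[1] + trans[1];
        double pz = a31 * x + a32 * y + a33 * z + center[2] + trans[2];
        if (use_disp) {
          px += disp(idx, 0); py += disp(idx, 1); pz += disp(idx, 2);
        }
        double u = (px - origin_m[0]) / spacing_m[0];
        double v = (py - origin_m[1]) / spacing_m[1];
        double w = (pz - origin_m[2]) / spacing_m[2];
        bool inside;
        double b = trilin(moving, mx, my, mz, u, v, w, inside);
        double a = fixed[idx];
        n += 1; sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
      }
    }
  }
  if (n < 32) return NA_REAL;
  double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  if (va <= 0 || vb <= 0) return NA_REAL;
  return (sab - sa * sb / n) / std::sqrt(va * vb);
}

// Resample a volume and return both the interpolated value and the exact
// spatial gradient of the trilinear interpolant (per physical unit) at
// every output voxel. Out-of-field: value 0, gradient 0.
// [[Rcpp::export]]
List cpp_sample_grad3d(NumericVector vol, IntegerVector dim_in,
                       NumericVector spacing_in, NumericVector origin_in,
                       NumericVector mat, NumericVector trans,
                       NumericVector center, IntegerVector dim_out,
                       NumericVector spacing_out, NumericVector origin_out,
                       NumericMatrix disp) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  size_t n_out = (size_t)ox * oy * oz;
  NumericVector val(n_out), gx(n_out), gy(n_out), gz(n_out);
  LogicalVector omask(n_out);
  bool use_disp = (size_t)disp.nrow() == n_out;
  double a11 = mat[0], a21 = mat[1], a31 = mat[2];
  double a12 = mat[3], a22 = mat[4], a32 = mat[5];
  double a13 = mat[6], a23 = mat[7], a33 = mat[8];
  const double *p = REAL(vol);
  size_t sxy = (size_t)nx * ny;
  size_t idx = 0;
  for (int k = 0; k < oz; k++) {
    double z = origin_out[2] + k * spacing_out[2] - center[2];
    for (int j = 0; j < oy; j++) {
      double y = origin_out[1] + j * spacing_out[1] - center[1];
      for (int i = 0; i < ox; i++, idx++) {
        double x = origin_out[0] + i * spacing_out[0] - center[0];
        double px = a11 * x + a12 * y + a13 * z + center[0] + trans[0];
        double py = a21 * x + a22 * y + a23 * z + center[1] + trans[1];
        double pz = a31 * x + a32 * y + a33 * z + center[2] + trans[2];
        if (use_disp) {
          px += disp(idx, 0); py += disp(idx, 1); pz += disp(idx, 2);
        }
        double u = (px - origin_in[0]) / spacing_in[0];
        double v = (py - origin_in[1]) / spacing_in[1];
        double w = (pz - origin_in[2]) / spacing_in[2];
        if (u < 0 || v < 0 || w < 0 || u > nx - 1.0 || v > ny - 1.0 ||
            w > nz - 1.0) {
          omask[idx] = false;
          continue;
        }
        omask[idx] = true;
        int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
            k0 = (int)std::floor(w);
        if (i0 == nx - 1) i0--;
        if (j0 == ny - 1) j0--;
        if (k0 == nz - 1) k0--;
        if (nz == 1) k0 = 0;
        double fu = u - i0, fv = v - j0, fw = (nz == 1) ? 0.0 : w - k0;
        int k1 = (nz == 1) ? k0 : k0 + 1;
        size_t b00 = i0 + (size_t)nx * j0 + sxy * k0;
        size_t b01 = i0 + (size_t)nx * j0 + sxy * k1;
        double c000 = p[b00], c100 = p[b00 + 1];
        double c010 = p[b00 + nx], c110 = p[b00 + nx + 1];
        double c001 = p[b01], c101 = p[b01 + 1];
        double c011 = p[b01 + nx], c111 = p[b01 + nx + 1];
        double w000 = (1 - fu) * (1 - fv) * (1 - fw),
               w100 = fu * (1 - fv) * (1 - fw),
               w010 = (1 - fu) * fv * (1 - fw), w110 = fu * fv * (1 - fw),
               w001 = (1 - fu) * (1 - fv) * fw, w101 = fu * (1 - fv) * fw,
               w011 = (1 - fu) * fv * fw, w111 = fu * fv * fw;
        val[idx] = c000 * w000 + c100 * w100 + c010 * w010 + c110 * w110 +
                   c001 * w001 + c101 * w101 + c011 * w011 + c111 * w111;
        gx[idx] = ((c100 - c000) * (1 - fv) * (1 - fw) +
                   (c110 - c010) * fv * (1 - fw) +
                   (c101 - c001) * (1 - fv) * fw + (c111 - c011) * fv * fw) /
                  spacing_in[0];
        gy[idx] = ((c010 - c000) * (1 - fu) * (1 - fw) +
                   (c110 - c100) * fu * (1 - fw) +
                   (c011 - c001) * (1 - fu) * fw + (c111 - c101) * fu * fw) /
                  spacing_in[1];
        gz[idx] = (nz == 1) ? 0.0
                            : ((c001 - c000) * (1 - fu) * (1 - fv) +
                               (c101 - c100) * fu * (1 - fv) +
                               (c011 - c010) * (1 - fu) * fv +
                               (c111 - c110) * fu * fv) /
                                  spacing_in[2];
      }
    }
  }
  val.attr("dim") = dim_out;
  omask.attr("dim") = dim_out;
  gx.attr("dim") = dim_out;
  gy.attr("dim") = dim_out;
  gz.attr("dim") = dim_out;
  return List::create(_["value"] = val, _["mask"] = omask, _["gx"] = gx,
                      _["gy"] = gy, _["gz"] = gz);
}
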