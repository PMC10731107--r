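#include <Rcpp.h>
using namespace Rcpp;

// Sampling of a 3D volume at continuous 0-based voxel coordinates.
// interp: 0 = nearest neighbour, 1 = trilinear. Points outside the grid give NA.

static inline double get3(const double* v, int nx, int ny, int i, int j, int k) {
  return v[i + (size_t)nx * (j + (size_t)ny * k)];
}

// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector vol, IntegerVector dim,
                                NumericMatrix pts, int interp) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  const double* v = vol.begin();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (interp == 0) {
      int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
        out[p] = NA_REAL;
      } else {
        out[p] = get3(v, nx, ny, i, j, k);
      }
    } else {
      if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
        out[p] = NA_REAL;
        continue;
      }
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      if (i0 == nx - 1) i0--;
      if (j0 == ny - 1) j0--;
      if (k0 == nz - 1) k0--;
      double fx = x - i0, fy = y - j0, fz = z - k0;
      double c000 = get3(v, nx, ny, i0,     j0,     k0);
      double c100 = get3(v, nx, ny, i0 + 1, j0,     k0);
      double c010 = get3(v, nx, ny, i0,     j0 + 1, k0);
      double c110 = get3(v, nx, ny, i0 + 1, j0 + 1, k0);
      double c001 = get3(v, nx, ny, i0,     j0,     k0 + 1);
      double c101 = get3(v, nx, ny, i0 + 1, j0,     k0 + 1);
      double c011 = get3(v, nx, ny, i0,     j0 + 1, k0 + 1);
      double c111 = get3(v, nx, ny, i0 + 1, j0 + 1, k0 + 1);
      double c00 = c000 * (1 - fx) + c100 * fx;
      double c10 = c010 * (1 - fx) + c110 * fx;
      double c01 = c001 * (1 - fx) + c101 * fx;
      double c11 = c011 * (1 - fx) + c111 * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[p] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

// Mean squared intensity difference between fixed-image samples and the moving
// image sampled at rigidly mapped positions. fixed_pts are world coordinates of
// the fixed samples; the map is x_m = R (x_f - center) + center + trans. Moving
// world -> voxel uses (w - origin) / spacing. Points mapping outside the moving
// grid compare against background (0 HU), so transforms that push structure out
// of the field of view are penalized rather than rewarded; the in-grid count is
// returned alongside the cost.
// [[Rcpp::export]]
NumericVector cpp_rigid_mse(NumericVector mov, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericVector fixed_vals, NumericMatrix fixed_pts,
                            NumericMatrix rot, NumericVector center,
                            NumericVector trans) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = fixed_pts.nrow();
  const double* v = mov.begin();
  double r00 = rot(0, 0), r01 = rot(0, 1), r02 = rot(0, 2);
  double r10 = rot(1, 0), r11 = rot(1, 1), r12 = rot(1, 2);
  double r20 = rot(2, 0), r21 = rot(2, 1), r22 = rot(2, 2);
  double cx = center[0], cy = center[1], cz = center[2];
  double tx = trans[0], ty = trans[1], tz = trans[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double ss = 0.0;
  long nvalid = 0;
  for (int p = 0; p < n; ++p) {
    double dx = fixed_pts(p, 0) - cx, dy = fixed_pts(p, 1) - cy, dz = fixed_pts(p, 2) - cz;
    double wx = r00 * dx + r01 * dy + r02 * dz + cx + tx;
    double wy = r10 * dx + r11 * dy + r12 * dz + cy + ty;
    double wz = r20 * dx + r21 * dy + r22 * dz + cz + tz;
    double x = (wx - ox) / sx, y = (wy - oy) / sy, z = (wz - oz) / sz;
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      ss += fixed_vals[p] * fixed_vals[p];  // moving background beyond the FOV
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = get3(v, nx, ny, i0,     j0,     k0);
    double c100 = get3(v, nx, ny, i0 + 1, j0,     k0);
    double c010 = get3(v, nx, ny, i0,     j0 + 1, k0);
    double c110 = get3(v, nx, ny, i0 + 1, j0 + 1, k0);
    double c001 = get3(v, nx, ny, i0,     j0,     k0 + 1);
    double c101 = get3(v, nx, ny, i0 + 1, j0,     k0 + 1);
    double c011 = get3(v, nx, ny, i0,     j0 + 1, k0 + 1);
    double c111 = get3(v, nx, ny, i0 + 1, j0 + 1, k0 + 1);
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    double m = c0 * (1 - fz) + c1 * fz;
    double d = m - fixed_vals[p];
    ss += d * d;
    ++nvalid;
  }
  NumericVector out(2);
  out[0] = n > 0 ? ss / n : R_PosInf;
  out[1] = (double)nvalid;
  return out;
}

// MSD cost plus analytic gradient with respect to the 6 rigid parameters
// (three ZYX Euler angles in degrees, three translations in mm). dR[k] are
// the derivative matrices dR/d(angle_k) (already in per-degree units),
// flattened column-major into a 9 x 3 matrix.
// [[Rcpp::export]]
NumericVector cpp_rigid_mse_grad(NumericVector mov, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericVector fixed_vals, NumericMatrix fixed_pts,
                                 NumericMatrix rot, NumericMatrix drot,
                                 NumericVector center, NumericVector trans) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = fixed_pts.nrow();
  const double* v = mov.begin();
  double r00 = rot(0, 0), r01 = rot(0, 1), r02 = rot(0, 2);
  double r10 = rot(1, 0), r11 = rot(1, 1), r12 = rot(1, 2);
  double r20 = rot(2, 0), r21 = rot(2, 1), r22 = rot(2, 2);
  double cx = center[0], cy = center[1], cz = center[2];
  double tx = trans[0], ty = trans[1], tz = trans[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double ss = 0.0;
  double g[6] = {0, 0, 0, 0, 0, 0};
  long nvalid = 0;
  for (int p = 0; p < n; ++p) {
    double dx = fixed_pts(p, 0) - cx, dy = fixed_pts(p, 1) - cy, dz = fixed_pts(p, 2) - cz;
    double wx = r00 * dx + r01 * dy + r02 * dz + cx + tx;
    double wy = r10 * dx + r11 * dy + r12 * dz + cy + ty;
    double wz = r20 * dx + r21 * dy + r22 * dz + cz + tz;
    double x = (wx - ox) / sx, y = (wy - oy) / sy, z = (wz - oz) / sz;
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      ss += fixed_vals[p] * fixed_vals[p];  // moving background beyond the FOV
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = get3(v, nx, ny, i0,     j0,     k0);
    double c100 = get3(v, nx, ny, i0 + 1, j0,     k0);
    double c010 = get3(v, nx, ny, i0,     j0 + 1, k0);
    double c110 = get3(v, nx, ny, i0 + 1, j0 + 1, k0);
    double c001 = get3(v, nx, ny, i0,     j0,     k0 + 1);
    double c101 = get3(v, nx, ny, i0 + 1, j0,     k0 + 1);
    double c011 = get3(v, nx, ny, i0,     j0 + 1, k0 + 1);
    double c111 = get3(v, nx, ny, i0 + 1, j0 + 1, k0 + 1);
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    double m = c0 * (1 - fz) + c1 * fz;
    double r = m - fixed_vals[p];
    ss += r * r;
    ++nvalid;
    double dmx = ((c100 - c000) * (1 - fy) + (c110 - c010) * fy) * (1 - fz) +
                 ((c101 - c001) * (1 - fy) + (c111 - c011) * fy) * fz;
    double dmy = ((c010 - c000) * (1 - fx) + (c110 - c100) * fx) * (1 - fz) +
                 ((c011 - c001) * (1 - fx) + (c111 - c101) * fx) * fz;
    double dmz = (c1 - c0);
    double gwx = dmx / sx, gwy = dmy / sy, gwz = dmz / sz;
    g[3] += 2 * r * gwx;
    g[4] += 2 * r * gwy;
    g[5] += 2 * r * gwz;
    for (int k = 0; k < 3; ++k) {
      double ax = drot(0, k) * dx + drot(3, k) * dy + drot(6, k) * dz;
      double ay = drot(1, k) * dx + drot(4, k) * dy + drot(7, k) * dz;
      double az = drot(2, k) * dx + drot(5, k) * dy + drot(8, k) * dz;
      g[k] += 2 * r * (gwx * ax + gwy * ay + gwz * az);
    }
  }
  NumericVector out(8);
  if (n == 0) {
    out[0] = R_PosInf;
    return out;
  }
  out[0] = ss / n;
  for (int k = 0; k < 6; ++k) out[1 + k] = g[k] / n;
  out[7] = (double)nvalid;
  return out;
}
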