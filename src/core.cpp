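#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Volumes are R arrays [nx, ny, nz], column-major; world coordinates are
// x = patient left, y = patient posterior (table side), z = axial.
// Voxel (i,j,k) centre sits at origin + (i,j,k) * spacing (0-based).

// In-plane bilinear sample of slice k at continuous voxel coords (cx, cy).
// Outside the grid the volume is taken as `fill`.
static inline double bilin(const double *v, int nx, int ny, long zoff,
                           double cx, double cy, double fill) {
  if (cx < -0.5 || cx > nx - 0.5 || cy < -0.5 || cy > ny - 0.5) return fill;
  int ix = (int)std::floor(cx), iy = (int)std::floor(cy);
  double fx = cx - ix, fy = cy - iy;
  int ix1 = ix + 1, iy1 = iy + 1;
  double v00 = 0, v10 = 0, v01 = 0, v11 = 0;
  bool bx0 = ix >= 0 && ix < nx, bx1 = ix1 >= 0 && ix1 < nx;
  bool by0 = iy >= 0 && iy < ny, by1 = iy1 >= 0 && iy1 < ny;
  if (bx0 && by0) v00 = v[zoff + ix  + (long)nx * iy];
  if (bx1 && by0) v10 = v[zoff + ix1 + (long)nx * iy];
  if (bx0 && by1) v01 = v[zoff + ix  + (long)nx * iy1];
  if (bx1 && by1) v11 = v[zoff + ix1 + (long)nx * iy1];
  // edge fill: missing corners contribute `fill`
  if (!(bx0 && by0)) v00 = fill;
  if (!(bx1 && by0)) v10 = fill;
  if (!(bx0 && by1)) v01 = fill;
  if (!(bx1 && by1)) v11 = fill;
  return (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
         (1 - fx) * fy * v01 + fx * fy * v11;
}

// Splat val into slice k at continuous voxel coords with bilinear weights
// (exact adjoint of bilin with fill = 0).
static inline void splat(double *v, int nx, int ny, long zoff,
                         double cx, double cy, double val) {
  if (cx < -0.5 || cx > nx - 0.5 || cy < -0.5 || cy > ny - 0.5) return;
  int ix = (int)std::floor(cx), iy = (int)std::floor(cy);
  double fx = cx - ix, fy = cy - iy;
  int ix1 = ix + 1, iy1 = iy + 1;
  bool bx0 = ix >= 0 && ix < nx, bx1 = ix1 >= 0 && ix1 < nx;
  bool by0 = iy >= 0 && iy < ny, by1 = iy1 >= 0 && iy1 < ny;
  if (bx0 && by0) v[zoff + ix  + (long)nx * iy ] += (1 - fx) * (1 - fy) * val;
  if (bx1 && by0) v[zoff + ix1 + (long)nx * iy ] += fx * (1 - fy) * val;
  if (bx0 && by1) v[zoff + ix  + (long)nx * iy1] += (1 - fx) * fy * val;
  if (bx1 && by1) v[zoff + ix1 + (long)nx * iy1] += fx * fy * val;
}

// Clip ray p(t) = r0 + t*d against the in-plane bounding box of the grid.
// Returns false when the ray misses the grid.
static bool clip_ray(double r0x, double r0y, double dx, double dy,
                     double xlo, double xhi, double ylo, double yhi,
                     double &tmin, double &tmax) {
  tmin = -1e30; tmax = 1e30;
  if (std::fabs(dx) < 1e-12) {
    if (r0x < xlo || r0x > xhi) return false;
  } else {
    double t1 = (xlo - r0x) / dx, t2 = (xhi - r0x) / dx;
    if (t1 > t2) std::swap(t1, t2);
    if (t1 > tmin) tmin = t1;
    if (t2 < tmax) tmax = t2;
  }
  if (std::fabs(dy) < 1e-12) {
    if (r0y < ylo || r0y > yhi) return false;
  } else {
    double t1 = (ylo - r0y) / dy, t2 = (yhi - r0y) / dy;
    if (t1 > t2) std::swap(t1, t2);
    if (t1 > tmin) tmin = t1;
    if (t2 < tmax) tmax = t2;
  }
  return tmax > tmin;
}

// Attenuated parallel-beam forward projection, rays confined to transaxial
// planes. Detector at angle theta from anterior, rotating toward patient
// left: ray direction toward detector d = (sin t, -cos t), detector axis
// u = (cos t, sin t). step_mm is the ray sampling interval; mu is in cm^-1.
// Emission weight per sample is step_mm * a * exp(-0.1 * step_mm * cum_mu)
// with the attenuation sum taken from the sample (inclusive) to the detector.
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector act, NumericVector mu,
                                  IntegerVector dim, NumericVector spacing,
                                  NumericVector origin, NumericVector angles_deg,
                                  double det_spacing, int nu,
                                  NumericVector center, double step_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nv = angles_deg.size();
  NumericVector out(Dimension(nu, nz, nv));
  const double *a = act.begin(), *m = mu.begin();
  double *p = out.begin();
  double sx = spacing[0], sy = spacing[1];
  double ox = origin[0], oy = origin[1];
  double xlo = ox - 0.5 * sx, xhi = ox + (nx - 0.5) * sx;
  double ylo = oy - 0.5 * sy, yhi = oy + (ny - 0.5) * sy;
  double mustep = 0.1 * step_mm; // mm -> cm for mu in cm^-1

  for (int v = 0; v < nv; ++v) {
    double th = angles_deg[v] * M_PI / 180.0;
    double dx = std::sin(th), dy = -std::cos(th);
    double ux = std::cos(th), uy = std::sin(th);
    for (int iu = 0; iu < nu; ++iu) {
      double off = (iu - 0.5 * (nu - 1)) * det_spacing;
      double r0x = center[0] + ux * off, r0y = center[1] + uy * off;
      double tmin, tmax;
      if (!clip_ray(r0x, r0y, dx, dy, xlo, xhi, ylo, yhi, tmin, tmax)) continue;
      int nstep = (int)std::ceil((tmax - tmin) / step_mm);
      if (nstep < 1) continue;
      for (int k = 0; k < nz; ++k) {
        long zoff = (long)nx * ny * k;
        double acc = 0.0, sum = 0.0;
        // march from the detector side (t = tmax) inward
        for (int s = 0; s < nstep; ++s) {
          double t = tmax - (s + 0.5) * step_mm;
          if (t < tmin) break;
          double cx = (r0x + t * dx - ox) / sx;
          double cy = (r0y + t * dy - oy) / sy;
          double muv = bilin(m, nx, ny, zoff, cx, cy, 0.0);
          acc += mustep * muv;
          double av = bilin(a, nx, ny, zoff, cx, cy, 0.0);
          if (av > 0) sum += step_mm * av * std::exp(-acc);
        }
        p[iu + (long)nu * k + (long)nu * nz * v] = sum;
      }
    }
  }
  return out;
}

// Exact adjoint of cpp_forward_project for the view subset supplied:
// back-projects per-ray values with the same attenuated bilinear weights.
// [[Rcpp::export]]
NumericVector cpp_back_project(NumericVector proj, NumericVector mu,
                               IntegerVector dim, NumericVector spacing,
                               NumericVector origin, NumericVector angles_deg,
                               double det_spacing, int nu,
                               NumericVector center, double step_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nv = angles_deg.size();
  NumericVector out(Dimension(nx, ny, nz));
  const double *m = mu.begin(), *p = proj.begin();
  double *vol = out.begin();
  double sx = spacing[0], sy = spacing[1];
  double ox = origin[0], oy = origin[1];
  double xlo = ox - 0.5 * sx, xhi = ox + (nx - 0.5) * sx;
  double ylo = oy - 0.5 * sy, yhi = oy + (ny - 0.5) * sy;
  double mustep = 0.1 * step_mm;

  for (int v = 0; v < nv; ++v) {
    double th = angles_deg[v] * M_PI / 180.0;
    double dx = std::sin(th), dy = -std::cos(th);
    double ux = std::cos(th), uy = std::sin(th);
    for (int iu = 0; iu < nu; ++iu) {
      double off = (iu - 0.5 * (nu - 1)) * det_spacing;
      double r0x = center[0] + ux * off, r0y = center[1] + uy * off;
      double tmin, tmax;
      if (!clip_ray(r0x, r0y, dx, dy, xlo, xhi, ylo, yhi, tmin, tmax)) continue;
      int nstep = (int)std::ceil((tmax - tmin) / step_mm);
      if (nstep < 1) continue;
      for (int k = 0; k < nz; ++k) {
        long zoff = (long)nx * ny * k;
        double val = p[iu + (long)nu * k + (long)nu * nz * v];
        double acc = 0.0;
        for (int s = 0; s < nstep; ++s) {
          double t = tmax - (s + 0.5) * step_mm;
          if (t < tmin) break;
          double cx = (r0x + t * dx - ox) / sx;
          double cy = (r0y + t * dy - oy) / sy;
          double muv = bilin(m, nx, ny, zoff, cx, cy, 0.0);
          acc += mustep * muv;
          if (val != 0)
            splat(vol, nx, ny, zoff, cx, cy, val * step_mm * std::exp(-acc));
        }
      }
    }
  }
  return out;
}

// Trilinear resampling under an affine map: output voxel with world position
// q is sampled from the source volume at world point A %*% q + b.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector sdim,
                                  NumericVector sspacing, NumericVector sorigin,
                                  IntegerVector tdim, NumericVector tspacing,
                                  NumericVector torigin, NumericMatrix A,
                                  NumericVector b, double fill) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int mx = tdim[0], my = tdim[1], mz = tdim[2];
  NumericVector out(Dimension(mx, my, mz));
  const double *s = src.begin();
  double *o = out.begin();
  for (int k = 0; k < mz; ++k) {
    double qz = torigin[2] + k * tspacing[2];
    for (int j = 0; j < my; ++j) {
      double qy = torigin[1] + j * tspacing[1];
      for (int i = 0; i < mx; ++i) {
        double qx = torigin[0] + i * tspacing[0];
        double px = A(0,0)*qx + A(0,1)*qy + A(0,2)*qz + b[0];
        double py = A(1,0)*qx + A(1,1)*qy + A(1,2)*qz + b[1];
        double pz = A(2,0)*qx + A(2,1)*qy + A(2,2)*qz + b[2];
        double cx = (px - sorigin[0]) / sspacing[0];
        double cy = (py - sorigin[1]) / sspacing[1];
        double cz = (pz - sorigin[2]) / sspacing[2];
        double val = fill;
        if (cx >= 0 && cx <= nx - 1 && cy >= 0 && cy <= ny - 1 &&
            cz >= 0 && cz <= nz - 1) {
          int ix = (int)std::floor(cx), iy = (int)std::floor(cy),
              iz = (int)std::floor(cz);
          if (ix == nx - 1) ix--; if (iy == ny - 1) iy--; if (iz == nz - 1) iz--;
          double fx = cx - ix, fy = cy - iy, fz = cz - iz;
          long i000 = ix + (long)nx * (iy + (long)ny * iz);
          long dxs = 1, dys = nx, dzs = (long)nx * ny;
          double c00 = s[i000] * (1-fx) + s[i000+dxs] * fx;
          double c10 = s[i000+dys] * (1-fx) + s[i000+dys+dxs] * fx;
          double c01 = s[i000+dzs] * (1-fx) + s[i000+dzs+dxs] * fx;
          double c11 = s[i000+dzs+dys] * (1-fx) + s[i000+dzs+dys+dxs] * fx;
          val = (c00*(1-fy) + c10*fy) * (1-fz) + (c01*(1-fy) + c11*fy) * fz;
        }
        o[i + (long)mx * (j + (long)my * k)] = val;
      }
    }
  }
  return out;
}

// 2-D connected-component labelling of a logical matrix, 4- or 8-connectivity.
// Labels are 1..n in first-encounter (column-major) order; background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int> > nb;
  nb.push_back(std::make_pair(-1, 0)); nb.push_back(std::make_pair(1, 0));
  nb.push_back(std::make_pair(0, -1)); nb.push_back(std::make_pair(0, 1));
  if (connectivity == 8) {
    nb.push_back(std::make_pair(-1, -1)); nb.push_back(std::make_pair(-1, 1));
    nb.push_back(std::make_pair(1, -1));  nb.push_back(std::make_pair(1, 1));
  }
  int cur = 0;
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    if (!mask(r, c) || lab(r, c)) continue;
    ++cur;
    std::queue<std::pair<int,int> > q;
    q.push(std::make_pair(r, c));
    lab(r, c) = cur;
    while (!q.empty()) {
      std::pair<int,int> p = q.front(); q.pop();
      for (size_t t = 0; t < nb.size(); ++t) {
        int rr = p.first + nb[t].first, cc = p.second + nb[t].second;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (mask(rr, cc) && !lab(rr, cc)) {
          lab(rr, cc) = cur;
          q.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return lab;
}
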