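// Synthetic depth-frame renderer: per-pixel ray marching against a canopy
// height field over an infinite flat ground plane. The surface seen by a
// ray is z = H(x, y) inside the grid (nodata cells fall back to the ground
// elevation) and z = ground outside it. Returns Euclidean range along the
// ray, NA where the ray misses within [min_range, max_range].

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

inline double surf_z(const NumericMatrix& H, double x0, double y0,
                     double cell, double ground, double px, double py) {
  int i = (int)std::floor((px - x0) / cell);
  int j = (int)std::floor((py - y0) / cell);
  if (i < 0 || j < 0 || i >= H.ncol() || j >= H.nrow()) return ground;
  double h = H(j, i);  // rows index y, cols index x
  return R_finite(h) ? h : ground;
}

}  // namespace

// [[Rcpp::export(name = ".render_heightfield")]]
NumericMatrix render_heightfield_cpp(NumericMatrix H, double x0, double y0,
                                     double cell, double ground,
                                     NumericVector intr, NumericMatrix Rmat,
                                     NumericVector tvec, int width, int height,
                                     double min_range, double max_range) {
  const double fx = intr[0], fy = intr[1], cx = intr[2], cy = intr[3];
  NumericMatrix out(height, width);
  std::fill(out.begin(), out.end(), NA_REAL);
  const double step = 0.5 * cell;
  double z_top = ground;
  for (int i = 0; i < H.length(); ++i)
    if (R_finite(H[i]) && H[i] > z_top) z_top = H[i];

  for (int v = 0; v < height; ++v) {
    for (int u = 0; u < width; ++u) {
      double dx = (u - cx) / fx, dy = (v - cy) / fy, dz = 1.0;
      double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
      dx /= nrm; dy /= nrm; dz /= nrm;
      double wd[3] = {Rmat(0, 0) * dx + Rmat(0, 1) * dy + Rmat(0, 2) * dz,
                      Rmat(1, 0) * dx + Rmat(1, 1) * dy + Rmat(1, 2) * dz,
                      Rmat(2, 0) * dx + Rmat(2, 1) * dy + Rmat(2, 2) * dz};
      double o[3] = {tvec[0], tvec[1], tvec[2]};

      // the surface lives in z within [ground, z_top]: clip the march to
      // that band (the camera is assumed above the canopy)
      double t_start = step, t_stop = max_range;
      if (wd[2] < -1e-12) {
        double te = (z_top - o[2]) / wd[2];      // enter the band
        double tg = (ground - o[2]) / wd[2];     // reach the ground plane
        if (te > t_start) t_start = std::floor(te / step) * step;
        if (tg + 2 * step < t_stop) t_stop = tg + 2 * step;
      } else if (o[2] > z_top) {
        continue;  // upward ray from above the surface: no hit
      }
      double t_prev = t_start - step;
      bool below_prev = false;
      bool found = false;
      // coarse march so occlusions are honoured; only hits inside
      // [min_range, max_range] are reported
      for (double t = t_start; t <= t_stop; t += step) {
        double px = o[0] + wd[0] * t, py = o[1] + wd[1] * t,
               pz = o[2] + wd[2] * t;
        bool below = pz <= surf_z(H, x0, y0, cell, ground, px, py);
        if (below && !below_prev) {
          // refine by bisection on the crossing interval
          double ta = t_prev, tb = t;
          for (int it = 0; it < 40; ++it) {
            double tm = 0.5 * (ta + tb);
            double qx = o[0] + wd[0] * tm, qy = o[1] + wd[1] * tm,
                   qz = o[2] + wd[2] * tm;
            if (qz <= surf_z(H, x0, y0, cell, ground, qx, qy)) tb = tm;
            else ta = tm;
          }
          double thit = 0.5 * (ta + tb);
          if (thit >= min_range && thit <= max_range) out(v, u) = thit;
          found = true;
          break;
        }
        below_prev = below;
        t_prev = t;
      }
      (void)found;
    }
  }
  return out;
}
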