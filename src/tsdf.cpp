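// Hashed truncated-signed-distance (TSDF) volume: sparse voxel storage
// addressed by a large-prime XOR spatial hash (chained buckets via
// std::unordered_map), projective integration of depth frames along pixel
// rays, Amanatides-Woo ray casting against the stored band, and surface
// extraction at signed-distance zero crossings.

#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int64_t pack_key(int x, int y, int z) {
  // 21 bits per axis, offset to keep coordinates positive
  const int64_t off = 1 << 20;
  return (((int64_t)(x + off)) << 42) | (((int64_t)(y + off)) << 21) |
         ((int64_t)(z + off));
}
inline void unpack_key(int64_t k, int& x, int& y, int& z) {
  const int64_t off = 1 << 20;
  x = (int)((k >> 42) & 0x1FFFFF) - (int)off;
  y = (int)((k >> 21) & 0x1FFFFF) - (int)off;
  z = (int)(k & 0x1FFFFF) - (int)off;
}

struct PrimeXorHash {
  size_t operator()(const int64_t& k) const {
    int x, y, z;
    unpack_key(k, x, y, z);
    return (size_t)((x * 73856093) ^ (y * 19349669) ^ (z * 83492791));
  }
};

struct Voxel { double d; double w; };

struct TSDF {
  double voxel;
  double trunc;
  std::unordered_map<int64_t, Voxel, PrimeXorHash> map;
};

inline TSDF* get_vol(SEXP xp) {
  Rcpp::XPtr<TSDF> p(xp);
  return p.get();
}

}  // namespace

// [[Rcpp::export(name = ".tsdf_create")]]
SEXP tsdf_create_cpp(double voxel_size, double truncation) {
  TSDF* v = new TSDF();
  v->voxel = voxel_size;
  v->trunc = truncation;
  Rcpp::XPtr<TSDF> p(v, true);
  return p;
}

// [[Rcpp::export(name = ".tsdf_params")]]
NumericVector tsdf_params_cpp(SEXP xp) {
  TSDF* v = get_vol(xp);
  return NumericVector::create(_["voxel_size"] = v->voxel,
                               _["truncation"] = v->trunc,
                               _["n_voxels"] = (double)v->map.size());
}

// Integrate one depth frame. `ranges` is height x width (rows = pixel v),
// NA marks invalid pixels. R (3x3) and t map camera coords into world.
// Camera model: pixel (u,v) ray direction ((u-cx)/fx, (v-cy)/fy, 1), 0-based.
// Every voxel crossed by a ray within +/- truncation of the measured range
// receives one weighted running-average update per frame.
// [[Rcpp::export(name = ".tsdf_integrate")]]
void tsdf_integrate_cpp(SEXP xp, NumericMatrix ranges, NumericVector intr,
                        NumericMatrix Rmat, NumericVector tvec) {
  TSDF* vol = get_vol(xp);
  const int h = ranges.nrow(), w = ranges.ncol();
  const double fx = intr[0], fy = intr[1], cx = intr[2], cy = intr[3];
  const double vs = vol->voxel, tr = vol->trunc;
  const double step = vs * 0.5;

  for (int v = 0; v < h; ++v) {
    for (int u = 0; u < w; ++u) {
      double r = ranges(v, u);
      if (!R_finite(r)) continue;
      double dx = (u - cx) / fx, dy = (v - cy) / fy, dz = 1.0;
      double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
      dx /= nrm; dy /= nrm; dz /= nrm;
      // world-frame direction and origin
      double wx = Rmat(0, 0) * dx + Rmat(0, 1) * dy + Rmat(0, 2) * dz;
      double wy = Rmat(1, 0) * dx + Rmat(1, 1) * dy + Rmat(1, 2) * dz;
      double wz = Rmat(2, 0) * dx + Rmat(2, 1) * dy + Rmat(2, 2) * dz;
      double ox = tvec[0], oy = tvec[1], oz = tvec[2];

      double t0 = r - tr, t1 = r + tr;
      if (t0 < 0) t0 = 0;
      int64_t last_key = INT64_MIN;
      for (double t = t0; t <= t1 + 1e-12; t += step) {
        double px = ox + wx * t, py = oy + wy * t, pz = oz + wz * t;
        int ix = (int)std::floor(px / vs);
        int iy = (int)std::floor(py / vs);
        int iz = (int)std::floor(pz / vs);
        int64_t key = pack_key(ix, iy, iz);
        if (key == last_key) continue;  // one update per voxel per ray
        last_key = key;
        // signed distance at the voxel CENTER projected onto the ray, not
        // at the (quantized) sample position: keeps the stored field an
        // exact linear ramp along the ray
        double tc = ((ix + 0.5) * vs - ox) * wx + ((iy + 0.5) * vs - oy) * wy +
                    ((iz + 0.5) * vs - oz) * wz;
        double sdf = r - tc;
        if (sdf > tr) sdf = tr; else if (sdf < -tr) sdf = -tr;
        Voxel& vx = vol->map[key];
        vx.d = (vx.d * vx.w + sdf) / (vx.w + 1.0);
        vx.w += 1.0;
      }
    }
  }
}

// [[Rcpp::export(name = ".tsdf_data")]]
DataFrame tsdf_data_cpp(SEXP xp) {
  TSDF* vol = get_vol(xp);
  size_t n = vol->map.size();
  IntegerVector ix(n), iy(n), iz(n);
  NumericVector d(n), w(n);
  size_t i = 0;
  for (const auto& kv : vol->map) {
    int x, y, z;
    unpack_key(kv.first, x, y, z);
    ix[i] = x; iy[i] = y; iz[i] = z;
    d[i] = kv.second.d; w[i] = kv.second.w;
    ++i;
  }
  return DataFrame::create(_["ix"] = ix, _["iy"] = iy, _["iz"] = iz,
                           _["sdf"] = d, _["weight"] = w);
}

// Ray casting: per pixel, walk the voxel grid (Amanatides-Woo traversal)
// between min_range and max_range, detect the first +/- sign change of the
// stored signed distance, and return the interpolated zero-crossing range.
// Returns list(range = h x w matrix with NA misses, points = k x 3 world
// coords of the predicted surface samples).
// [[Rcpp::export(name = ".tsdf_raycast")]]
List tsdf_raycast_cpp(SEXP xp, NumericVector intr, NumericMatrix Rmat,
                      NumericVector tvec, int width, int height,
                      double min_range, double max_range) {
  TSDF* vol = get_vol(xp);
  const double fx = intr[0], fy = intr[1], cx = intr[2], cy = intr[3];
  const double vs = vol->voxel;
  NumericMatrix out(height, width);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> ptx, pty, ptz;

  // bounding box of allocated voxels (world units) to clip the walk
  if (vol->map.empty())
    return List::create(_["range"] = out,
                        _["points"] = NumericMatrix(0, 3));
  double blo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double bhi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (const auto& kv : vol->map) {
    int c[3];
    unpack_key(kv.first, c[0], c[1], c[2]);
    for (int j = 0; j < 3; ++j) {
      double lo = c[j] * vs, hi = (c[j] + 1) * vs;
      if (lo < blo[j]) blo[j] = lo;
      if (hi > bhi[j]) bhi[j] = hi;
    }
  }

  for (int v = 0; v < height; ++v) {
    for (int u = 0; u < width; ++u) {
      double dx = (u - cx) / fx, dy = (v - cy) / fy, dz = 1.0;
      double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
      dx /= nrm; dy /= nrm; dz /= nrm;
      double wd[3] = {Rmat(0, 0) * dx + Rmat(0, 1) * dy + Rmat(0, 2) * dz,
                      Rmat(1, 0) * dx + Rmat(1, 1) * dy + Rmat(1, 2) * dz,
                      Rmat(2, 0) * dx + Rmat(2, 1) * dy + Rmat(2, 2) * dz};
      double o[3] = {tvec[0], tvec[1], tvec[2]};

      // clip [t_enter, t_exit] to the allocated bounding box
      double t0 = min_range, t1 = max_range;
      bool miss = false;
      for (int j = 0; j < 3 && !miss; ++j) {
        if (std::fabs(wd[j]) < 1e-12) {
          if (o[j] < blo[j] || o[j] > bhi[j]) miss = true;
        } else {
          double ta = (blo[j] - o[j]) / wd[j];
          double tb = (bhi[j] - o[j]) / wd[j];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
        }
      }
      if (miss || t0 >= t1) continue;

      // Amanatides-Woo walk from t0 to t1
      double sx = o[0] + wd[0] * t0, sy = o[1] + wd[1] * t0,
             sz = o[2] + wd[2] * t0;
      int ix = (int)std::floor(sx / vs), iy = (int)std::floor(sy / vs),
          iz = (int)std::floor(sz / vs);
      int stepv[3];
      double tMax[3], tDelta[3];
      int cell[3] = {ix, iy, iz};
      for (int j = 0; j < 3; ++j) {
        if (wd[j] > 1e-15) {
          stepv[j] = 1;
          tMax[j] = t0 + ((cell[j] + 1) * vs - (o[j] + wd[j] * t0)) / wd[j];
          tDelta[j] = vs / wd[j];
        } else if (wd[j] < -1e-15) {
          stepv[j] = -1;
          tMax[j] = t0 + (cell[j] * vs - (o[j] + wd[j] * t0)) / wd[j];
          tDelta[j] = -vs / wd[j];
        } else {
          stepv[j] = 0;
          tMax[j] = R_PosInf;
          tDelta[j] = R_PosInf;
        }
      }
      double t_prev_mid = NA_REAL, d_prev = NA_REAL;
      double t_cur = t0;
      bool hit = false;
      while (t_cur <= t1 && !hit) {
        // exit parameter of current voxel
        int jm = 0;
        if (tMax[1] < tMax[jm]) jm = 1;
        if (tMax[2] < tMax[jm]) jm = 2;
        double t_exit = tMax[jm];
        double t_mid = 0.5 * (t_cur + std::min(t_exit, t1));
        auto it = vol->map.find(pack_key(cell[0], cell[1], cell[2]));
        if (it != vol->map.end() && it->second.w > 0) {
          double d_cur = it->second.d;
          if (R_finite(d_prev) && d_prev > 0 && d_cur <= 0) {
            double tz = t_prev_mid +
                        (t_mid - t_prev_mid) * d_prev / (d_prev - d_cur);
            out(v, u) = tz;
            ptx.push_back(o[0] + wd[0] * tz);
            pty.push_back(o[1] + wd[1] * tz);
            ptz.push_back(o[2] + wd[2] * tz);
            hit = true;
            break;
          }
          d_prev = d_cur;
          t_prev_mid = t_mid;
        } else if (R_finite(t_prev_mid) &&
                   t_cur - t_prev_mid > 2.0 * vs) {
          d_prev = NA_REAL;  // band interrupted: restart sign tracking
        }
        cell[jm] += stepv[jm];
        t_cur = t_exit;
        tMax[jm] += tDelta[jm];
      }
    }
  }
  size_t np = ptx.size();
  NumericMatrix pts(np, 3);
  for (size_t i = 0; i < np; ++i) {
    pts(i, 0) = ptx[i]; pts(i, 1) = pty[i]; pts(i, 2) = ptz[i];
  }
  return List::create(_["range"] = out, _["points"] = pts);
}

// Surface extraction: one point per zero crossing between face-adjacent
// voxels of opposite sign, linearly interpolated between voxel centers.
// [[Rcpp::export(name = ".tsdf_extract")]]
NumericMatrix tsdf_extract_cpp(SEXP xp, double min_weight = 1.0,
                               double max_step = -1.0) {
  TSDF* vol = get_vol(xp);
  const double vs = vol->voxel;
  const double tr = vol->trunc;
  // a true signed-distance field changes by at most the voxel pitch
  // between face neighbours; crossings violating that (or sitting at the
  // clamp) are silhouette artifacts, not surface
  if (max_step < 0) max_step = 2.0 * vs;
  std::vector<double> px, py, pz;
  const int dirs[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (const auto& kv : vol->map) {
    if (kv.second.w < min_weight) continue;
    double d1 = kv.second.d;
    int c[3];
    unpack_key(kv.first, c[0], c[1], c[2]);
    for (int k = 0; k < 3; ++k) {
      auto it = vol->map.find(
          pack_key(c[0] + dirs[k][0], c[1] + dirs[k][1], c[2] + dirs[k][2]));
      if (it == vol->map.end() || it->second.w < min_weight) continue;
      double d2 = it->second.d;
      if (std::fabs(d1) >= 0.99 * tr || std::fabs(d2) >= 0.99 * tr) continue;
      if (std::fabs(d1 - d2) > max_step) continue;
      if ((d1 > 0 && d2 <= 0) || (d1 <= 0 && d2 > 0)) {
        double f = (d1 == d2) ? 0.5 : d1 / (d1 - d2);
        double a[3];
        for (int j = 0; j < 3; ++j)
          a[j] = (c[j] + 0.5 + f * dirs[k][j]) * vs;
        px.push_back(a[0]); py.push_back(a[1]); pz.push_back(a[2]);
      }
    }
  }
  size_t n = px.size();
  NumericMatrix out(n, 3);
  for (size_t i = 0; i < n; ++i) {
    out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i];
  }
  return out;
}
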