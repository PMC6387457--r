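# fixture builders shared across the suite (all generated in code)

# regular planar grid (z = 0), n x n, unit spacing by default
grid_cloud <- function(n = 10, spacing = 1, z = 0) {
  g <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  point_cloud(cbind(g$x * spacing, g$y * spacing, z))
}

# unit-cube corners plus face and edge midpoints (27 highly degenerate pts)
cube_fixture <- function(origin = c(0, 0, 0)) {
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  edges <- NULL
  for (i in 1:7) for (j in (i + 1):8) {
    if (sum(abs(corners[i, ] - corners[j, ])) == 1)
      edges <- rbind(edges, (corners[i, ] + corners[j, ]) / 2)
  }
  faces <- rbind(c(.5, .5, 0), c(.5, .5, 1), c(.5, 0, .5),
                 c(.5, 1, .5), c(0, .5, .5), c(1, .5, .5))
  m <- rbind(corners, edges, faces)
  point_cloud(sweep(m, 2, origin, "+"))
}

# points uniform on and inside a ball of radius r (half on the surface)
ball_fixture <- function(n, r = 0.5, seed = 42) {
  set.seed(seed)
  n_surf <- n %/% 2
  u <- matrix(rnorm(3 * n_surf), n_surf, 3)
  surf <- u / sqrt(rowSums(u^2)) * r
  u2 <- matrix(rnorm(3 * (n - n_surf)), n - n_surf, 3)
  inner <- u2 / sqrt(rowSums(u2^2)) * (r * runif(n - n_surf)^(1 / 3))
  point_cloud(rbind(surf, inner))
}

# dense flat square cloud spanning [0, side]^2 at height z
flat_cloud <- function(side = 1, z = 0, spacing = 0.01) {
  g <- expand.grid(x = seq(0, side, by = spacing),
                   y = seq(0, side, by = spacing))
  point_cloud(cbind(g$x, g$y, z))
}

# rotation matrix from an axis-angle
rot_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# rotation matrix from a unit quaternion (w, x, y, z)
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# brute-force least-squares rigid alignment over unit quaternions
quaternion_align_oracle <- function(source, target) {
  obj <- function(q) {
    R <- quat_to_rot(q)
    tv <- colMeans(target) - as.vector(R %*% colMeans(source))
    moved <- sweep(source %*% t(R), 2, tv, "+")
    sum((moved - target)^2)
  }
  best <- NULL
  for (start in list(c(1, 0, 0, 0), c(0.5, 0.5, 0.5, 0.5),
                     c(0.7, -0.3, 0.4, 0.1))) {
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  R <- quat_to_rot(best$par)
  list(R = R, t = colMeans(target) - as.vector(R %*% colMeans(source)),
       value = best$value)
}

# python + scipy oracle for Delaunay-based alpha volumes (tiny fixtures)
scipy_alpha_volume_oracle <- function(coords, alpha) {
  inp <- tempfile(fileext = ".csv")
  utils::write.table(coords, inp, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  script <- sprintf("
import numpy as np
from scipy.spatial import Delaunay
pts = np.loadtxt(%s, delimiter=',')
tri = Delaunay(pts)
vol = 0.0
for simp in tri.simplices:
    p = pts[simp]
    A = np.vstack([p[1]-p[0], p[2]-p[0], p[3]-p[0]])
    v = abs(np.linalg.det(A)) / 6.0
    # circumradius
    B = 2*(p[1:] - p[0])
    rhs = (p[1:]**2).sum(1) - (p[0]**2).sum()
    try:
        c = np.linalg.solve(B, rhs)
    except np.linalg.LinAlgError:
        continue
    r = np.linalg.norm(c - p[0])
    if r < %.17g:
        vol += v
print(float(vol))
", deparse(inp), alpha)
  out <- system2("python", "-", input = script, stdout = TRUE)
  as.numeric(out[length(out)])
}
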