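#' 3D alpha-shape volume of a point cloud
#'
#' Builds the 3D Delaunay tetrahedralization of the cloud, keeps the
#' tetrahedra whose circumscribing sphere radius is below `alpha`, and
#' returns the summed volume of the kept tetrahedra (the standard alpha
#' complex). Small `alpha` yields a tight body hugging the points; as
#' `alpha` grows the volume increases monotonically toward the convex-hull
#' volume.
#'
#' Near-degenerate (coplanar/cospherical) inputs are handled by a fixed
#' symbolic jitter of 1e-9 (relative) applied only to the combinatorial
#' build; volumes are evaluated on the original coordinates, so the
#' convex-hull limit is exact even for degenerate fixtures.
#'
#' @param cloud a [point_cloud()] with at least 4 affinely independent
#'   points.
#' @param alpha radius parameter, m (> 0); `Inf` gives the convex hull.
#' @param seed seed of the jitter stream (fixed default for determinism).
#' @return an object of class `alpha_shape_result`: list with `alpha`,
#'   `volume` (m3), `n_tetrahedra` (kept), `n_boundary_triangles`, and
#'   `hull_volume` (m3, the alpha -> Inf limit).
#' @export
alpha_shape_volume <- function(cloud, alpha = 0.2, seed = 1) {
  if (!is.infinite(alpha) && alpha <= 0) stop("alpha must be > 0")
  m <- unclass(point_cloud(cloud))
  if (nrow(m) < 4)
    stop("degenerate input: alpha shape needs at least 4 points")
  sv <- svd(sweep(m, 2, colMeans(m)), nu = 0, nv = 0)$d
  if (sv[3] < 1e-12 * max(sv[1], 1e-300))
    stop("degenerate input: points are coplanar (no 3D volume)")
  dt <- .delaunay3d(m, seed = seed, jitter = 1e-9)
  # degenerate originals can yield ~1e-18-signed slivers; clamp so the
  # volume is exactly non-decreasing in alpha
  vol <- pmax(dt$volume, 0)
  keep <- if (is.infinite(alpha)) rep(TRUE, length(vol)) else
    dt$circumradius < alpha
  n_boundary <- .count_boundary_triangles(dt$vertices[keep, , drop = FALSE])
  structure(list(alpha = alpha,
                 volume = max(0, sum(vol[keep])),
                 n_tetrahedra = sum(keep),
                 n_boundary_triangles = n_boundary,
                 hull_volume = max(0, sum(vol))),
            class = "alpha_shape_result")
}

#' @export
print.alpha_shape_result <- function(x, ...) {
  cat(sprintf(
    "alpha_shape_result: alpha %.3g m, volume %.5g m3 (hull %.5g m3)\n",
    x$alpha, x$volume, x$hull_volume))
  cat(sprintf("  %d tetrahedra kept, %d boundary triangles\n",
              x$n_tetrahedra, x$n_boundary_triangles))
  invisible(x)
}

# faces used by exactly one kept tetrahedron
.count_boundary_triangles <- function(verts) {
  if (nrow(verts) == 0) return(0L)
  faces <- rbind(verts[, c(1, 2, 3), drop = FALSE],
                 verts[, c(1, 2, 4), drop = FALSE],
                 verts[, c(1, 3, 4), drop = FALSE],
                 verts[, c(2, 3, 4), drop = FALSE])
  faces <- t(apply(faces, 1, sort))
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  sum(table(key) == 1L)
}

#' Raw Delaunay tetrahedralization
#'
#' Low-level access to the incremental Bowyer-Watson build behind
#' [alpha_shape_volume()].
#'
#' @param cloud a [point_cloud()] (>= 4 points).
#' @param seed jitter stream seed.
#' @return list with `vertices` (tetrahedra x 4, 1-based point indices),
#'   `volume` (signed, build orientation; m3) and `circumradius` (m).
#' @export
delaunay_tetrahedra <- function(cloud, seed = 1) {
  m <- unclass(point_cloud(cloud))
  .delaunay3d(m, seed = seed, jitter = 1e-9)
}
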