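#' Create a hashed TSDF volume
#'
#' Sparse truncated-signed-distance voxel store addressed by a large-prime
#' XOR spatial hash. Only voxels within the truncation band of an observed
#' surface are ever allocated.
#'
#' @param voxel_size voxel edge length, m (default 5 mm: preserves
#'   grass-blade scale on a 1 m2 plot at tractable memory).
#' @param truncation truncation distance, m (default 4 voxel sizes).
#' @return an object of class `tsdf_volume` (external pointer).
#' @export
tsdf_volume <- function(voxel_size = 0.005, truncation = 4 * voxel_size) {
  if (voxel_size <= 0 || truncation <= 0)
    stop("voxel_size and truncation must be > 0")
  ptr <- .tsdf_create(voxel_size, truncation)
  structure(list(ptr = ptr, voxel_size = voxel_size, truncation = truncation),
            class = "tsdf_volume")
}

#' @export
print.tsdf_volume <- function(x, ...) {
  p <- .tsdf_params(x$ptr)
  cat(sprintf("tsdf_volume: voxel %.3g m, truncation %.3g m, %d voxels\n",
              p[["voxel_size"]], p[["truncation"]], as.integer(p[["n_voxels"]])))
  invisible(x)
}

#' Number of allocated voxels
#' @param volume a [tsdf_volume()].
#' @return integer count.
#' @export
tsdf_size <- function(volume) as.integer(.tsdf_params(volume$ptr)[["n_voxels"]])

#' Allocated voxels as a data frame
#'
#' @param volume a [tsdf_volume()].
#' @return data frame with integer voxel coordinates `ix, iy, iz`, the
#'   stored signed distance `sdf` (m) and the accumulated `weight`.
#' @export
tsdf_data <- function(volume) .tsdf_data(volume$ptr)

#' Integrate a depth frame into a TSDF volume
#'
#' For every valid pixel, each voxel crossed by the pixel ray within the
#' truncation band of the measured range receives one weighted
#' running-average signed-distance update; voxels outside every band are
#' never allocated. Modifies the volume in place and returns it.
#'
#' @param volume a [tsdf_volume()].
#' @param frame a depth frame (list with `range` matrix).
#' @param pose a [rigid_pose()] mapping camera to world coordinates.
#' @param intrinsics a [camera_intrinsics()] matching the frame size.
#' @return the volume, invisibly.
#' @export
integrate_frame <- function(volume, frame, pose, intrinsics) {
  rng <- frame$range
  if (nrow(rng) != intrinsics$height || ncol(rng) != intrinsics$width)
    stop("frame dimensions (", nrow(rng), " x ", ncol(rng),
         ") do not match intrinsics (", intrinsics$height, " x ",
         intrinsics$width, ")")
  .tsdf_integrate(volume$ptr, rng, .intr_vec(intrinsics), pose$R, pose$t)
  invisible(volume)
}

#' Ray-cast a TSDF volume from a camera pose
#'
#' Marches every pixel ray through the voxel grid (integer Amanatides-Woo
#' traversal), detects the first positive-to-negative sign change of the
#' stored signed distance and returns the interpolated zero-crossing range.
#' Pixels whose ray never crosses a stored band are invalid.
#'
#' @param volume a [tsdf_volume()].
#' @param pose a [rigid_pose()].
#' @param intrinsics a [camera_intrinsics()].
#' @return list with `range` (predicted depth frame matrix, `NA` misses)
#'   and `points` (predicted surface samples, world frame, as a
#'   [point_cloud()]).
#' @export
raycast <- function(volume, pose, intrinsics) {
  out <- .tsdf_raycast(volume$ptr, .intr_vec(intrinsics), pose$R, pose$t,
                       intrinsics$width, intrinsics$height,
                       intrinsics$min_range, intrinsics$max_range)
  out$points <- point_cloud(out$points)
  out
}

#' Extract the zero-crossing surface of a TSDF volume as a point cloud
#'
#' One point per sign change between face-adjacent voxels, linearly
#' interpolated between voxel centres.
#'
#' Crossings at the truncation clamp or with a signed-distance jump above
#' `max_step` are silhouette artifacts ("veil" points at depth
#' discontinuities) and are suppressed.
#'
#' @param volume a [tsdf_volume()].
#' @param min_weight minimum voxel weight for a voxel to participate.
#' @param max_step largest signed-distance change between face neighbours
#'   accepted as true surface, m; defaults to twice the voxel size.
#' @return a [point_cloud()]; empty (with a warning) if the stored
#'   distances never change sign.
#' @export
extract_point_cloud <- function(volume, min_weight = 1,
                                max_step = 2 * volume$voxel_size) {
  if (tsdf_size(volume) == 0) stop("volume is empty: integrate frames first")
  pts <- .tsdf_extract(volume$ptr, min_weight, max_step)
  if (nrow(pts) == 0)
    warning("no zero crossing in volume: returning an empty cloud")
  point_cloud(pts)
}

#' Fuse a depth-frame sequence into a point cloud
#'
#' Frame 0 defines the world frame. Each subsequent frame is registered by
#' point-to-point ICP against the ray-cast prediction of the current model
#' (frame-to-model tracking; set `frame_to_model = FALSE` for
#' frame-to-frame), then integrated. Frames whose ICP residual exceeds
#' `fail_rms` are skipped and logged, never silently integrated.
#'
#' @param frames list of depth frames from [render_depth_frames()] (or any
#'   list with `range` matrices).
#' @param intrinsics a [camera_intrinsics()].
#' @param voxel_size,truncation TSDF resolution, m.
#' @param icp_max_points per-frame subsample size used for registration.
#' @param max_iter,tol ICP iteration controls.
#' @param max_corr ICP correspondence distance cap, m. The default 2 cm is
#'   below the typical lateral spacing of grass-blade columns, so
#'   correspondences cannot jump between neighbouring blades.
#' @param reciprocal keep only mutual nearest-neighbour correspondences.
#' @param fail_rms residual above which a frame is skipped, m.
#' @param frame_to_model register against the ray-cast model prediction
#'   (default) rather than the previous frame's points.
#' @param verbose print per-frame registration summaries.
#' @return list with `cloud` (extracted [point_cloud()]), `poses` (list of
#'   [rigid_pose()] per frame, `NA` entries for skipped frames), `rms`
#'   (per-frame ICP residual) and `skipped` (integer indices).
#' @export
reconstruct <- function(frames, intrinsics, voxel_size = 0.005,
                        truncation = 4 * voxel_size, icp_max_points = 5000,
                        max_iter = 50, tol = 1e-6, max_corr = 0.02,
                        reciprocal = TRUE, fail_rms = 0.03,
                        frame_to_model = TRUE, verbose = FALSE) {
  if (length(frames) < 1) stop("need at least 1 frame")
  vol <- tsdf_volume(voxel_size, truncation)
  poses <- vector("list", length(frames))
  rms <- rep(NA_real_, length(frames))
  skipped <- integer()

  poses[[1]] <- rigid_pose()
  integrate_frame(vol, frames[[1]], poses[[1]], intrinsics)
  rms[1] <- 0
  last_pose <- poses[[1]]
  prev_points <- NULL

  for (i in seq_along(frames)[-1]) {
    target <- if (frame_to_model) {
      raycast(vol, last_pose, intrinsics)$points
    } else {
      prev_points
    }
    if (is.null(target) || nrow(target) < 3) target <-
        transform_cloud(frame_to_points(frames[[i - 1]], intrinsics), last_pose)
    src <- frame_to_points(frames[[i]], intrinsics)
    if (nrow(src) > icp_max_points) {
      idx <- round(seq(1, nrow(src), length.out = icp_max_points))
      src <- point_cloud(src[idx, , drop = FALSE])
    }
    fit <- icp_register(src, target, init = last_pose, max_iter = max_iter,
                        tol = tol, max_corr = max_corr,
                        reciprocal = reciprocal)
    rms[i] <- fit$rms
    if (verbose)
      message(sprintf("frame %d: icp rms %.4f m, %d iter", i, fit$rms,
                      fit$iterations))
    if (!is.finite(fit$rms) || fit$rms > fail_rms) {
      skipped <- c(skipped, i)
      message(sprintf("frame %d skipped: icp rms %.4f m above %.4f m",
                      i, fit$rms, fail_rms))
      next
    }
    poses[[i]] <- fit$pose
    integrate_frame(vol, frames[[i]], fit$pose, intrinsics)
    last_pose <- fit$pose
    prev_points <- transform_cloud(frame_to_points(frames[[i]], intrinsics),
                                   fit$pose)
  }
  list(cloud = extract_point_cloud(vol), poses = poses, rms = rms,
       skipped = skipped, volume = vol)
}
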