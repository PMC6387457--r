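#' Depth-camera intrinsics
#'
#' Pinhole model for a time-of-flight depth camera. Defaults emulate a
#' Kinect-class sensor scaled to half resolution: 256 x 212 pixels with a
#' 70 degree horizontal field of view (about 60 degrees vertically) and a
#' working range of 0.5-4.5 m.
#'
#' @param width,height image size in pixels.
#' @param fov_h_deg horizontal field of view in degrees (sets the focal
#'   length unless `fx` is given).
#' @param fx,fy focal lengths in pixels; `fy` defaults to `fx`.
#' @param cx,cy principal point in pixels (0-based pixel coordinates).
#' @param min_range,max_range valid depth range, m.
#' @return an object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(width = 256L, height = 212L, fov_h_deg = 70,
                              fx = NULL, fy = NULL, cx = NULL, cy = NULL,
                              min_range = 0.5, max_range = 4.5) {
  if (width <= 0 || height <= 0) stop("width and height must be > 0")
  if (is.null(fx)) fx <- (width / 2) / tan(fov_h_deg * pi / 360)
  if (is.null(fy)) fy <- fx
  if (fx <= 0 || fy <= 0) stop("focal lengths must be > 0")
  if (!(min_range > 0 && min_range < max_range))
    stop("need 0 < min_range < max_range")
  if (is.null(cx)) cx <- (width - 1) / 2
  if (is.null(cy)) cy <- (height - 1) / 2
  structure(list(width = as.integer(width), height = as.integer(height),
                 fx = fx, fy = fy, cx = cx, cy = cy,
                 min_range = min_range, max_range = max_range),
            class = "camera_intrinsics")
}

.intr_vec <- function(intr) c(intr$fx, intr$fy, intr$cx, intr$cy)

#' Rigid camera pose
#'
#' A pose maps camera coordinates (x right, y down, z along the optical
#' axis) into the world frame: `p_world = R p_cam + t`. The world frame is
#' z-up.
#'
#' @param R 3 x 3 rotation matrix (orthonormal, det +1 within 1e-6).
#' @param t length-3 translation (camera centre in world coordinates), m.
#' @return an object of class `rigid_pose`.
#' @export
rigid_pose <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6 ||
      abs(det(R) - 1) > 1e-6)
    stop("R must be orthonormal with determinant +1")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_pose")
}

#' @rdname rigid_pose
#' @param a,b poses; `pose_compose(a, b)` is the pose applying `b` then `a`.
#' @export
pose_compose <- function(a, b) rigid_pose(a$R %*% b$R, a$R %*% b$t + a$t)

#' @rdname rigid_pose
#' @param pose a pose to invert.
#' @export
pose_inverse <- function(pose) rigid_pose(t(pose$R), -t(pose$R) %*% pose$t)

#' Rotation angle between two poses, degrees
#' @param a,b poses.
#' @return angle of the relative rotation, degrees.
#' @export
pose_rotation_angle <- function(a, b) {
  R <- t(a$R) %*% b$R
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Nadir pose looking straight down
#'
#' Camera above `(x, y)` at altitude `z`, optical axis along -z (world),
#' camera x aligned with world x.
#'
#' @param x,y,z camera centre, m.
#' @return a [rigid_pose()].
#' @export
nadir_pose <- function(x, y, z) {
  # camera x -> world x, camera y (down in image) -> world -y, z -> -z
  rigid_pose(R = cbind(c(1, 0, 0), c(0, -1, 0), c(0, 0, -1)), t = c(x, y, z))
}

#' Hand-held top-view sweep trajectory
#'
#' Emulates a slow hand-held sweep above the plot centre: near-nadir poses
#' translating along x with a small smooth pitch ramp, as a sensor held
#' from the top view at ~30 fps would see.
#'
#' @param n_poses number of poses.
#' @param altitude camera height above ground, m.
#' @param center plot centre (x, y), m.
#' @param step translation between consecutive poses, m.
#' @param pitch_amp_deg amplitude of the pitch ramp, degrees.
#' @return list of [rigid_pose()].
#' @export
sweep_trajectory <- function(n_poses = 10, altitude = 1.7, center = c(0.5, 0.5),
                             step = 0.007, pitch_amp_deg = 1.5) {
  if (n_poses < 1) stop("trajectory needs at least 1 pose")
  xs <- center[1] + (seq_len(n_poses) - (n_poses + 1) / 2) * step
  lapply(seq_len(n_poses), function(i) {
    base <- nadir_pose(xs[i], center[2], altitude)
    a <- pitch_amp_deg * pi / 180 * sin(2 * pi * (i - 1) / max(1, n_poses))
    Rx <- cbind(c(1, 0, 0), c(0, cos(a), sin(a)), c(0, -sin(a), cos(a)))
    rigid_pose(base$R %*% Rx, base$t)
  })
}

#' Render synthetic depth frames of a plot
#'
#' Ray-marches each pixel against the canopy-top height field of the chosen
#' cloud over a flat ground plane at z = 0, returning per-pixel Euclidean
#' range along the ray plus optional Gaussian range noise. Ranges outside
#' the camera's working range become the invalid sentinel (`NA`). Frames
#' carry their true poses for oracle use.
#'
#' @param truth a [ground_truth_plot()] from [generate_canopy()], or a bare
#'   [point_cloud()].
#' @param trajectory list of [rigid_pose()]s, each viewing the plot.
#' @param intrinsics a [camera_intrinsics()].
#' @param noise_sd Gaussian range noise SD, m (0 = noise free).
#' @param which `"canopy"` or `"stubble"` when `truth` is a ground-truth
#'   plot.
#' @param surface_cell height-field resolution used by the renderer, m.
#' @param seed seed for the noise stream.
#' @return list of depth frames; each is a list with `range` (height x
#'   width matrix, m, `NA` invalid), `index`, and `true_pose`.
#' @export
render_depth_frames <- function(truth, trajectory, intrinsics = camera_intrinsics(),
                                noise_sd = 0, which = c("canopy", "stubble"),
                                surface_cell = 0.004, seed = 1) {
  which <- match.arg(which)
  if (length(trajectory) < 1) stop("trajectory needs at least 1 pose")
  cloud <- if (inherits(truth, "ground_truth_plot")) truth[[which]] else
    point_cloud(truth)
  dsm <- rasterize_dsm(cloud, surface_cell)
  frames <- vector("list", length(trajectory))
  for (i in seq_along(trajectory)) {
    pose <- trajectory[[i]]
    rng <- .render_heightfield(dsm$data, dsm$origin[1], dsm$origin[2],
                               dsm$cell_size, 0,
                               .intr_vec(intrinsics), pose$R, pose$t,
                               intrinsics$width, intrinsics$height,
                               intrinsics$min_range, intrinsics$max_range)
    if (noise_sd > 0) {
      rng <- with_stage_seed(seed, "render-noise", i, {
        rng + matrix(rnorm(length(rng), 0, noise_sd), nrow(rng), ncol(rng))
      })
      rng[rng < intrinsics$min_range | rng > intrinsics$max_range] <- NA_real_
    }
    frames[[i]] <- list(range = rng, index = i, true_pose = pose)
  }
  frames
}

# valid pixels of a frame as 3D points in camera coordinates
frame_to_points <- function(frame, intrinsics) {
  rng <- frame$range
  h <- nrow(rng); w <- ncol(rng)
  vv <- matrix(0:(h - 1), h, w)
  uu <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ok <- is.finite(rng)
  dx <- (uu[ok] - intrinsics$cx) / intrinsics$fx
  dy <- (vv[ok] - intrinsics$cy) / intrinsics$fy
  nrm <- sqrt(dx^2 + dy^2 + 1)
  r <- rng[ok]
  point_cloud(cbind(r * dx / nrm, r * dy / nrm, r / nrm))
}

#' Dense samples of the surface a renderer sees
#'
#' The renderer's surface is the union of canopy-top columns over a flat
#' ground plane. For round-trip evaluation (cloud-to-truth distances) this
#' returns dense samples of that surface: canopy-top cell centres, ground
#' cells, and the vertical walls where adjacent columns differ in height.
#'
#' @param cloud the canopy [point_cloud()] the frames were rendered from.
#' @param cell_size sampling resolution, m (match the renderer's
#'   `surface_cell`).
#' @param margin ground margin around the canopy footprint, m.
#' @param wall_min_step minimum height difference treated as a wall, m.
#' @return a [point_cloud()] of surface samples.
#' @export
surface_samples <- function(cloud, cell_size = 0.004, margin = 0.8,
                            wall_min_step = 0.008) {
  dsm <- rasterize_dsm(cloud, cell_size)
  h <- dsm$data
  h[!is.finite(h)] <- 0        # nodata cells are ground for the renderer
  nx <- ncol(h); ny <- nrow(h)
  xc <- dsm$origin[1] + (seq_len(nx) - 0.5) * cell_size
  yc <- dsm$origin[2] + (seq_len(ny) - 0.5) * cell_size
  tops <- cbind(rep(xc, each = ny), rep(yc, times = nx), as.vector(h))

  # walls between laterally adjacent columns
  wall <- function(h1, h2, wx, wy) {
    d <- abs(h1 - h2)
    sel <- which(d > wall_min_step)
    if (!length(sel)) return(NULL)
    lo <- pmin(h1, h2)[sel]
    n_z <- pmax(1L, ceiling(d[sel] / cell_size))
    reps <- rep(seq_along(sel), n_z)
    zf <- unlist(lapply(n_z, function(k) (seq_len(k) - 0.5) / k))
    cbind(wx[sel][reps], wy[sel][reps],
          lo[reps] + zf * d[sel][reps])
  }
  xg <- matrix(rep(xc, each = ny), ny, nx)
  yg <- matrix(rep(yc, times = nx), ny, nx)
  wx_v <- wall(as.vector(h[, -nx]), as.vector(h[, -1]),
               as.vector((xg[, -nx] + xg[, -1]) / 2), as.vector(yg[, -nx]))
  wx_h <- wall(as.vector(h[-ny, ]), as.vector(h[-1, ]),
               as.vector(xg[-ny, ]), as.vector((yg[-ny, ] + yg[-1, ]) / 2))

  gx <- seq(dsm$origin[1] - margin, dsm$origin[1] + nx * cell_size + margin,
            by = cell_size)
  gy <- seq(dsm$origin[2] - margin, dsm$origin[2] + ny * cell_size + margin,
            by = cell_size)
  ground <- cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx)), 0)
  point_cloud(rbind(tops, wx_v, wx_h, ground))
}

#' Write depth frames to disk
#'
#' One 16-bit little-endian millimetre raw grid per frame (row-major,
#' 0 = invalid) plus a JSON-lines sidecar holding the intrinsics and each
#' frame's pose.
#'
#' @param frames list of depth frames from [render_depth_frames()].
#' @param dir output directory (created if needed).
#' @param intrinsics the [camera_intrinsics()] the frames were rendered
#'   with.
#' @return `dir`, invisibly.
#' @export
write_depth_frames <- function(frames, dir, intrinsics) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sidecar <- file.path(dir, "frames.jsonl")
  lines <- jsonlite::toJSON(c(list(type = "intrinsics"),
                              unclass(intrinsics)), auto_unbox = TRUE,
                            digits = NA)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    fn <- sprintf("frame_%04d.raw", i)
    mm <- round(t(fr$range) * 1000)            # row-major on disk
    mm[!is.finite(mm)] <- 0
    mm <- pmin(pmax(mm, 0), 65535)
    con <- file(file.path(dir, fn), "wb")
    writeBin(as.integer(mm), con, size = 2L, endian = "little")
    close(con)
    pose <- fr$true_pose
    lines <- c(lines, jsonlite::toJSON(list(
      type = "frame", file = fn, index = i,
      R = if (!is.null(pose)) as.vector(pose$R) else NULL,
      t = if (!is.null(pose)) pose$t else NULL), auto_unbox = TRUE,
      digits = NA))
  }
  writeLines(lines, sidecar)
  invisible(dir)
}

#' Read depth frames written by [write_depth_frames()]
#'
#' @param dir directory holding `frames.jsonl` and the raw grids.
#' @return list with `frames` (ranges in m, `NA` invalid, poses restored)
#'   and `intrinsics`.
#' @export
read_depth_frames <- function(dir) {
  sidecar <- file.path(dir, "frames.jsonl")
  if (!file.exists(sidecar)) stop("no frames.jsonl sidecar in ", dir)
  recs <- lapply(readLines(sidecar), jsonlite::fromJSON)
  types <- vapply(recs, `[[`, "", "type")
  ih <- recs[[which(types == "intrinsics")[1]]]
  intr <- camera_intrinsics(width = ih$width, height = ih$height,
                            fx = ih$fx, fy = ih$fy, cx = ih$cx, cy = ih$cy,
                            min_range = ih$min_range,
                            max_range = ih$max_range)
  frames <- lapply(recs[types == "frame"], function(r) {
    con <- file(file.path(dir, r$file), "rb")
    mm <- readBin(con, "integer", n = intr$width * intr$height, size = 2L,
                  endian = "little", signed = FALSE)
    close(con)
    if (length(mm) != intr$width * intr$height)
      stop("truncated raw frame: ", r$file)
    rng <- t(matrix(mm / 1000, intr$width, intr$height))
    rng[rng == 0] <- NA_real_
    pose <- if (!is.null(r$R)) rigid_pose(matrix(r$R, 3, 3), r$t) else NULL
    list(range = rng, index = r$index, true_pose = pose)
  })
  list(frames = frames, intrinsics = intr)
}
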