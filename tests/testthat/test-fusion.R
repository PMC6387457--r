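plane_setup <- function(z_cam = 1.0, intr = camera_intrinsics(width = 64L,
                                                              height = 53L)) {
  pose <- nadir_pose(0.5, 0.5, z_cam)
  frame <- render_depth_frames(flat_cloud(1, z = 0), list(pose), intr,
                               noise_sd = 0)[[1]]
  list(pose = pose, frame = frame, intr = intr)
}

test_that("integrating a plane frame puts the zero crossing on the plane", {
  s <- plane_setup()
  vol <- tsdf_volume(0.005, 0.02)
  integrate_frame(vol, s$frame, s$pose, s$intr)
  cl <- extract_point_cloud(vol)
  expect_gt(nrow(cl), 100)
  # plane z = 0: all crossings within half a voxel, tight RMS
  expect_lt(max(abs(cl[, 3])), 0.005 / 2 + 1e-12)
  expect_lt(sqrt(mean(cl[, 3]^2)), 0.005 / 4)
})

test_that("re-integrating the same frame scales weights, not distances", {
  s <- plane_setup()
  vol <- tsdf_volume(0.005, 0.02)
  integrate_frame(vol, s$frame, s$pose, s$intr)
  d1 <- tsdf_data(vol)
  d1 <- d1[order(d1$ix, d1$iy, d1$iz), ]
  for (i in 1:9) integrate_frame(vol, s$frame, s$pose, s$intr)
  d10 <- tsdf_data(vol)
  d10 <- d10[order(d10$ix, d10$iy, d10$iz), ]
  expect_identical(nrow(d10), nrow(d1))
  expect_equal(d10$weight, d1$weight * 10)
  expect_equal(d10$sdf, d1$sdf, tolerance = 1e-12)
})

test_that("empty frames change nothing and mismatched frames error", {
  s <- plane_setup()
  vol <- tsdf_volume(0.005, 0.02)
  empty <- list(range = matrix(NA_real_, s$intr$height, s$intr$width))
  integrate_frame(vol, empty, s$pose, s$intr)
  expect_identical(tsdf_size(vol), 0L)
  bad <- list(range = matrix(1, 10, 10))
  expect_error(integrate_frame(vol, bad, s$pose, s$intr),
               "do not match intrinsics")
})

test_that("voxel allocation stays within the truncation-band bound", {
  s <- plane_setup()
  vol <- tsdf_volume(0.005, 0.02)
  integrate_frame(vol, s$frame, s$pose, s$intr)
  n_valid <- sum(is.finite(s$frame$range))
  # each ray can touch at most ~the band length in voxels, + traversal slack
  band_voxels <- 2 * 0.02 / 0.005 + 3
  expect_lte(tsdf_size(vol), n_valid * band_voxels)
})

test_that("ray casting reproduces the rendered frame and misses cleanly", {
  s <- plane_setup()
  vol <- tsdf_volume(0.005, 0.02)
  integrate_frame(vol, s$frame, s$pose, s$intr)
  rc <- raycast(vol, s$pose, s$intr)
  both <- is.finite(rc$range) & is.finite(s$frame$range)
  expect_gt(mean(both), 0.9)
  expect_lt(max(abs(rc$range[both] - s$frame$range[both])), 0.005 / 2)
  # looking away from every stored voxel: all pixels invalid
  away <- rigid_pose(nadir_pose(0.5, 0.5, 1)$R, c(0.5, 0.5, -5))
  rc2 <- raycast(vol, rigid_pose(diag(3), c(0, 0, 10)), s$intr)
  expect_true(all(!is.finite(rc2$range)))
  expect_identical(nrow(rc2$points), 0L)
})

test_that("surface extraction respects weights and warns with no crossing", {
  s <- plane_setup()
  vol <- tsdf_volume(0.005, 0.02)
  integrate_frame(vol, s$frame, s$pose, s$intr)
  expect_warning(cl <- extract_point_cloud(vol, min_weight = 1e6),
                 "no zero crossing")
  expect_identical(nrow(cl), 0L)
  vol2 <- tsdf_volume(0.005, 0.02)
  expect_error(extract_point_cloud(vol2), "empty")
})

test_that("two parallel planes extract as two separated coplanar clusters", {
  intr <- camera_intrinsics(width = 64L, height = 53L)
  vol <- tsdf_volume(0.005, 0.02)
  s1 <- plane_setup(intr = intr)
  integrate_frame(vol, s1$frame, s1$pose, intr)
  # second plane at z = 0.3, shifted far in x so the bands never touch;
  # wide enough to fill the whole field of view (the renderer treats
  # terrain outside the height field as ground, which must not leak in)
  pose2 <- nadir_pose(5.5, 0.5, 1.3)
  plane2 <- point_cloud(sweep(unclass(flat_cloud(3, z = 0.3)), 2,
                              c(4, -1, 0), "+"))
  f2 <- render_depth_frames(plane2, list(pose2), intr, noise_sd = 0,
                            surface_cell = 0.02)[[1]]
  integrate_frame(vol, f2, pose2, intr)
  cl <- extract_point_cloud(vol)
  low <- cl[, 3] < 0.15
  expect_gt(sum(low), 50)
  expect_gt(sum(!low), 50)
  expect_lt(max(abs(cl[low, 3] - 0)), 0.0026)
  expect_lt(max(abs(cl[!low, 3] - 0.3)), 0.0026)
  # cluster gap equals the plane spacing within a voxel
  expect_equal(mean(cl[!low, 3]) - mean(cl[low, 3]), 0.3, tolerance = 0.005)
})

test_that("a single frame reconstructs to the base-case volume", {
  intr <- camera_intrinsics(width = 64L, height = 53L)
  tr <- generate_canopy(plot_spec("p", ryegrass_profile(), seed = 5))
  traj <- sweep_trajectory(1)
  fr <- render_depth_frames(tr, traj, intr, noise_sd = 0)
  rec <- reconstruct(fr, intr, voxel_size = 0.008)
  vol <- tsdf_volume(0.008, 4 * 0.008)
  integrate_frame(vol, fr[[1]], rigid_pose(), intr)
  expect_identical(unclass(rec$cloud), unclass(extract_point_cloud(vol)))
  expect_identical(rec$skipped, integer(0))
  expect_error(reconstruct(list(), intr), "at least 1 frame")
})

test_that("composing relative poses reproduces the absolute trajectory", {
  intr <- camera_intrinsics(width = 96L, height = 80L)
  tr <- generate_canopy(plot_spec("p", ryegrass_profile(), seed = 5))
  traj <- sweep_trajectory(4)
  fr <- render_depth_frames(tr, traj, intr, noise_sd = 0, surface_cell = 0.006)
  rec <- reconstruct(fr, intr, voxel_size = 0.008)
  # single-reference convention: absolute = prod of inter-frame increments
  acc <- rec$poses[[1]]
  for (i in 2:4) {
    rel <- pose_compose(pose_inverse(rec$poses[[i - 1]]), rec$poses[[i]])
    acc <- pose_compose(acc, rel)
    expect_equal(acc$R, rec$poses[[i]]$R, tolerance = 1e-12)
    expect_equal(acc$t, rec$poses[[i]]$t, tolerance = 1e-12)
  }
})
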