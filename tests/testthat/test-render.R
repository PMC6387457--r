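small_intr <- function() camera_intrinsics(width = 64L, height = 53L)

test_that("a flat ground plane renders the closed-form range 1/cos", {
  intr <- small_intr()
  pose <- nadir_pose(0.5, 0.5, 1.0)
  fr <- render_depth_frames(flat_cloud(1, z = 0), list(pose), intr,
                            noise_sd = 0)[[1]]
  uu <- matrix(0:(intr$width - 1), intr$height, intr$width, byrow = TRUE)
  vv <- matrix(0:(intr$height - 1), intr$height, intr$width)
  expected <- sqrt(((uu - intr$cx) / intr$fx)^2 +
                   ((vv - intr$cy) / intr$fy)^2 + 1) * 1.0
  expect_true(all(is.finite(fr$range)))
  expect_equal(fr$range, expected, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(fr$true_pose, pose)
})

test_that("surfaces closer than min_range are invalid", {
  intr <- small_intr()                     # min_range 0.5 m
  pose <- nadir_pose(0.5, 0.5, 0.8)
  # canopy at z = 0.35 under the camera: range ~0.45 < 0.5 -> invalid;
  # surrounding ground at ~0.8 m stays valid
  obj <- flat_cloud(0.3, z = 0.35, spacing = 0.005)
  obj <- point_cloud(sweep(unclass(obj), 2, c(0.35, 0.35, 0), "+"))
  fr <- render_depth_frames(obj, list(pose), intr, noise_sd = 0)[[1]]
  center_px <- fr$range[round(intr$cy) + 1, round(intr$cx) + 1]
  expect_true(is.na(center_px))
  expect_gt(sum(is.finite(fr$range)), 0)
  expect_true(all(fr$range[is.finite(fr$range)] >= intr$min_range))
})

test_that("rendering is deterministic and noise is seeded", {
  intr <- small_intr()
  pose <- nadir_pose(0.5, 0.5, 1.2)
  tr <- generate_canopy(plot_spec("p", ryegrass_profile(), seed = 8))
  f1 <- render_depth_frames(tr, list(pose, pose), intr, noise_sd = 0)
  expect_identical(f1[[1]]$range, f1[[2]]$range)
  n1 <- render_depth_frames(tr, list(pose), intr, noise_sd = 0.005, seed = 2)
  n2 <- render_depth_frames(tr, list(pose), intr, noise_sd = 0.005, seed = 2)
  n3 <- render_depth_frames(tr, list(pose), intr, noise_sd = 0.005, seed = 3)
  expect_identical(n1[[1]]$range, n2[[1]]$range)
  expect_false(identical(n1[[1]]$range, n3[[1]]$range))
  expect_error(render_depth_frames(tr, list(), intr), "at least 1 pose")
})

test_that("intrinsics and poses validate their invariants", {
  expect_error(camera_intrinsics(width = 0), "width")
  expect_error(camera_intrinsics(min_range = 2, max_range = 1), "min_range")
  expect_error(rigid_pose(R = diag(3) * 2), "orthonormal")
  bad <- diag(3); bad[1, 1] <- -1          # reflection
  expect_error(rigid_pose(R = bad), "orthonormal")
  # composition and inversion are exact
  a <- rigid_pose(rot_axis_angle(c(1, 2, 3), 0.4), c(1, 2, 3))
  b <- rigid_pose(rot_axis_angle(c(-1, 1, 0), -0.2), c(0.1, 0, -0.5))
  ab <- pose_compose(a, b)
  back <- pose_compose(pose_inverse(a), ab)
  expect_equal(back$R, b$R, tolerance = 1e-12)
  expect_equal(back$t, b$t, tolerance = 1e-12)
})

test_that("depth frames round-trip through the raw-grid disk format", {
  intr <- small_intr()
  tr <- generate_canopy(plot_spec("p", ryegrass_profile(), seed = 8))
  frames <- render_depth_frames(tr, sweep_trajectory(2), intr, noise_sd = 0)
  d <- file.path(tempdir(), "framesdisk")
  write_depth_frames(frames, d, intr)
  back <- read_depth_frames(d)
  expect_identical(back$intrinsics$width, intr$width)
  expect_equal(back$intrinsics$fx, intr$fx, tolerance = 1e-12)
  for (i in 1:2) {
    a <- frames[[i]]$range; b <- back$frames[[i]]$range
    expect_identical(dim(a), dim(b))
    expect_identical(is.na(a), is.na(b))
    # ranges are quantized to millimetres on disk
    expect_lt(max(abs(a - b), na.rm = TRUE), 5e-4 + 1e-12)
    expect_equal(back$frames[[i]]$true_pose$R, frames[[i]]$true_pose$R,
                 tolerance = 1e-12)
  }
})
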