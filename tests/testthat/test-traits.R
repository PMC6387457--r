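test_that("plane-pair differencing recovers a constant offset exactly", {
  pre <- flat_cloud(1, z = 0.6, spacing = 0.005)
  post <- flat_cloud(1, z = 0.1, spacing = 0.005)
  hd <- height_by_differencing(pre, post, cell_size = 0.02)
  v <- hd$raster$data[is.finite(hd$raster$data)]
  expect_true(all(abs(v - 0.5) < 1e-12))
  expect_equal(hd$max_height, 0.5)
  expect_equal(hd$mean_height, 0.5)
  # identical models difference to zero everywhere
  hd0 <- height_by_differencing(pre, pre, cell_size = 0.02)
  expect_true(all(hd0$raster$data[is.finite(hd0$raster$data)] == 0))
})

test_that("synthetic-plot differencing tracks the tallest tiller", {
  sp <- plot_spec("p", timothy_profile(), seed = 14, stubble_height = 0.05)
  tr <- generate_canopy(sp)
  hd <- height_by_differencing(tr$canopy, tr$stubble, cell_size = 0.02)
  truth <- max(tr$tip_heights) - 0.05
  # within one cell's aggregation error: the stubble top under the tallest
  # tip is the cut surface (or a mid-leaf point slightly below it)
  expect_lt(abs(hd$max_height - truth), 0.05)
  expect_gt(hd$mean_height, 0)
  expect_lte(hd$mean_height, hd$max_height)
})

test_that("disjoint footprints raise an explicit error", {
  a <- flat_cloud(1, z = 0.5)
  b <- point_cloud(sweep(unclass(flat_cloud(1, z = 0.1)), 2, c(10, 0, 0), "+"))
  expect_error(height_by_differencing(a, b, 0.02), "disjoint")
})

test_that("DSM solid volume integrates boxes, clamps and skips nodata", {
  m <- matrix(0.5, 10, 10)
  dsm <- height_raster(m, c(0, 0), 0.1)
  expect_equal(dsm_solid_volume(dsm, 0), 0.5)
  expect_equal(dsm_solid_volume(dsm, 1), 0)          # ground above crop
  m2 <- m; m2[, 1:5] <- NA
  expect_equal(dsm_solid_volume(height_raster(m2, c(0, 0), 0.1), 0), 0.25)
})

test_that("cover area counts cells at or above the threshold", {
  full <- flat_cloud(1, z = 0.3, spacing = 0.01)
  expect_equal(cover_area(full, cell_size = 0.02, height_threshold = 0), 1.0)
  expect_equal(cover_area(point_cloud(NULL), 0.02, 0), 0)
  # canopy over one quadrant only
  quad <- crop_cloud(full, c(0, 0.5), c(0, 0.5))
  a <- cover_area(quad, cell_size = 0.02, height_threshold = 0.1)
  expect_lt(abs(a - 0.25), 0.03)                     # one boundary-cell row
  expect_equal(cover_area(full, 0.02, height_threshold = 0.3), 1.0)
  expect_equal(cover_area(full, 0.02, height_threshold = 0.31), 0)
})

test_that("alpha, DSM and analytic volumes agree on a solid box canopy", {
  set.seed(18)
  n <- 4000
  # solid box 1 x 1 x 0.4: points on all faces and in the interior
  face <- function(fix, val) {
    m <- cbind(runif(n / 8), runif(n / 8), runif(n / 8))
    m[, fix] <- val
    m
  }
  gtop <- expand.grid(x = seq(0, 1, by = 0.02), y = seq(0, 1, by = 0.02))
  pts <- rbind(face(3, 0), cbind(gtop$x, gtop$y, 1), face(1, 0), face(1, 1),
               face(2, 0), face(2, 1),
               cbind(runif(n / 4), runif(n / 4), runif(n / 4)))
  pts[, 3] <- pts[, 3] * 0.4
  box <- point_cloud(pts)
  v_alpha <- alpha_shape_volume(box, alpha = 5)$volume
  v_dsm <- dsm_solid_volume(rasterize_dsm(box, 0.02), 0)
  v_true <- 1 * 1 * 0.4
  expect_lt(abs(v_alpha - v_true) / v_true, 0.05)
  expect_lt(abs(v_dsm - v_true) / v_true, 0.05)
  expect_lt(abs(v_alpha - v_dsm) / v_true, 0.05)
})

test_that("trait records are deterministic and translation invariant", {
  tr <- generate_canopy(plot_spec("p", ryegrass_profile(), seed = 20))
  pre <- tr$canopy; post <- tr$stubble
  a <- extract_traits(pre, post, plot_id = "p")
  b <- extract_traits(pre, post, plot_id = "p")
  expect_identical(a, b)
  expect_lte(a$mean_height_m, a$max_height_m)
  expect_true(all(unlist(a[-1]) >= 0 | is.na(unlist(a[-1]))))
  shift <- rigid_pose(diag(3), c(3, -2, 0))
  a2 <- extract_traits(swardscan:::transform_cloud(pre, shift),
                       swardscan:::transform_cloud(post, shift),
                       plot_id = "p")
  for (col in c("max_height_m", "mean_height_m", "cover_m2",
                "alpha_volume_m3", "dsm_volume_m3"))
    expect_equal(a2[[col]], a[[col]], tolerance = 1e-9,
                 label = col)
})

test_that("rasterization follows the max rule with half-open cells", {
  cl <- point_cloud(rbind(c(0.05, 0.05, 0.7)))
  r <- rasterize_dsm(cl, 0.1, extent = list(origin = c(0, 0), size = c(1, 1)))
  expect_equal(r$data[1, 1], 0.7)
  expect_equal(sum(is.finite(r$data)), 1L)
  # max rule within a cell
  cl2 <- point_cloud(rbind(c(0.05, 0.05, 0.3), c(0.06, 0.04, 0.6)))
  r2 <- rasterize_dsm(cl2, 0.1, extent = list(origin = c(0, 0), size = c(1, 1)))
  expect_equal(r2$data[1, 1], 0.6)
  # a point on the outer max edge lands in the last cell
  cl3 <- point_cloud(rbind(c(1, 1, 0.2), c(0, 0, 0.1)))
  r3 <- rasterize_dsm(cl3, 0.1, extent = list(origin = c(0, 0), size = c(1, 1)))
  expect_equal(r3$data[10, 10], 0.2)
  # uniform canopy rasterizes to its height everywhere covered
  r4 <- rasterize_dsm(flat_cloud(1, z = 0.4), 0.05)
  expect_true(all(r4$data[is.finite(r4$data)] == 0.4))
  expect_warning(rasterize_dsm(point_cloud(NULL), 0.1), "empty cloud")
})
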