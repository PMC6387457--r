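zero_var_profile <- function() {
  species_profile(name = "uniform", tiller_density = 400, height_mean = 0.5,
                  height_sd = 0, leaf_points_per_tiller = 8,
                  bend_fraction = 0.3, allometric_slope = 0.5,
                  allometric_intercept = 0.1, biomass_noise_sd = 0,
                  plot_height_sd = 0)
}

test_that("zero-variance swards put every tip and tape height at the mean", {
  tr <- generate_canopy(plot_spec("p1", zero_var_profile(), seed = 3))
  expect_equal(unname(tr$tip_heights), rep(0.5, length(tr$tip_heights)))
  expect_equal(unname(tr$tape_heights), rep(0.5, 5))
  expect_equal(max(tr$canopy[, 3]), 0.5)
})

test_that("generation is deterministic for a fixed seed", {
  sp <- plot_spec("p1", timothy_profile(), seed = 99)
  a <- generate_canopy(sp)
  b <- generate_canopy(sp)
  expect_identical(a$canopy, b$canopy)
  expect_identical(a$stubble, b$stubble)
  expect_identical(a$tape_heights, b$tape_heights)
  expect_identical(a$dry_biomass, b$dry_biomass)
  c <- generate_canopy(plot_spec("p1", timothy_profile(), seed = 100))
  expect_false(identical(a$canopy, c$canopy))
})

test_that("invalid profiles and plot specs are rejected by field name", {
  expect_error(species_profile("x", tiller_density = -1, height_mean = 0.5,
                               height_sd = 0.1, leaf_points_per_tiller = 8,
                               bend_fraction = 0.5, allometric_slope = 1,
                               allometric_intercept = 0, biomass_noise_sd = 0),
               "tiller_density")
  expect_error(species_profile("x", tiller_density = 100, height_mean = 0.5,
                               height_sd = 0.1, leaf_points_per_tiller = 8,
                               bend_fraction = 1.5, allometric_slope = 1,
                               allometric_intercept = 0, biomass_noise_sd = 0),
               "bend_fraction")
  expect_error(plot_spec("p", timothy_profile(), 1, extent = c(0, 1)),
               "extent")
  expect_error(plot_spec("p", timothy_profile(), 1, stubble_height = 0.7),
               "stubble_height")
})

test_that("cloud sizes, height consistency and stubble clipping hold", {
  for (seed in c(2, 17, 31)) {
    sp <- plot_spec("p", ryegrass_profile(), seed = seed)
    tr <- generate_canopy(sp)
    prof <- sp$species
    expect_gte(nrow(tr$canopy),
               prof$tiller_density * prod(sp$extent) *
                 prof$leaf_points_per_tiller)
    # noise-free in z: the tallest point is the tallest tiller tip
    expect_equal(max(tr$canopy[, 3]), max(tr$tip_heights), tolerance = 1e-12)
    expect_lte(max(tr$stubble[, 3]), sp$stubble_height + 1e-12)
    # plate meter never exceeds the tallest tape measurement
    expect_lte(tr$plate_meter_height, max(tr$tape_heights))
    expect_gte(tr$dry_biomass, 0)
    expect_gte(tr$true_canopy_volume, 0)
  }
})

test_that("plate meter reads a compressed central statistic", {
  # uniform canopy at exactly 0.50 m
  expect_equal(simulate_plate_meter(flat_cloud(1, z = 0.5)), 0.5)
  # 99% of the area at 0.4 m, 1% at 1.0 m: closer to 0.4 than to 1.0
  g <- unclass(flat_cloud(1, z = 0.4, spacing = 0.005))
  tall <- cbind(runif(350, 0.45, 0.55), runif(350, 0.45, 0.55), 1.0)
  h <- simulate_plate_meter(point_cloud(rbind(g, tall)))
  expect_lt(abs(h - 0.4), abs(h - 1.0))
  expect_lte(h, 1.0)
  # empty cloud and empty footprint give the no-vegetation sentinel
  expect_identical(simulate_plate_meter(point_cloud(NULL)), NA_real_)
  far <- point_cloud(cbind(5 + runif(200), 5 + runif(200), 0.3))
  expect_identical(simulate_plate_meter(far, center = c(0.5, 0.5)), NA_real_)
})

test_that("growth-habit contrast: height predicts biomass for timothy only", {
  fields <- list(ryegrass = ryegrass_profile(), timothy = timothy_profile())
  r2 <- sapply(names(fields), function(f) {
    truth <- simulate_field(fields[[f]], n_plots = 10, master_seed = 4,
                            field_label = f)
    fit <- fit_simple_regression(paired_samples(
      plot_id = vapply(truth, `[[`, "", "plot_id"),
      x = vapply(truth, `[[`, 0, "dry_biomass"),
      y = vapply(truth, function(tr) mean(tr$tip_heights), 0),
      field = f, level = "plot"))
    fit$r_squared
  })
  expect_gt(r2[["timothy"]], r2[["ryegrass"]] + 0.3)
})
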