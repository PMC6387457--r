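#' Species profile for the synthetic sward generator
#'
#' Encodes the growth-habit contrast between a ryegrass-dominant sward
#' (dense tillering, leaves bent toward a common canopy height, biomass
#' carried mostly in the allometric intercept) and a timothy-dominant sward
#' (sparser, taller, high tiller-height variance, biomass driven by the
#' allometric slope).
#'
#' @param name species label.
#' @param tiller_density tillers per m2 (> 0).
#' @param height_mean mean tiller height, m (> 0).
#' @param height_sd within-plot SD of tiller height, m (>= 0).
#' @param leaf_points_per_tiller points sampled along each tiller (>= 2).
#' @param bend_fraction in `[0, 1]`; how strongly individual tiller tips are
#'   pulled toward the plot-level mean height (leaf bending to a "common
#'   height").
#' @param allometric_slope kg dry matter per m of mean sward height per m2.
#' @param allometric_intercept kg dry matter per m2 at zero height.
#' @param biomass_noise_sd SD of additive biomass noise, kg per m2 (>= 0).
#' @param plot_height_sd between-plot SD of the mean sward height, m
#'   (>= 0); the source of plot-to-plot variation a field survey sees.
#' @return an object of class `species_profile`.
#' @export
species_profile <- function(name, tiller_density, height_mean, height_sd,
                            leaf_points_per_tiller, bend_fraction,
                            allometric_slope, allometric_intercept,
                            biomass_noise_sd, plot_height_sd = 0) {
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid species profile: `", field, "` must be ", what)
  }
  chk(tiller_density > 0, "tiller_density", "> 0")
  chk(height_mean > 0, "height_mean", "> 0")
  chk(height_sd >= 0, "height_sd", ">= 0")
  chk(leaf_points_per_tiller >= 2, "leaf_points_per_tiller", ">= 2")
  chk(bend_fraction >= 0 && bend_fraction <= 1, "bend_fraction", "in [0, 1]")
  chk(biomass_noise_sd >= 0, "biomass_noise_sd", ">= 0")
  chk(plot_height_sd >= 0, "plot_height_sd", ">= 0")
  structure(list(name = name, tiller_density = tiller_density,
                 height_mean = height_mean, height_sd = height_sd,
                 leaf_points_per_tiller = as.integer(leaf_points_per_tiller),
                 bend_fraction = bend_fraction,
                 allometric_slope = allometric_slope,
                 allometric_intercept = allometric_intercept,
                 biomass_noise_sd = biomass_noise_sd,
                 plot_height_sd = plot_height_sd),
            class = "species_profile")
}

#' Default ryegrass-dominant profile
#'
#' Dense tillering, strong leaf bending to a common height, biomass mostly
#' in the intercept: sward height is a weak biomass proxy.
#' @return a [species_profile()].
#' @export
ryegrass_profile <- function() {
  species_profile(
    name = "ryegrass", tiller_density = 2500, height_mean = 0.45,
    height_sd = 0.07, leaf_points_per_tiller = 12, bend_fraction = 0.75,
    allometric_slope = 0.06, allometric_intercept = 0.34,
    biomass_noise_sd = 0.035, plot_height_sd = 0.05)
}

#' Default timothy-dominant profile
#'
#' Sparser, taller, high within- and between-plot height variance, biomass
#' driven by height: sward height is a strong biomass proxy.
#' @return a [species_profile()].
#' @export
timothy_profile <- function() {
  species_profile(
    name = "timothy", tiller_density = 1100, height_mean = 0.60,
    height_sd = 0.16, leaf_points_per_tiller = 14, bend_fraction = 0.10,
    allometric_slope = 0.85, allometric_intercept = 0.03,
    biomass_noise_sd = 0.035, plot_height_sd = 0.10)
}

#' Specification of one synthetic 1 m2 sampling plot
#'
#' @param plot_id plot label.
#' @param species a [species_profile()].
#' @param seed integer master seed for this plot.
#' @param extent numeric length-2 plot size (m x m), default 1 x 1.
#' @param stubble_height post-harvest residual height, m; must be below the
#'   species' mean height.
#' @return an object of class `plot_spec`.
#' @export
plot_spec <- function(plot_id, species, seed, extent = c(1, 1),
                      stubble_height = 0.05) {
  stopifnot(inherits(species, "species_profile"))
  if (any(extent <= 0)) stop("plot extent must be strictly positive")
  if (stubble_height >= species$height_mean)
    stop("stubble_height must be below the species' mean height")
  structure(list(plot_id = as.character(plot_id), species = species,
                 seed = as.integer(seed), extent = as.numeric(extent),
                 stubble_height = stubble_height),
            class = "plot_spec")
}

# truncated-at-zero normal draws (exact via inverse CDF; sd = 0 collapses)
.rtnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

#' Generate a synthetic sward plot with ground truth
#'
#' Builds one plot's pre-harvest canopy cloud, post-harvest stubble cloud
#' and the field measurements a survey records: tape heights at the four
#' quadrant centres plus the plot centre (95th percentile of tiller-tip
#' heights within a 5 cm probe radius), a rising-plate-meter compressed
#' height, and dry biomass from the species' linear allometry in mean
#' sward height with additive noise.
#'
#' Each tiller is a near-vertical polyline of leaf points leaning outward
#' with height; tiller heights are truncated-normal and tips are shrunk
#' toward the plot mean by `bend_fraction`. All randomness derives from the
#' plot seed via per-stage sub-streams.
#'
#' @param spec a [plot_spec()].
#' @return an object of class `ground_truth_plot` with elements `plot_id`,
#'   `canopy` and `stubble` ([point_cloud()]s), `tape_heights` (named,
#'   q1..q4 + center, m), `plate_meter_height` (m), `dry_biomass`
#'   (kg per m2), `true_canopy_volume` (m3), `true_cover_area` (m2),
#'   `tip_heights`, `tiller_xy` and `spec`.
#' @export
generate_canopy <- function(spec) {
  stopifnot(inherits(spec, "plot_spec"))
  sp <- spec$species
  ex <- spec$extent
  area <- prod(ex)
  n_till <- max(4L, as.integer(round(sp$tiller_density * area)))

  xy <- with_stage_seed(spec$seed, "layout", 0L, {
    cbind(runif(n_till) * ex[1], runif(n_till) * ex[2])
  })
  h <- with_stage_seed(spec$seed, "heights", 0L, {
    mu_plot <- max(0.05, rnorm(1, sp$height_mean, sp$plot_height_sd))
    .rtnorm0(n_till, mu_plot, sp$height_sd)
  })
  # leaf bending pulls tips toward the realized plot mean
  tips <- (1 - sp$bend_fraction) * h + sp$bend_fraction * mean(h)

  m <- sp$leaf_points_per_tiller
  leaf <- with_stage_seed(spec$seed, "leaves", 0L, {
    f <- rep(seq_len(m) / m, times = n_till)          # last point = the tip
    tip_rep <- rep(tips, each = m)
    theta <- rep(runif(n_till, 0, 2 * pi), each = m)  # lean direction
    lean <- 0.15 * f^2 * tip_rep                       # arc outward with height
    jit <- matrix(rnorm(2L * n_till * m, 0, 0.004), ncol = 2)
    x <- rep(xy[, 1], each = m) + lean * cos(theta) + jit[, 1]
    y <- rep(xy[, 2], each = m) + lean * sin(theta) + jit[, 2]
    z <- f * tip_rep
    cbind(x, y, z)
  })
  canopy <- point_cloud(leaf)

  # stubble: the same layout clipped at the cutting height, plus one point
  # at exactly the cut top of every tiller so the residual surface is dense
  keep <- leaf[, 3] <= spec$stubble_height
  cut_tops <- cbind(xy, pmin(tips, spec$stubble_height))
  stubble <- point_cloud(rbind(leaf[keep, , drop = FALSE], cut_tops))

  probes <- rbind(q1 = c(0.25, 0.25), q2 = c(0.75, 0.25),
                  q3 = c(0.25, 0.75), q4 = c(0.75, 0.75),
                  center = c(0.5, 0.5))
  probes <- sweep(probes, 2, ex, "*")
  tape <- vapply(seq_len(nrow(probes)), function(i) {
    r <- 0.05
    repeat {
      d2 <- (xy[, 1] - probes[i, 1])^2 + (xy[, 2] - probes[i, 2])^2
      sel <- d2 <= r^2
      if (any(sel)) return(unname(quantile(tips[sel], 0.95)))
      r <- r * 2  # widen until a tiller is found (sparse stands)
    }
  }, numeric(1))
  names(tape) <- rownames(probes)

  plate <- simulate_plate_meter(canopy, probe_area = 0.25,
                                center = ex / 2)
  # a compressed height can never exceed the tallest measured tip
  plate <- min(plate, max(tape))

  biomass <- with_stage_seed(spec$seed, "biomass", 0L, {
    max(0, sp$allometric_intercept + sp$allometric_slope * mean(tips) +
          rnorm(1, 0, sp$biomass_noise_sd))
  })

  # reference solid volume / cover from a fine canopy-top grid
  dsm <- rasterize_dsm(canopy, cell_size = 0.01,
                       extent = list(origin = c(0, 0), size = ex))
  vol <- sum(pmax(dsm$data, 0), na.rm = TRUE) * dsm$cell_size^2
  cov <- sum(is.finite(dsm$data)) * dsm$cell_size^2

  structure(list(plot_id = spec$plot_id, canopy = canopy, stubble = stubble,
                 tape_heights = tape, plate_meter_height = plate,
                 dry_biomass = biomass, true_canopy_volume = vol,
                 true_cover_area = cov, tip_heights = tips, tiller_xy = xy,
                 spec = spec),
            class = "ground_truth_plot")
}

#' @export
print.ground_truth_plot <- function(x, ...) {
  cat(sprintf(
    "ground_truth_plot '%s': %d canopy pts, %d stubble pts\n",
    x$plot_id, nrow(x$canopy), nrow(x$stubble)))
  cat(sprintf("  tape %.3f-%.3f m, plate %.3f m, biomass %.3f kg/m2\n",
              min(x$tape_heights), max(x$tape_heights),
              x$plate_meter_height, x$dry_biomass))
  invisible(x)
}

#' Simulate a rising plate meter reading
#'
#' The plate bends the tallest leaves down to a common height; this is
#' modelled as the 60th percentile of the canopy-top heights within the
#' plate footprint (a centred square of the given area), always at or
#' below the footprint's maximum canopy height.
#'
#' @param canopy a [point_cloud()].
#' @param probe_area plate footprint area, m2 (default 0.25).
#' @param center footprint centre (x, y); defaults to the canopy centroid.
#' @param prob percentile of canopy-top heights returned (default 0.6).
#' @param cell_size grid used to form the canopy-top surface, m.
#' @return compressed height in m, or `NA_real_` (no-vegetation sentinel)
#'   when no canopy lies in the footprint.
#' @export
simulate_plate_meter <- function(canopy, probe_area = 0.25, center = NULL,
                                 prob = 0.6, cell_size = 0.02) {
  m <- unclass(point_cloud(canopy))
  if (nrow(m) == 0) return(NA_real_)
  if (is.null(center)) center <- c(mean(range(m[, 1])), mean(range(m[, 2])))
  half <- sqrt(probe_area) / 2
  sel <- abs(m[, 1] - center[1]) <= half & abs(m[, 2] - center[2]) <= half
  if (!any(sel)) return(NA_real_)
  dsm <- rasterize_dsm(point_cloud(m[sel, , drop = FALSE]), cell_size)
  tops <- dsm$data[is.finite(dsm$data)]
  min(unname(quantile(tops, prob)), max(tops))
}
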