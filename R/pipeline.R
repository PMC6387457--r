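#' Configuration of a full simulate-reconstruct-filter-traits-stats run
#'
#' All tunables of the pipeline in one serializable object; validation
#' happens here, before any computation. A run's configuration is written
#' beside its outputs so every result directory is reproducible.
#'
#' @param seed master seed; every stage draws from sub-streams derived
#'   from it (see [derive_seed()]).
#' @param plots_per_field plots simulated per field.
#' @param fields named list of [species_profile()]s.
#' @param use_fusion reconstruct clouds from rendered depth frames (the
#'   full sensing chain); `FALSE` extracts traits from the generator's
#'   ground-truth clouds directly.
#' @param n_frames depth frames per cloud when fusing.
#' @param noise_sd depth noise SD, m.
#' @param voxel_size,truncation TSDF resolution, m.
#' @param k,outlier_mode,multiplier outlier-filter settings
#'   (see [remove_outliers()]).
#' @param alpha alpha-shape radius, m.
#' @param cell_size trait raster cell size, m.
#' @param height_threshold cover-area threshold above ground, m.
#' @param intrinsics a [camera_intrinsics()].
#' @param out_dir output directory (`NULL` = keep results in memory only).
#' @param write_clouds write filtered clouds as PLY under `out_dir`.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, plots_per_field = 10,
                       fields = list(ryegrass = ryegrass_profile(),
                                     timothy = timothy_profile()),
                       use_fusion = TRUE, n_frames = 6, noise_sd = 0.003,
                       voxel_size = 0.008, truncation = 4 * voxel_size,
                       k = 64, outlier_mode = "mean_plus_sd", multiplier = 1,
                       alpha = 0.2, cell_size = 0.02, height_threshold = 0.05,
                       intrinsics = camera_intrinsics(width = 128L,
                                                      height = 106L),
                       out_dir = NULL, write_clouds = TRUE) {
  if (alpha <= 0) stop("config validation: alpha must be > 0")
  if (voxel_size <= 0) stop("config validation: voxel_size must be > 0")
  if (cell_size <= 0) stop("config validation: cell_size must be > 0")
  if (plots_per_field < 1) stop("config validation: plots_per_field >= 1")
  if (!length(fields) || is.null(names(fields)))
    stop("config validation: fields must be a named list of species profiles")
  for (f in fields) stopifnot(inherits(f, "species_profile"))
  structure(as.list(environment()), class = "run_config")
}

#' Simulate a field of ground-truth plots
#'
#' @param profile a [species_profile()].
#' @param n_plots number of 1 m2 plots.
#' @param master_seed run master seed.
#' @param field_label label used in ids and seed derivation.
#' @return list of `ground_truth_plot`s.
#' @export
simulate_field <- function(profile, n_plots = 10, master_seed = 1,
                           field_label = profile$name) {
  lapply(seq_len(n_plots), function(i) {
    sp <- plot_spec(plot_id = sprintf("%s_p%02d", field_label, i),
                    species = profile,
                    seed = derive_seed(master_seed, paste0("plot-", field_label), i))
    generate_canopy(sp)
  })
}

# 95th-percentile difference height per quadrant of the plot extent
.quadrant_heights <- function(diff_raster, extent = c(1, 1)) {
  d <- diff_raster$data
  cs <- diff_raster$cell_size
  xc <- diff_raster$origin[1] + (seq_len(ncol(d)) - 0.5) * cs
  yc <- diff_raster$origin[2] + (seq_len(nrow(d)) - 0.5) * cs
  qx <- rep(xc, each = nrow(d)) >= extent[1] / 2
  qy <- rep(yc, times = ncol(d)) >= extent[2] / 2
  quad <- ifelse(!qx & !qy, "q1", ifelse(qx & !qy, "q2",
                 ifelse(!qx & qy, "q3", "q4")))
  v <- as.vector(d)
  vapply(c("q1", "q2", "q3", "q4"), function(q) {
    vals <- v[quad == q & is.finite(v)]
    if (!length(vals)) return(NA_real_)
    unname(quantile(vals, 0.95))
  }, numeric(1))
}

# model clouds (pre, post) for one plot: full fusion chain or truth clouds
.model_clouds <- function(truth, config) {
  if (!config$use_fusion)
    return(list(
      pre = crop_cloud(truth$canopy, c(0, truth$spec$extent[1]),
                       c(0, truth$spec$extent[2])),
      post = crop_cloud(truth$stubble, c(0, truth$spec$extent[1]),
                        c(0, truth$spec$extent[2]))))
  traj <- sweep_trajectory(config$n_frames)
  clouds <- lapply(c("canopy", "stubble"), function(wh) {
    fr <- render_depth_frames(truth, traj, config$intrinsics,
                              noise_sd = config$noise_sd, which = wh,
                              surface_cell = 0.006,
                              seed = derive_seed(truth$spec$seed, wh))
    rec <- reconstruct(fr, config$intrinsics, voxel_size = config$voxel_size,
                       truncation = config$truncation)
    # reconstruction lives in the frame of camera 0; the renderer's true
    # first pose anchors it back into the plot frame, and the model is
    # cropped to the 1 m2 sampling plot like the field protocol
    crop_cloud(transform_cloud(rec$cloud, traj[[1]]),
               xlim = c(0, truth$spec$extent[1]),
               ylim = c(0, truth$spec$extent[2]))
  })
  names(clouds) <- c("pre", "post")
  clouds
}

#' Run the full sward-characterization pipeline
#'
#' simulate -> render -> reconstruct -> filter -> traits -> statistics for
#' every plot of every configured field. Deterministic for a fixed config;
#' when `config$out_dir` is set, writes the ground-truth table, trait
#' records, paired samples, statistics summary, the exact configuration
#' and a log, plus filtered clouds as PLY if requested.
#'
#' @param config a [run_config()].
#' @return list with `truth` (per-field lists of ground-truth plots),
#'   `traits` (data frame of trait records), `pairs` (all
#'   [paired_samples()] rows), `stats` (list of fitted relationships) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- c(sprintf("swardscan pipeline, master seed %d", config$seed),
                 sprintf("defaults: alpha %.3g m, k %d, mode %s, voxel %.3g m, cell %.3g m",
                         config$alpha, config$k, config$outlier_mode,
                         config$voxel_size, config$cell_size))
  truth_all <- list()
  trait_rows <- list()
  pair_rows <- list()

  for (fname in names(config$fields)) {
    profile <- config$fields[[fname]]
    truth <- simulate_field(profile, config$plots_per_field, config$seed,
                            field_label = fname)
    truth_all[[fname]] <- truth
    for (tr in truth) {
      stage <- sprintf("plot %s", tr$plot_id)
      clouds <- tryCatch(.model_clouds(tr, config), error = function(e)
        stop("stage reconstruct failed for ", stage, ": ",
             conditionMessage(e)))
      filt <- tryCatch(list(
        pre = remove_outliers(clouds$pre, k = config$k,
                              mode = config$outlier_mode,
                              multiplier = config$multiplier),
        post = remove_outliers(clouds$post, k = config$k,
                               mode = config$outlier_mode,
                               multiplier = config$multiplier)),
        error = function(e) stop("stage filter failed for ", stage, ": ",
                                 conditionMessage(e)))
      log_lines <- c(log_lines, sprintf(
        "%s: filtered %d + %d points (pre + post)", stage,
        length(filt$pre$report$removed), length(filt$post$report$removed)))
      rec <- tryCatch(
        extract_traits(filt$pre$cloud, filt$post$cloud, plot_id = tr$plot_id,
                       alpha = config$alpha, cell_size = config$cell_size,
                       height_threshold = config$height_threshold,
                       ground_level = 0),
        error = function(e) stop("stage traits failed for ", stage, ": ",
                                 conditionMessage(e)))
      hd <- height_by_differencing(filt$pre$cloud, filt$post$cloud,
                                   config$cell_size)
      qh <- .quadrant_heights(hd$raster, extent = tr$spec$extent)
      rec$field <- fname
      rec$plate_height_m <- tr$plate_meter_height
      rec$tape_mean_m <- mean(tr$tape_heights)
      rec$dry_biomass_kg_m2 <- tr$dry_biomass
      trait_rows[[tr$plot_id]] <- rec
      ok <- is.finite(qh)
      if (any(ok))
        pair_rows[[paste0(tr$plot_id, "_hq")]] <- paired_samples(
          plot_id = tr$plot_id, x = tr$tape_heights[c("q1", "q2", "q3", "q4")][ok],
          y = qh[ok], field = fname, level = "quadrant",
          quadrant = names(qh)[ok])
    }
  }

  traits <- do.call(rbind, trait_rows)
  rownames(traits) <- NULL
  pairs_quad <- do.call(rbind, pair_rows)
  rownames(pairs_quad) <- NULL

  stats <- pipeline_statistics(traits, pairs_quad)

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    gt <- do.call(rbind, lapply(unlist(truth_all, recursive = FALSE),
                                ground_truth_row))
    write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
    write.csv(traits, file.path(out_dir, "traits.csv"), row.names = FALSE)
    write.csv(pairs_quad, file.path(out_dir, "pairs_quadrant.csv"),
              row.names = FALSE)
    writeLines(stats_report(stats), file.path(out_dir, "stats_report.txt"))
    cfg <- config
    cfg$fields <- lapply(cfg$fields, unclass)
    cfg$intrinsics <- unclass(cfg$intrinsics)
    jsonlite::write_json(cfg[setdiff(names(cfg), "out_dir")],
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    if (isTRUE(config$write_clouds)) {
      for (fname in names(truth_all)) for (tr in truth_all[[fname]]) {
        write_ply(tr$canopy, file.path(out_dir,
                                       paste0(tr$plot_id, "_canopy.ply")))
      }
    }
  }
  list(truth = truth_all, traits = traits, pairs = pairs_quad,
       stats = stats, out_dir = out_dir)
}

# one CSV row of a plot's ground truth (tape q1..q4 + center, plate, biomass)
ground_truth_row <- function(tr) {
  data.frame(plot_id = tr$plot_id,
             q1 = tr$tape_heights[["q1"]], q2 = tr$tape_heights[["q2"]],
             q3 = tr$tape_heights[["q3"]], q4 = tr$tape_heights[["q4"]],
             center = tr$tape_heights[["center"]],
             plate_m = tr$plate_meter_height,
             biomass_kg_m2 = tr$dry_biomass, stringsAsFactors = FALSE)
}

#' Validation statistics over pipeline outputs
#'
#' Per-field simple regressions of estimated height on tape height
#' (quadrant and plot level), of estimated mean height and alpha volume on
#' dry biomass, the between-field equality-of-lines test for the
#' height-biomass relationship, and the quadrant-replicate lack-of-fit
#' test of estimated height against plate-meter height.
#'
#' @param traits trait data frame from [run_pipeline()].
#' @param pairs_quad quadrant-level [paired_samples()].
#' @return named list of fitted results.
#' @export
pipeline_statistics <- function(traits, pairs_quad) {
  fields <- unique(traits$field)
  out <- list()
  for (f in fields) {
    tf <- traits[traits$field == f, ]
    pq <- pairs_quad[pairs_quad$field == f, ]
    out[[f]] <- list(
      height_quadrant = try_fit(pq),
      height_plot = try_fit(aggregate_quadrants_to_plots(pq)),
      biomass_height = try_fit(paired_samples(
        tf$plot_id, x = tf$dry_biomass_kg_m2, y = tf$mean_height_m,
        field = f, level = "plot")),
      biomass_volume = try_fit(paired_samples(
        tf$plot_id, x = tf$dry_biomass_kg_m2, y = tf$alpha_volume_m3,
        field = f, level = "plot")),
      volume_plate = try_fit(paired_samples(
        tf$plot_id, x = tf$plate_height_m, y = tf$alpha_volume_m3,
        field = f, level = "plot"))
    )
    # lack of fit: quadrant estimates replicate the plot-level plate height
    lof_df <- merge(pq, data.frame(plot_id = tf$plot_id,
                                   plate = tf$plate_height_m), by = "plot_id")
    out[[f]]$lack_of_fit <- tryCatch(
      lack_of_fit_test(data.frame(x = lof_df$plate, y = lof_df$y)),
      error = function(e) NULL)
  }
  if (length(fields) >= 2) {
    # equality-of-lines contrast at quadrant level (plot biomass replicated
    # over the four quadrant height estimates: n = 4 x plots per field)
    quad_bio <- function(f) {
      tf <- traits[traits$field == f, ]
      pq <- pairs_quad[pairs_quad$field == f, ]
      mg <- merge(pq, data.frame(plot_id = tf$plot_id,
                                 biomass = tf$dry_biomass_kg_m2),
                  by = "plot_id")
      paired_samples(mg$plot_id, x = mg$biomass, y = mg$y, field = f,
                     level = "quadrant", quadrant = mg$quadrant)
    }
    out$field_contrast <- tryCatch(
      compare_fields(quad_bio(fields[1]), quad_bio(fields[2])),
      error = function(e) NULL)
  }
  out
}

try_fit <- function(samples) {
  tryCatch(fit_simple_regression(samples), error = function(e) NULL)
}

# human-readable statistics report
stats_report <- function(stats) {
  lines <- character()
  for (f in setdiff(names(stats), "field_contrast")) {
    lines <- c(lines, sprintf("== field: %s ==", f))
    for (rel in c("height_quadrant", "height_plot", "biomass_height",
                  "biomass_volume", "volume_plate")) {
      fit <- stats[[f]][[rel]]
      lines <- c(lines, if (is.null(fit)) sprintf("%s: not estimable", rel)
                 else sprintf(
        "%s: R2 = %.3f, r = %.3f, slope %.3g (SE %.3g), n = %d",
        rel, fit$r_squared, fit$pearson_r, fit$slope, fit$slope_se, fit$n))
    }
    lof <- stats[[f]]$lack_of_fit
    if (!is.null(lof))
      lines <- c(lines, sprintf("lack_of_fit: F(%d, %d) = %.3g, p = %.3g",
                                lof$df_lof, lof$df_pe, lof$F, lof$p_value))
  }
  fc <- stats$field_contrast
  if (!is.null(fc))
    lines <- c(lines, sprintf(
      "field contrast (height~biomass): F(%d, %d) = %.3g, p = %.3g",
      fc$df1, fc$df2, fc$F, fc$p_value))
  lines
}
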