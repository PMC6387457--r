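#' Paired validation samples
#'
#' Tidy container pairing ground-truth (`x`) with model estimates (`y`) at
#' quadrant or plot level, used by all validation statistics.
#'
#' @param plot_id plot labels.
#' @param x ground-truth values.
#' @param y estimated values.
#' @param field field label (e.g. `"ryegrass"`, `"timothy"`).
#' @param level `"plot"` or `"quadrant"`.
#' @param quadrant quadrant labels (`NA` at plot level).
#' @return data frame of class `paired_samples`.
#' @export
paired_samples <- function(plot_id, x, y, field = "field",
                           level = c("plot", "quadrant"), quadrant = NA) {
  level <- match.arg(level)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  df <- data.frame(plot_id = as.character(plot_id),
                   quadrant = as.character(quadrant),
                   field = as.character(field), level = level,
                   x = as.numeric(x), y = as.numeric(y),
                   stringsAsFactors = FALSE)
  class(df) <- c("paired_samples", class(df))
  df
}

#' Simple linear regression of estimates on ground truth
#'
#' Ordinary least squares `y ~ x` with Pearson correlation, R-squared,
#' coefficient standard errors and residual standard error — the per-field
#' validation fit.
#'
#' @param samples a [paired_samples()] data frame (or any data frame with
#'   `x` and `y`).
#' @return list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `pearson_r`, `slope_se`, `intercept_se`, `residual_se`,
#'   `n`.
#' @export
fit_simple_regression <- function(samples) {
  x <- samples$x; y <- samples$y
  n <- length(x)
  if (n < 3) stop("need at least 3 samples, got ", n)
  if (sd(x) == 0) stop("x is constant: regression undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  r <- sign(coef(fit)[["x"]]) * sqrt(max(0, sm$r.squared))
  structure(list(slope = unname(coef(fit)[["x"]]),
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 r_squared = sm$r.squared,
                 pearson_r = unname(r),
                 slope_se = sm$coefficients["x", "Std. Error"],
                 intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
                 residual_se = sm$sigma,
                 n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "regression_result: y = %.4g + %.4g x  (n = %d)\n  R2 = %.4f, r = %.4f, SE(slope) = %.3g, SE(intercept) = %.3g, residual SE = %.3g\n",
    x$intercept, x$slope, x$n, x$r_squared, x$pearson_r, x$slope_se,
    x$intercept_se, x$residual_se))
  invisible(x)
}

#' Lack-of-fit F test for a simple linear regression
#'
#' Splits the residual sum of squares into pure error (within groups of
#' replicated `x`) and lack of fit, and tests the linear model against the
#' saturated group-means model. Quadrants sharing a plot-level `x` supply
#' the replication.
#'
#' @param samples data frame with `x` and `y`; at least one `x` value must
#'   have >= 2 replicates.
#' @return list of class `lack_of_fit_result`: `F`, `df_lof`, `df_pe`,
#'   `p_value`, `ss_lack_of_fit`, `ss_pure_error`, `ss_model`, `ss_total`.
#' @export
lack_of_fit_test <- function(samples) {
  x <- samples$x; y <- samples$y
  g <- factor(x)
  if (max(table(g)) < 2)
    stop("no replicated x values: use quadrant-level data, where quadrants ",
         "within a plot replicate the plot-level x")
  n <- length(y)
  n_groups <- nlevels(g)
  m_lin <- lm(y ~ x)
  m_sat <- lm(y ~ g)
  ss_pe <- sum(residuals(m_sat)^2)
  ss_lof <- max(0, sum(residuals(m_lin)^2) - ss_pe)
  df_pe <- n - n_groups
  df_lof <- n_groups - 2L
  ss_total <- sum((y - mean(y))^2)
  ss_model <- ss_total - ss_lof - ss_pe
  if (df_lof <= 0) {
    Fstat <- 0; p <- NA_real_
  } else {
    Fstat <- (ss_lof / df_lof) / (ss_pe / df_pe)
    p <- pf(Fstat, df_lof, df_pe, lower.tail = FALSE)
  }
  structure(list(F = Fstat, df_lof = df_lof, df_pe = df_pe, p_value = p,
                 ss_lack_of_fit = ss_lof, ss_pure_error = ss_pe,
                 ss_model = ss_model, ss_total = ss_total),
            class = "lack_of_fit_result")
}

#' @export
print.lack_of_fit_result <- function(x, ...) {
  cat(sprintf(
    "lack_of_fit_result: F(%d, %d) = %.4g, p = %.4g\n  SS lack-of-fit %.4g, SS pure error %.4g\n",
    x$df_lof, x$df_pe, x$F, x$p_value, x$ss_lack_of_fit, x$ss_pure_error))
  invisible(x)
}

#' Compare the validation relationship between two fields
#'
#' Fits each field's simple regression and tests whether one line fits
#' both fields: a pooled model with field-specific slope and intercept is
#' compared against the common line by an F test on the interaction terms
#' (2 numerator degrees of freedom).
#'
#' @param field1,field2 [paired_samples()] data frames for the two fields.
#' @return list of class `field_comparison`: `fit1`, `fit2`
#'   ([fit_simple_regression()] results), `F`, `df1`, `df2`, `p_value`.
#' @export
compare_fields <- function(field1, field2) {
  fit1 <- fit_simple_regression(field1)
  fit2 <- fit_simple_regression(field2)
  lab1 <- if (length(unique(field1$field)) == 1) field1$field[1] else "field1"
  lab2 <- if (length(unique(field2$field)) == 1) field2$field[1] else "field2"
  if (identical(lab1, lab2)) { lab1 <- "field1"; lab2 <- "field2" }
  pooled <- data.frame(
    x = c(field1$x, field2$x), y = c(field1$y, field2$y),
    field = factor(c(rep(lab1, nrow(field1)), rep(lab2, nrow(field2)))))
  m0 <- lm(y ~ x, data = pooled)
  m1 <- lm(y ~ x * field, data = pooled)
  aov_tab <- anova(m0, m1)
  Fstat <- aov_tab$F[2]
  if (!is.finite(Fstat)) Fstat <- 0
  structure(list(fit1 = fit1, fit2 = fit2, F = Fstat,
                 df1 = aov_tab$Df[2], df2 = aov_tab$Res.Df[2],
                 p_value = aov_tab$`Pr(>F)`[2]),
            class = "field_comparison")
}

#' @export
print.field_comparison <- function(x, ...) {
  cat(sprintf("field_comparison: interaction F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p_value))
  cat(sprintf("  field 1: R2 = %.4f (n = %d)   field 2: R2 = %.4f (n = %d)\n",
              x$fit1$r_squared, x$fit1$n, x$fit2$r_squared, x$fit2$n))
  invisible(x)
}

#' Average quadrant-level pairs to plot level
#'
#' Arithmetic mean of `x` and `y` per plot; plots with fewer than four
#' quadrants are averaged over the available quadrants (with a message),
#' not dropped.
#'
#' @param samples quadrant-level [paired_samples()].
#' @return plot-level [paired_samples()].
#' @export
aggregate_quadrants_to_plots <- function(samples) {
  stopifnot(all(c("plot_id", "x", "y") %in% names(samples)))
  key <- interaction(samples$field, samples$plot_id, drop = TRUE)
  cnt <- tapply(samples$x, key, length)
  if (any(cnt < 4))
    message(sum(cnt < 4), " plot(s) averaged over fewer than 4 quadrants")
  agg_x <- tapply(samples$x, key, mean)
  agg_y <- tapply(samples$y, key, mean)
  first <- !duplicated(key)
  meta <- samples[first, c("plot_id", "field")]
  idx <- match(names(agg_x), as.character(key[first]))
  paired_samples(plot_id = meta$plot_id[idx], x = as.numeric(agg_x),
                 y = as.numeric(agg_y), field = meta$field[idx],
                 level = "plot")
}
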