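test_that("an exact linear relationship is recovered exactly", {
  x <- 1:10
  s <- paired_samples(plot_id = as.character(1:10), x = x, y = 2 * x + 1)
  # base lm warns that a perfect fit makes its summary unreliable
  fit <- suppressWarnings(fit_simple_regression(s))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit$residual_se, 0, tolerance = 1e-12)
  expect_identical(fit$n, 10L)
})

test_that("OLS matches the normal equations and R2 = r^2 on random data", {
  set.seed(15)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- 1.5 * x + rnorm(n)
    fit <- fit_simple_regression(data.frame(x = x, y = y))
    X <- cbind(1, x)
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
    expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-12)
    expect_equal(fit$pearson_r, cor(x, y), tolerance = 1e-10)
  }
})

test_that("degenerate regressions are rejected", {
  expect_error(fit_simple_regression(data.frame(x = c(1, 2), y = c(1, 2))),
               "at least 3")
  expect_error(fit_simple_regression(data.frame(x = rep(2, 5), y = rnorm(5))),
               "constant")
})

test_that("independent x and y give near-zero R2 at large n", {
  set.seed(2)
  x <- rnorm(1e4); y <- rnorm(1e4)
  fit <- fit_simple_regression(data.frame(x = x, y = y))
  expect_lt(fit$r_squared, 0.05)
})

test_that("lack-of-fit decomposition behaves on canonical cases", {
  # two replicate groups, perfect linear fit through group means
  df <- data.frame(x = c(1, 1, 2, 2), y = c(1, 3, 4, 6))
  lof <- lack_of_fit_test(df)
  expect_equal(lof$F, 0)
  expect_equal(lof$ss_lack_of_fit, 0, tolerance = 1e-12)
  expect_gt(lof$ss_pure_error, 0)
  # sums of squares decompose the corrected total
  set.seed(4)
  df2 <- data.frame(x = rep(1:6, each = 4))
  df2$y <- 0.5 + 2 * df2$x + 0.3 * df2$x^2 + rnorm(nrow(df2), 0, 0.3)
  lof2 <- lack_of_fit_test(df2)
  expect_equal(lof2$ss_total,
               lof2$ss_model + lof2$ss_lack_of_fit + lof2$ss_pure_error,
               tolerance = 1e-9 * lof2$ss_total)
  expect_true(all(c(lof2$ss_model, lof2$ss_lack_of_fit,
                    lof2$ss_pure_error) >= 0))
  expect_error(lack_of_fit_test(data.frame(x = 1:8, y = rnorm(8))),
               "replicated")
})

test_that("a strongly quadratic relationship fails the lack-of-fit test", {
  set.seed(6)
  x <- rep(seq(0, 1, length.out = 10), each = 4)   # n = 40
  y <- 4 * (x - 0.5)^2 + rnorm(length(x), 0, 0.05)
  lof <- lack_of_fit_test(data.frame(x = x, y = y))
  expect_lt(lof$p_value, 0.01)
})

test_that("field comparison detects equal and different lines correctly", {
  set.seed(12)
  x <- rnorm(30); y <- 2 + x + rnorm(30, 0, 0.2)
  f1 <- paired_samples(as.character(1:30), x, y, field = "a")
  f2 <- paired_samples(as.character(1:30), x, y, field = "b")
  same <- compare_fields(f1, f2)
  expect_equal(same$F, 0, tolerance = 1e-9)
  # clearly different slopes
  y2 <- 2 - x + rnorm(30, 0, 0.2)
  diff <- compare_fields(f1, paired_samples(as.character(1:30), x, y2,
                                            field = "b"))
  expect_lt(diff$p_value, 1e-6)
  expect_identical(diff$fit1$n, 30L)
})

test_that("quadrant aggregation averages x and y per plot", {
  s <- paired_samples(plot_id = rep(c("p1", "p2"), each = 4),
                      x = c(rep(2, 4), 1:4), y = c(rep(5, 4), 11:14),
                      field = "f", level = "quadrant",
                      quadrant = rep(paste0("q", 1:4), 2))
  agg <- aggregate_quadrants_to_plots(s)
  agg <- agg[order(agg$plot_id), ]
  expect_equal(agg$x, c(2, 2.5))
  expect_equal(agg$y, c(5, 12.5))
  expect_identical(nrow(agg), 2L)
  expect_message(
    aggregate_quadrants_to_plots(s[-1, ]), "fewer than 4 quadrants")
})

test_that("plot-level aggregation strengthens noisy linear relationships", {
  # averaging the within-plot replicates reduces noise in y, so plot-level
  # R2 exceeds quadrant-level R2 in expectation
  set.seed(33)
  n_rep <- 200
  gains <- replicate(n_rep, {
    plot_x <- runif(10, 0.3, 0.8)
    x <- rep(plot_x, each = 4) + rnorm(40, 0, 0.05)
    y <- 1.2 * x + rnorm(40, 0, 0.08)
    s <- paired_samples(rep(sprintf("p%02d", 1:10), each = 4), x, y,
                        level = "quadrant",
                        quadrant = rep(paste0("q", 1:4), 10))
    rq <- fit_simple_regression(s)$r_squared
    rp <- fit_simple_regression(aggregate_quadrants_to_plots(s))$r_squared
    rp - rq
  })
  expect_gt(mean(gains), 0)
})

test_that("a timothy-like truth correlation reproduces the expected R2", {
  # population r chosen at 0.94 (R2 0.884); the mean fitted R2 over many
  # 10-plot fields sits near 0.88
  set.seed(44)
  r_target <- 0.94
  sd_h <- 0.10; slope <- 0.85
  noise <- slope * sd_h * sqrt(1 / r_target^2 - 1)
  r2s <- replicate(300, {
    h <- rnorm(10, 0.6, sd_h)
    b <- 0.03 + slope * h + rnorm(10, 0, noise)
    fit_simple_regression(data.frame(x = b, y = h))$r_squared
  })
  expect_lt(abs(mean(r2s) - 0.88), 0.05)
})
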