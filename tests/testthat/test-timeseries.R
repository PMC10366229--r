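test_that("load_series reads files, directories and replicate columns", {
  dir <- withr::local_tempdir()
  t <- seq(0, 1, by = 0.05)
  for (k in 1:2) {
    utils::write.csv(
      data.frame(time = t, A = cos(2 * pi * t) + k, B = sin(2 * pi * t)),
      file.path(dir, sprintf("rep%d.csv", k)),
      row.names = FALSE
    )
  }
  raw <- load_series(dir)
  expect_s3_class(raw, "raw_series_set")
  expect_length(raw$replicates, 2)
  expect_identical(raw$components, c("A", "B"))

  df <- data.frame(
    time = rep(t, 3), rep = rep(1:3, each = length(t)),
    A = rep(t, 3)^2 + rep(1:3, each = length(t))
  )
  raw2 <- load_series(df, replicate_col = "rep")
  expect_length(raw2$replicates, 3)

  bad <- data.frame(time = c(0, 1, 1, 2), A = 1:4)
  expect_error(load_series(bad), "non-monotone")
  expect_error(load_series(data.frame(t = t, A = t)), "time column")
})

test_that("normalization maps to [0,1], is idempotent and flags constants", {
  t <- seq(0, 1, length.out = 10)
  raw <- raw_series_set(list(list(
    times = t,
    values = cbind(A = c(2, 4, 6, rep(4, 7)), B = rep(5, 10))
  )))
  norm <- normalize_series(raw)
  expect_equal(norm$replicates[[1]]$values[1:3, "A"], c(0, 0.5, 1),
               ignore_attr = TRUE)
  expect_equal(norm$replicates[[1]]$values[, "B"], rep(0, 10),
               ignore_attr = TRUE)
  expect_identical(attr(norm, "degenerate")[[1]], "B")
  # idempotence
  again <- normalize_series(norm)
  expect_equal(again$replicates[[1]]$values[, "A"],
               norm$replicates[[1]]$values[, "A"])
})

test_that("processing is invariant under positive affine maps of the raw data", {
  t <- seq(0, 0.99, by = 0.01)
  mk <- function(a, b) {
    raw_series_set(list(list(times = t, values = cbind(
      X = a * cos(2 * pi * t) + b, Y = a * sin(2 * pi * t) + b
    ))))
  }
  p1 <- interpolate_and_differentiate(mk(1, 0), "spline")[[1]]
  p2 <- interpolate_and_differentiate(mk(3.7, -2), "spline")[[1]]
  expect_equal(p1$values, p2$values, tolerance = 1e-8)
  expect_equal(p1$derivatives, p2$derivatives, tolerance = 1e-8)
})

test_that("fourier fit recovers the analytic derivative of a cosine", {
  t <- seq(0, 0.99, by = 0.01)
  raw <- raw_series_set(list(list(times = t, values = cbind(X = cos(2 * pi * t)))))
  ps <- interpolate_and_differentiate(raw, "fourier", order = 1,
                                      estimate_noise = FALSE)[[1]]
  # derivative is reported in normalized units: scaled by 1 / range = 1/2
  expected <- -2 * pi * sin(2 * pi * ps$grid) / 2
  interior <- seq(5, 95)
  expect_lt(max(abs(ps$derivatives[interior, "X"] - expected[interior])), 1e-3)
})

test_that("spline derivatives are exact for low-degree polynomials", {
  t <- seq(0, 1, length.out = 30)
  raw <- raw_series_set(list(list(times = t, values = cbind(
    lin = 2 * t + 1, quad = t^2, cub = t^3
  ))))
  ps <- interpolate_and_differentiate(raw, "spline", grid_size = 50,
                                      estimate_noise = FALSE)[[1]]
  interior <- 5:45
  g <- ps$grid[interior]
  # normalized-unit derivatives: divide the analytic derivative by the range
  expect_lt(max(abs(ps$derivatives[interior, "lin"] - 1)), 1e-8)
  expect_lt(max(abs(ps$derivatives[interior, "quad"] - 2 * g / max(t^2))), 1e-7)
  # the cubic's central difference carries an O(h^2) truncation error
  expect_lt(max(abs(ps$derivatives[interior, "cub"] - 3 * g^2 / max(t^3))), 1e-2)
})

test_that("fourier smoothing reduces the residual of a noisy sine", {
  set.seed(42)
  t <- seq(0, 0.99, by = 0.01)
  clean <- sin(2 * pi * t) + 2
  noisy <- clean * (1 + stats::rnorm(length(t), sd = 0.1))
  raw <- raw_series_set(list(list(times = t, values = cbind(X = noisy))))
  ps <- interpolate_and_differentiate(raw, "fourier", order = 4,
                                      estimate_noise = FALSE)[[1]]
  fitted_at_t <- ps$fits$X$predict(t)
  expect_lt(stats::var(fitted_at_t - clean), stats::var(noisy - clean))
})

test_that("noise-level estimator is calibrated against seeded multiplicative noise", {
  spec <- fixtures("SFL")
  ests <- vapply(1:20, function(s) {
    data <- add_noise(simulate_network(spec, n_replicates = 2, seed = s),
                      10, seed = s + 100)
    raw <- as_raw_series(data)
    fitted <- interpolate_and_differentiate(raw, "fourier", order = 4,
                                            estimate_noise = FALSE)
    estimate_noise_level(raw, fitted)
  }, numeric(1))
  expect_true(all(ests > 5 & ests < 15))

  # near zero for noiseless data
  data0 <- simulate_network(spec, n_replicates = 2, seed = 1)
  raw0 <- as_raw_series(data0)
  fit0 <- interpolate_and_differentiate(raw0, "fourier", order = 4,
                                        estimate_noise = FALSE)
  expect_lt(estimate_noise_level(raw0, fit0), 2)

  # doubling the noise doubles the estimate (to 30%)
  est5 <- mean(vapply(1:5, function(s) {
    data <- add_noise(simulate_network(spec, n_replicates = 2, seed = s),
                      5, seed = s + 100)
    raw <- as_raw_series(data)
    estimate_noise_level(raw, interpolate_and_differentiate(
      raw, "fourier", order = 4, estimate_noise = FALSE))
  }, numeric(1)))
  est10 <- mean(ests)
  expect_gt(est10 / est5, 2 * 0.7)
  expect_lt(est10 / est5, 2 * 1.3)
})

test_that("period estimation finds the first autocorrelation peak", {
  t <- seq(0, 30, by = 0.05)
  expect_equal(estimate_period(t, sin(2 * pi * t / 5)), 5, tolerance = 0.02)

  set.seed(7)
  noisy <- sin(2 * pi * t / 5) * (1 + stats::rnorm(length(t), sd = 0.1))
  expect_equal(estimate_period(t, noisy), 5, tolerance = 0.25)

  # white noise is rejected as aperiodic in the typical case
  aperiodic <- vapply(1:10, function(s) {
    set.seed(s)
    inherits(try(estimate_period(t, stats::rnorm(length(t))), silent = TRUE),
             "try-error")
  }, logical(1))
  expect_gte(sum(aperiodic), 8)
})

test_that("moving windows match the closed-form segment count", {
  t <- seq(0, 10, by = 0.1)
  x <- cbind(A = sin(t))
  expect_length(moving_window_segments(t, x, window = 2, overlap_fraction = 0.5), 9)
  expect_length(moving_window_segments(t, x, window = 2, overlap_fraction = 0), 5)
  expect_length(moving_window_segments(t, x, window = 10, overlap_fraction = 0.9), 1)
  expect_error(moving_window_segments(t, x, window = 11), "duration")

  # property: count equals floor((D - W) / ((1 - o) W)) + 1
  set.seed(3)
  for (i in 1:20) {
    W <- stats::runif(1, 0.5, 9)
    o <- stats::runif(1, 0, 0.95)
    segs <- moving_window_segments(t, x, W, o)
    expect_length(segs, floor((10 - W) / ((1 - o) * W) + 1e-9) + 1)
    # every window fully inside the series
    for (s in segs) expect_true(min(s$times) >= 0 && max(s$times) <= 10)
  }
})

test_that("moving average is centered, shrinks at the ends, and smooths", {
  x <- c(1, -1, 1, -1, 1, -1)
  expect_identical(moving_average(x, 1), x)
  expect_equal(moving_average(rep(4, 9), 7), rep(4, 9))
  sm <- moving_average(x, 3)
  expect_equal(sm[2:5], c(1 / 3, -1 / 3, 1 / 3, -1 / 3))
  expect_equal(sm[1], 0) # shrunken end window: mean(1, -1)
  expect_error(moving_average(x, 0), "width")
  expect_error(moving_average(x, 4), "odd")
  expect_error(moving_average(x, 7), "length")
})

test_that("processed series round-trip to CSV with a JSON sidecar", {
  ps <- noiseless_dataset("fig1_pair", n = 1)[[1]]
  path <- file.path(withr::local_tempdir(), "rep.csv")
  write_processed_series(ps, path)
  back <- utils::read.csv(path)
  expect_equal(back$X, unname(ps$values[, "X"]))
  meta <- jsonlite::read_json(sub("csv$", "json", path), simplifyVector = TRUE)
  expect_identical(meta$fit_method, "exact")
})
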