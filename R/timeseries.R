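# Ingestion, normalization, interpolation/differentiation, segmentation and
# noise profiling of raw time-series replicates.

#' Construct a raw time-series replicate set
#'
#' A `raw_series_set` holds one or more replicates of a multivariate time
#' series: each replicate has a strictly increasing time vector and one value
#' column per observed component.
#'
#' @param replicates List of replicates; each a list with elements `times`
#'   (numeric, strictly increasing, length >= 4) and `values` (numeric matrix,
#'   one column per component).
#' @param components Character vector of component names. Defaults to the
#'   column names of the first replicate's value matrix.
#' @param metadata Free-form provenance list.
#' @return An object of class `raw_series_set`.
#' @export
raw_series_set <- function(replicates, components = NULL, metadata = list()) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  if (is.null(components)) components <- colnames(replicates[[1]]$values)
  if (is.null(components)) {
    components <- paste0("X", seq_len(ncol(replicates[[1]]$values)))
  }
  replicates <- lapply(replicates, function(rep) {
    times <- as.numeric(rep$times)
    values <- as.matrix(rep$values)
    if (length(times) < 4L) {
      stop("each replicate needs at least 4 time points")
    }
    if (any(diff(times) <= 0)) {
      stop("non-monotone times")
    }
    if (nrow(values) != length(times)) {
      stop("times and values have different lengths")
    }
    if (ncol(values) != length(components)) {
      stop("replicates disagree on the number of components")
    }
    if (!all(is.finite(values))) {
      stop("non-numeric cells: all values must be finite")
    }
    colnames(values) <- components
    list(times = times, values = values)
  })
  structure(
    list(replicates = replicates, components = components, metadata = metadata),
    class = "raw_series_set"
  )
}

#' @export
print.raw_series_set <- function(x, ...) {
  cat(sprintf(
    "<raw_series_set> %d replicate(s), %d component(s): %s\n",
    length(x$replicates), length(x$components),
    paste(x$components, collapse = ", ")
  ))
  lens <- vapply(x$replicates, function(r) length(r$times), integer(1))
  cat(sprintf("  samples per replicate: %s\n", paste(lens, collapse = ", ")))
  invisible(x)
}

#' Load time-series replicates from CSV
#'
#' Reads one CSV file (optionally with a replicate column), a directory of
#' CSVs (one replicate each), or an in-memory data frame.
#'
#' @param source Path to a CSV file, a directory of CSV files, or a data frame.
#' @param time_col Name of the time column (default `"time"`).
#' @param replicate_col Optional name of a replicate grouping column.
#' @return A [raw_series_set()].
#' @export
load_series <- function(source, time_col = "time", replicate_col = NULL) {
  frames <- list()
  if (is.data.frame(source)) {
    frames <- list(source)
  } else if (is.character(source) && length(source) == 1 && dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0) stop("no CSV files found in ", source)
    frames <- lapply(files, utils::read.csv)
  } else if (is.character(source)) {
    frames <- lapply(source, utils::read.csv)
  } else {
    stop("source must be a path, a vector of paths, or a data frame")
  }

  split_frame <- function(df) {
    if (!time_col %in% names(df)) stop("missing time column '", time_col, "'")
    if (!is.null(replicate_col) && replicate_col %in% names(df)) {
      groups <- split(df, df[[replicate_col]])
      lapply(groups, function(g) g[setdiff(names(g), replicate_col)])
    } else {
      list(df)
    }
  }
  frames <- unlist(lapply(frames, split_frame), recursive = FALSE)

  reps <- lapply(frames, function(df) {
    value_cols <- setdiff(names(df), time_col)
    if (length(value_cols) < 1) stop("need at least one component column")
    vals <- as.matrix(df[value_cols])
    if (!is.numeric(vals)) stop("non-numeric cells in component columns")
    times <- df[[time_col]]
    if (anyNA(times) || any(diff(times) <= 0)) stop("non-monotone times")
    list(times = as.numeric(times), values = vals)
  })
  raw_series_set(reps, metadata = list(source = if (is.character(source)) source else "data.frame"))
}

#' Min-max normalize every component of every replicate
#'
#' Affinely rescales each component of each replicate to have minimum 0 and
#' maximum 1. Constant components cannot be rescaled; they are set to 0 and
#' flagged as degenerate (attribute `"degenerate"`, one character vector per
#' replicate), and downstream scoring excludes them.
#'
#' @param raw A [raw_series_set()].
#' @return The normalized `raw_series_set` with a `"degenerate"` attribute.
#' @export
normalize_series <- function(raw) {
  stopifnot(inherits(raw, "raw_series_set"))
  degenerate <- vector("list", length(raw$replicates))
  for (i in seq_along(raw$replicates)) {
    vals <- raw$replicates[[i]]$values
    flat <- character(0)
    for (j in seq_len(ncol(vals))) {
      rng <- range(vals[, j])
      if (diff(rng) == 0) {
        vals[, j] <- 0
        flat <- c(flat, raw$components[j])
      } else {
        vals[, j] <- (vals[, j] - rng[1]) / diff(rng)
      }
    }
    raw$replicates[[i]]$values <- vals
    degenerate[[i]] <- flat
  }
  attr(raw, "degenerate") <- degenerate
  raw
}

# ---- fitting backends --------------------------------------------------------

# Fourier-series fit with the fundamental frequency as a free parameter
# (variable projection: linear least squares inside a 1-d search over omega).
fit_fourier <- function(times, y, order = 4, omega = NULL) {
  stopifnot(order >= 1, order <= 8)
  design <- function(t, om) {
    cols <- lapply(seq_len(order), function(j) cbind(cos(j * om * t), sin(j * om * t)))
    cbind(1, do.call(cbind, cols))
  }
  span <- diff(range(times))
  if (span <= 0) stop("degenerate time span")
  # guess the fundamental from the sampled window (one step beyond the span)
  dt <- stats::median(diff(times))
  om0 <- 2 * pi / (span + dt)
  rss <- function(om) {
    fit <- stats::lm.fit(design(times, om), y)
    sum(fit$residuals^2)
  }
  if (is.null(omega)) {
    # RSS is multimodal in omega: coarse grid first, then local refinement
    grid_om <- om0 * seq(0.5, 1.5, length.out = 21)
    best <- grid_om[which.min(vapply(grid_om, rss, numeric(1)))]
    half <- om0 * 0.05
    opt <- stats::optimize(rss, interval = c(best - half, best + half))
    omega <- opt$minimum
  }
  fit <- stats::lm.fit(design(times, omega), y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  predict_at <- function(t) drop(design(t, omega) %*% beta)
  deriv_at <- function(t) {
    cols <- lapply(seq_len(order), function(j) {
      cbind(-j * omega * sin(j * omega * t), j * omega * cos(j * omega * t))
    })
    drop(cbind(0, do.call(cbind, cols)) %*% beta)
  }
  list(
    predict = predict_at, deriv = deriv_at, omega = omega,
    n_coef = 2L * order + 1L, residuals = fit$residuals
  )
}

fit_spline <- function(times, y) {
  f <- stats::splinefun(times, y, method = "fmm")
  list(
    predict = function(t) f(t),
    deriv = NULL, # derivative taken by finite differences on the resampled grid
    n_coef = length(times),
    residuals = rep(0, length(times))
  )
}

# central differences with one-sided ends
central_diff <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d
}

#' Construct a processed (uniform-grid, normalized) replicate
#'
#' @param grid Uniform time grid of length T covering `[t0, t0 + duration)`.
#' @param values T x N matrix of component values, min-max normalized to
#'   `[0, 1]` per component (constant components are 0 and flagged).
#' @param derivatives T x N matrix of time derivatives on the grid (scaled by
#'   the same per-component factor as the values).
#' @param components Component names.
#' @param fit_method `"cubic-spline"`, `"fourier-k"` or `"exact"` (derivatives
#'   supplied by a simulator's vector field).
#' @param noise_level_pct Estimated measurement-noise level, in percent.
#' @param fits Optional list of per-component fit objects (used by
#'   [estimate_noise_level()]).
#' @return An object of class `processed_series`.
#' @export
processed_series <- function(grid, values, derivatives, components,
                             fit_method, noise_level_pct = 0, fits = NULL) {
  values <- as.matrix(values)
  derivatives <- as.matrix(derivatives)
  stopifnot(
    length(grid) == nrow(values), all(dim(values) == dim(derivatives)),
    all(is.finite(derivatives)), noise_level_pct >= 0
  )
  steps <- diff(grid)
  if (any(abs(steps - steps[1]) > 1e-8 * abs(steps[1]))) {
    stop("grid spacing must be constant")
  }
  degenerate <- character(0)
  for (j in seq_len(ncol(values))) {
    rng <- range(values[, j])
    if (diff(rng) == 0) {
      values[, j] <- 0
      derivatives[, j] <- 0
      degenerate <- c(degenerate, components[j])
    } else {
      values[, j] <- (values[, j] - rng[1]) / diff(rng)
      derivatives[, j] <- derivatives[, j] / diff(rng)
    }
  }
  colnames(values) <- components
  colnames(derivatives) <- components
  structure(
    list(
      grid = grid, duration = length(grid) * steps[1], values = values,
      derivatives = derivatives, components = components,
      fit_method = fit_method, noise_level_pct = noise_level_pct,
      degenerate = degenerate, fits = fits
    ),
    class = "processed_series"
  )
}

#' @export
print.processed_series <- function(x, ...) {
  cat(sprintf(
    "<processed_series> T = %d, duration = %.4g, fit = %s, noise = %.2f%%\n",
    length(x$grid), x$duration, x$fit_method, x$noise_level_pct
  ))
  invisible(x)
}

#' Interpolate, resample and differentiate raw replicates
#'
#' Fits each component of each replicate with either a cubic spline or a
#' Fourier series (order `order`, fundamental frequency optimized), resamples
#' the fit on a uniform grid, differentiates it (analytically for Fourier,
#' central differences for spline), and min-max normalizes the result.
#'
#' @param raw A [raw_series_set()].
#' @param method `"fourier"` or `"spline"`.
#' @param order Fourier order (1-8); ignored for spline.
#' @param grid_size Number of uniform grid points per replicate (default 100,
#'   i.e. 100 samples per period when a replicate covers one period).
#' @param estimate_noise If `TRUE` (default), attach the pooled noise-level
#'   estimate of [estimate_noise_level()] to every replicate.
#' @return A list of [processed_series()], one per replicate.
#' @export
interpolate_and_differentiate <- function(raw, method = c("fourier", "spline"),
                                          order = 4, grid_size = 100,
                                          estimate_noise = TRUE) {
  stopifnot(inherits(raw, "raw_series_set"))
  method <- match.arg(method)
  out <- lapply(raw$replicates, function(rep) {
    times <- rep$times
    span <- diff(range(times))
    # resample strictly inside the observed window: no extrapolation
    grid <- seq(times[1], times[length(times)], length.out = grid_size)
    dt <- grid[2] - grid[1]
    vals <- matrix(0, grid_size, length(raw$components))
    ders <- matrix(0, grid_size, length(raw$components))
    fits <- vector("list", length(raw$components))
    names(fits) <- raw$components
    for (j in seq_along(raw$components)) {
      y <- rep$values[, j]
      fit <- tryCatch(
        if (method == "fourier") fit_fourier(times, y, order = order) else fit_spline(times, y),
        error = function(e) stop("fit failure for component '", raw$components[j], "': ", conditionMessage(e))
      )
      vals[, j] <- fit$predict(grid)
      ders[, j] <- if (is.null(fit$deriv)) central_diff(vals[, j], dt) else fit$deriv(grid)
      fits[[j]] <- fit
    }
    fm <- if (method == "fourier") paste0("fourier-", order) else "cubic-spline"
    processed_series(grid, vals, ders, raw$components, fm, fits = fits)
  })
  # an interpolating spline leaves no residual to estimate noise from
  if (estimate_noise && method == "fourier") {
    noise <- estimate_noise_level(raw, out)
    out <- lapply(seq_along(out), function(i) {
      out[[i]]$noise_level_pct <- noise
      out[[i]]
    })
  }
  out
}

#' Estimate the measurement-noise level from fit residuals
#'
#' The noise level (in percent) is approximated from the residual between the
#' raw and fitted series: per component and replicate, the residual
#' root-mean-square relative to the fitted root-mean-square, with a
#' small-sample correction `sqrt(m / (m - p))` for the `p` fitted
#' coefficients; ratios are pooled by root-mean-square. For multiplicative
#' noise `X * (1 + e)`, `e ~ N(0, s^2)`, the estimate approaches `100 * s`.
#'
#' @param raw The [raw_series_set()] the fits came from.
#' @param fitted List of [processed_series()] (with `fits`), as returned by
#'   [interpolate_and_differentiate()].
#' @return Noise level in percent (nonnegative scalar), with per-replicate
#'   estimates in attribute `"per_replicate"`.
#' @export
estimate_noise_level <- function(raw, fitted) {
  stopifnot(inherits(raw, "raw_series_set"), length(fitted) == length(raw$replicates))
  per_rep <- vapply(seq_along(fitted), function(i) {
    ps <- fitted[[i]]
    rep <- raw$replicates[[i]]
    if (is.null(ps$fits)) stop("fitted replicates carry no fit objects")
    ratios <- vapply(seq_along(raw$components), function(j) {
      fit <- ps$fits[[j]]
      yhat <- fit$predict(rep$times)
      resid <- rep$values[, j] - yhat
      m <- length(resid)
      if (m <= fit$n_coef) return(NA_real_)
      rms_fit <- sqrt(mean(yhat^2))
      if (rms_fit == 0) return(NA_real_)
      sqrt(mean(resid^2) * m / (m - fit$n_coef)) / rms_fit
    }, numeric(1))
    ratios <- ratios[is.finite(ratios)]
    if (length(ratios) == 0) stop("empty overlap: no usable residuals")
    sqrt(mean(ratios^2))
  }, numeric(1))
  out <- max(0, 100 * sqrt(mean(per_rep^2)))
  attr(out, "per_replicate") <- 100 * per_rep
  out
}

#' Estimate the dominant period from the autocorrelation function
#'
#' Returns the lag of the first local maximum of the sample autocorrelation at
#' positive lag (refined by parabolic interpolation), in time units. Series
#' whose autocorrelation shows no convincing positive-lag peak (peak height
#' below `min_peak`) are rejected as aperiodic.
#'
#' @param times Strictly increasing, (near-)uniform time vector.
#' @param values Numeric vector, one component's series.
#' @param min_peak Minimum autocorrelation at the peak (default 0.2).
#' @return The period, in the units of `times`.
#' @export
estimate_period <- function(times, values, min_peak = 0.2) {
  stopifnot(length(times) == length(values), length(values) >= 8)
  dt <- stats::median(diff(times))
  ac <- drop(stats::acf(values, lag.max = length(values) - 2L, plot = FALSE)$acf)
  # ac[1] is lag 0
  k <- NA_integer_
  for (i in 3:(length(ac) - 1)) {
    if (ac[i] > ac[i - 1] && ac[i] >= ac[i + 1] && ac[i] > min_peak) {
      k <- i
      break
    }
  }
  if (is.na(k)) stop("aperiodic: no positive-lag autocorrelation peak")
  # parabolic refinement around the peak
  num <- ac[k - 1] - ac[k + 1]
  den <- ac[k - 1] - 2 * ac[k] + ac[k + 1]
  shift <- if (den != 0) 0.5 * num / den else 0
  ((k - 1) + shift) * dt
}

#' Cut a replicate into overlapping moving windows
#'
#' Windows of width `window` are placed from the start of the series and
#' shifted by `(1 - overlap_fraction) * window` until the next window would
#' leave the series; the segment count equals
#' `floor((D - W) / ((1 - o) * W)) + 1` for duration D.
#'
#' @param times,values One replicate (vector / matrix with matching rows).
#' @param window Window width in time units; must not exceed the duration.
#' @param overlap_fraction Fractional overlap of consecutive windows in
#'   `[0, 1)`; default 0.9.
#' @return List of replicates (`times`, `values`), each fully inside the series.
#' @export
moving_window_segments <- function(times, values, window, overlap_fraction = 0.9) {
  values <- as.matrix(values)
  stopifnot(
    length(times) == nrow(values),
    overlap_fraction >= 0, overlap_fraction < 1
  )
  duration <- diff(range(times))
  if (window > duration * (1 + 1e-9)) stop("window exceeds series duration")
  step <- (1 - overlap_fraction) * window
  tol <- 1e-9 * window
  starts <- times[1] + step * (0:floor((duration - window) / step + tol))
  lapply(starts, function(s) {
    sel <- times >= s - tol & times <= s + window + tol
    list(times = times[sel], values = values[sel, , drop = FALSE])
  })
}

#' Centered simple moving average
#'
#' @param x Numeric vector.
#' @param width Odd window width in points; ends are handled by shrinking the
#'   window symmetrically.
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(x, width) {
  if (width < 1) stop("width must be >= 1")
  if (width %% 2 == 0) stop("width must be odd")
  if (width > length(x)) stop("width exceeds series length")
  h <- (width - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Serialize a processed replicate to CSV (+ JSON sidecar)
#'
#' Writes grid, values and derivatives as one CSV, and the fit method, noise
#' level and duration as a JSON sidecar next to it.
#'
#' @param ps A [processed_series()].
#' @param path Output CSV path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_processed_series <- function(ps, path) {
  stopifnot(inherits(ps, "processed_series"))
  df <- data.frame(time = ps$grid)
  for (comp in ps$components) df[[comp]] <- ps$values[, comp]
  for (comp in ps$components) df[[paste0("d_", comp)]] <- ps$derivatives[, comp]
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(
      fit_method = ps$fit_method, noise_level_pct = ps$noise_level_pct,
      duration = ps$duration, components = ps$components,
      degenerate = ps$degenerate
    ),
    sidecar,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
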