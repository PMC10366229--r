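# Ground-truthed synthetic data: monotone regulatory ODE networks, replicate
# ensembles with random initial conditions and driven inputs, and measurement
# noise -- the fixture factory for the whole package.

#' Specify a monotone regulatory ODE network
#'
#' Each non-input component Y evolves as
#' `dY/dt = basal + sum of signed regulation terms - decay * Y`,
#' where a positive edge contributes an increasing term of its source and a
#' negative edge a decreasing one (`kinetics = "linear"`: `+/- w * X`;
#' `kinetics = "hill"`: `w * X^n / (K^n + X^n)` or `w * K^n / (K^n + X^n)`).
#' The linear decay makes every component's self-regulation negative. Input
#' components follow explicit waveforms and are not integrated.
#'
#' @param components Character vector of component names.
#' @param edges Data frame with columns `source`, `sign` (+1/-1), `target`.
#' @param kinetics `"linear"` or `"hill"`.
#' @param weights Numeric vector of edge strengths (recycled; default 1).
#' @param decay Named (or scalar) decay rate per non-input component
#'   (default 1).
#' @param basal Named (or scalar) basal production (default 0).
#' @param hill_k,hill_n Hill threshold and exponent (`kinetics = "hill"`).
#' @param inputs Named list of driven components; each element is a list with
#'   `type` (`"cosine"`, `"sine"` or `"random_fourier"`), `amplitude`,
#'   `period`, and for `random_fourier` the number of `harmonics` (random
#'   smooth signals get fresh seeded coefficients per replicate).
#' @param init_box Named list of `c(lo, hi)` initial-condition ranges for the
#'   integrated components.
#' @param duration Length of the recorded window (default 1; one period for
#'   oscillatory fixtures).
#' @param name Optional fixture name.
#' @param truth Optional ground-truth signed edge data frame (defaults to
#'   `edges`).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(components, edges, kinetics = c("linear", "hill"),
                         weights = 1, decay = 1, basal = 0,
                         hill_k = 1, hill_n = 4,
                         inputs = list(), init_box = NULL, duration = 1,
                         name = NULL, truth = NULL) {
  kinetics <- match.arg(kinetics)
  stopifnot(all(c("source", "sign", "target") %in% names(edges)))
  stopifnot(all(edges$source %in% components), all(edges$target %in% components))
  stopifnot(all(edges$sign %in% c(-1, 1)))
  if (any(edges$target %in% names(inputs))) stop("input components cannot be targets")
  edges$weight <- rep_len(weights, nrow(edges))
  free <- setdiff(components, names(inputs))
  expand <- function(x, default) {
    out <- stats::setNames(rep(default, length(free)), free)
    if (is.null(names(x))) out[] <- rep_len(x, length(free)) else out[names(x)] <- x
    out
  }
  decay <- expand(decay, 1)
  basal <- expand(basal, 0)
  if (is.null(init_box)) {
    init_box <- stats::setNames(rep(list(c(-1, 1)), length(free)), free)
  }
  stopifnot(all(free %in% names(init_box)))
  structure(
    list(
      components = components, edges = edges, kinetics = kinetics,
      decay = decay, basal = basal, hill_k = hill_k, hill_n = hill_n,
      inputs = inputs, init_box = init_box, duration = duration,
      name = name, truth = if (is.null(truth)) edges[c("source", "sign", "target")] else truth
    ),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec%s> %s kinetics, %d component(s), %d edge(s)\n",
    if (is.null(x$name)) "" else paste0(" ", x$name),
    x$kinetics, length(x$components), nrow(x$edges)
  ))
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %s %s %s (w = %g)\n", e$source,
                if (e$sign > 0) "->" else "-|", e$target, e$weight))
  }
  invisible(x)
}

# regulation term of one edge, as a function of the source value; an optional
# `kinetics` column on the edge overrides the spec-wide default
edge_term <- function(spec, edge, x) {
  w <- edge$weight
  kin <- if (!is.null(edge$kinetics) && !is.na(edge$kinetics)) edge$kinetics else spec$kinetics
  if (kin == "linear") {
    return(w * edge$sign * x)
  }
  kn <- spec$hill_k^spec$hill_n
  xn <- pmax(x, 0)^spec$hill_n
  if (edge$sign > 0) w * xn / (kn + xn) else w * kn / (kn + xn)
}

# time derivative of every integrated component given the full state
spec_rates <- function(spec, state) {
  state <- unlist(state)
  free <- names(spec$decay)
  rates <- spec$basal - spec$decay * state[free]
  for (i in seq_len(nrow(spec$edges))) {
    e <- spec$edges[i, ]
    rates[e$target] <- rates[e$target] + edge_term(spec, e, state[[e$source]])
  }
  rates
}

# realized input waveforms: value and derivative closures per input component
input_waves <- function(spec) {
  lapply(spec$inputs, function(def) {
    amp <- if (is.null(def$amplitude)) 1 else def$amplitude
    per <- if (is.null(def$period)) 1 else def$period
    w <- 2 * pi / per
    if (def$type == "cosine") {
      list(value = function(t) amp * cos(w * t),
           deriv = function(t) -amp * w * sin(w * t))
    } else if (def$type == "sine") {
      list(value = function(t) amp * sin(w * t),
           deriv = function(t) amp * w * cos(w * t))
    } else if (def$type == "random_fourier") {
      h <- if (is.null(def$harmonics)) 3 else def$harmonics
      a <- stats::rnorm(h)
      b <- stats::rnorm(h)
      scale <- amp / sqrt(sum((a^2 + b^2) / 2) + 1e-12)
      a <- a * scale
      b <- b * scale
      list(
        value = function(t) {
          drop(cos(outer(t, seq_len(h)) * w) %*% a + sin(outer(t, seq_len(h)) * w) %*% b)
        },
        deriv = function(t) {
          j <- seq_len(h)
          drop(-sin(outer(t, j) * w) %*% (j * w * a) + cos(outer(t, j) * w) %*% (j * w * b))
        }
      )
    } else {
      stop("unknown input type: ", def$type)
    }
  })
}

#' Simulate replicate time series from a network specification
#'
#' Integrates the ODEs with `deSolve::ode` (lsoda, tolerances `1e-10`) from
#' initial conditions drawn uniformly from the spec's `init_box`, sampling a
#' uniform grid of `n_samples` points over `[0, duration)` (100 samples per
#' period by default). Random driven inputs get fresh coefficients per
#' replicate. The exact derivatives from the vector field at the sample
#' points are stored alongside the values.
#'
#' @param spec A [network_spec()].
#' @param n_replicates Number of replicates (default 100).
#' @param duration Recorded window (defaults to `spec$duration`).
#' @param n_samples Samples on the recorded window (default 100).
#' @param init_box Override of the spec's initial-condition box.
#' @param seed RNG seed; identical seeds reproduce identical datasets.
#' @return An object of class `synthetic_dataset`: `spec`, `replicates` (each
#'   `times`, `values`, `derivatives`), `noise` metadata, `seed`.
#' @export
simulate_network <- function(spec, n_replicates = 100, duration = NULL,
                             n_samples = 100, init_box = NULL, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  if (is.null(duration)) duration <- spec$duration
  if (is.null(init_box)) init_box <- spec$init_box
  set.seed(seed)
  free <- names(spec$decay)
  grid <- duration * (seq_len(n_samples) - 1) / n_samples
  replicates <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    waves <- input_waves(spec) # draws random-fourier coefficients
    y0 <- vapply(free, function(cp) stats::runif(1, init_box[[cp]][1], init_box[[cp]][2]),
                 numeric(1))
    rhs <- function(t, y, parms) {
      state <- c(as.list(y), lapply(waves, function(wv) wv$value(t)))
      list(unname(spec_rates(spec, state)[free]))
    }
    times <- if (grid[1] == 0) grid else c(0, grid)
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
      stop("integration failure in replicate ", r)
    }
    sol <- sol[match(grid, times), , drop = FALSE]
    vals <- matrix(0, n_samples, length(spec$components),
                   dimnames = list(NULL, spec$components))
    ders <- vals
    vals[, free] <- sol[, free, drop = FALSE]
    for (cp in names(waves)) {
      vals[, cp] <- waves[[cp]]$value(grid)
      ders[, cp] <- waves[[cp]]$deriv(grid)
    }
    for (i in seq_len(n_samples)) {
      ders[i, free] <- spec_rates(spec, as.list(vals[i, ]))[free]
    }
    if (!all(is.finite(vals))) stop("integration blow-up in replicate ", r)
    replicates[[r]] <- list(times = grid, values = vals, derivatives = ders)
  }
  structure(
    list(
      spec = spec, replicates = replicates,
      noise = list(level_pct = 0, kind = "none", seed = NULL),
      seed = seed
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset%s> %d replicate(s) x %d sample(s), noise %g%% (%s)\n",
    if (is.null(x$spec$name)) "" else paste0(" ", x$spec$name),
    length(x$replicates), length(x$replicates[[1]]$times),
    x$noise$level_pct, x$noise$kind
  ))
  invisible(x)
}

#' Add measurement noise to a synthetic dataset
#'
#' Multiplicative noise replaces `X(t_i)` by `X(t_i) * (1 + e)` with
#' `e ~ N(0, (level_pct/100)^2)` i.i.d. per sample; additive noise adds
#' `e * RMS(X)` instead. Exact derivatives no longer apply and are dropped:
#' noisy data must be processed by fitting.
#'
#' @param data A [simulate_network()] result.
#' @param level_pct Noise level in percent (0 returns the input unchanged).
#' @param kind `"multiplicative"` (default) or `"additive"`.
#' @param seed RNG seed.
#' @return A `synthetic_dataset` with perturbed values.
#' @export
add_noise <- function(data, level_pct, kind = c("multiplicative", "additive"),
                      seed = 1L) {
  stopifnot(inherits(data, "synthetic_dataset"), level_pct >= 0)
  kind <- match.arg(kind)
  if (level_pct == 0) return(data)
  set.seed(seed)
  s <- level_pct / 100
  data$replicates <- lapply(data$replicates, function(rep) {
    eps <- matrix(stats::rnorm(length(rep$values), sd = s),
                  nrow(rep$values), ncol(rep$values))
    if (kind == "multiplicative") {
      rep$values <- rep$values * (1 + eps)
    } else {
      rms <- sqrt(colMeans(rep$values^2))
      rep$values <- rep$values + sweep(eps, 2, rms, "*")
    }
    rep$derivatives <- NULL
    rep
  })
  data$noise <- list(level_pct = level_pct, kind = kind, seed = seed)
  data
}

#' Convert a synthetic dataset to a raw replicate set
#'
#' @param data A [simulate_network()] (optionally [add_noise()]) result.
#' @return A [raw_series_set()].
#' @export
as_raw_series <- function(data) {
  stopifnot(inherits(data, "synthetic_dataset"))
  raw_series_set(
    lapply(data$replicates, function(r) list(times = r$times, values = r$values)),
    components = data$spec$components,
    metadata = list(fixture = data$spec$name, noise = data$noise)
  )
}

#' Process a dataset into normalized replicates with derivatives
#'
#' Noiseless synthetic data with stored vector-field derivatives become
#' `fit_method = "exact"` processed series directly (values and derivatives
#' min-max normalized per component). Noisy synthetic data and raw series
#' sets are fitted via [interpolate_and_differentiate()].
#'
#' @param x A `synthetic_dataset` or [raw_series_set()].
#' @param method,order,grid_size Passed to [interpolate_and_differentiate()]
#'   when fitting is needed.
#' @return List of [processed_series()].
#' @export
process_dataset <- function(x, method = "fourier", order = 4, grid_size = 100) {
  if (inherits(x, "raw_series_set")) {
    return(interpolate_and_differentiate(x, method = method, order = order,
                                         grid_size = grid_size))
  }
  stopifnot(inherits(x, "synthetic_dataset"))
  exact <- x$noise$level_pct == 0 &&
    all(vapply(x$replicates, function(r) !is.null(r$derivatives), logical(1)))
  if (!exact) {
    return(interpolate_and_differentiate(as_raw_series(x), method = method,
                                         order = order, grid_size = grid_size))
  }
  lapply(x$replicates, function(r) {
    processed_series(
      grid = r$times, values = r$values, derivatives = r$derivatives,
      components = x$spec$components, fit_method = "exact",
      noise_level_pct = 0
    )
  })
}

#' Numerical monotonicity audit of a network specification
#'
#' Verifies at random state points that perturbing each edge's source moves
#' its target's rate in the direction of the edge sign.
#'
#' @param spec A [network_spec()].
#' @param n_points Random state points per edge (default 100).
#' @param seed RNG seed.
#' @param box Named list of state ranges; defaults to the spec's `init_box`
#'   (inputs get `[-1, 1]`, or `[0, 2]` for Hill kinetics).
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
check_monotone <- function(spec, n_points = 100, seed = 1L, box = NULL) {
  set.seed(seed)
  default_rng <- if (spec$kinetics == "hill") c(1e-3, 2) else c(-1, 1)
  get_box <- function(cp) {
    if (!is.null(box) && cp %in% names(box)) return(box[[cp]])
    if (cp %in% names(spec$init_box)) return(spec$init_box[[cp]])
    default_rng
  }
  h <- 1e-4
  for (i in seq_len(nrow(spec$edges))) {
    e <- spec$edges[i, ]
    for (p in seq_len(n_points)) {
      state <- stats::setNames(lapply(spec$components, function(cp) {
        b <- get_box(cp)
        stats::runif(1, b[1], b[2])
      }), spec$components)
      up <- state
      up[[e$source]] <- up[[e$source]] + h
      d <- spec_rates(spec, up)[[e$target]] - spec_rates(spec, state)[[e$target]]
      if (d * e$sign <= 0) {
        stop(sprintf("monotonicity violated for edge %s %s %s", e$source,
                     if (e$sign > 0) "->" else "-|", e$target))
      }
    }
  }
  invisible(TRUE)
}

#' Catalog of ground-truthed network fixtures
#'
#' Named monotone network specifications with documented truth, spanning the
#' motifs the inference pipeline must handle:
#' \describe{
#'   \item{fig1_pair}{Cosine input X driving `dY/dt = X - Y`.}
#'   \item{fig1_triple}{Cosine input X1 driving Y as above plus a sine input
#'     X2 that does not enter the dynamics (its truth has no X2 edge).}
#'   \item{fig2_chain, IFL}{Random smooth input A with `A -| B` and joint 2D
#'     regulation `(A+, B+) -> C` (incoherent feed-forward: the chain through
#'     B opposes the direct positive edge).}
#'   \item{CFL}{Coherent feed-forward loop: `A -| B`, `B -> C` and a direct
#'     `A -| C` agreeing with the chain sign.}
#'   \item{SFL}{Single feed-forward chain `A -| B -> C`; any apparent
#'     `A -| C` is purely indirect.}
#'   \item{nfl_oscillator}{Three-node negative-feedback (Goodwin-type)
#'     oscillator: `C -| A` (Hill repression), `A -> B`, `B -> C`.}
#'   \item{repressilator}{Cyclic three-gene repressor ring
#'     `A -| B -| C -| A`.}
#' }
#' Oscillator initial-condition boxes cover their limit-cycle ranges, and
#' their `duration` is one (numerically measured) period.
#'
#' @param name Optional fixture name; omit for the full named list.
#' @return A [network_spec()] or a named list of them.
#' @export
fixtures <- function(name = NULL) {
  edge_df <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(source = m[, 1], sign = as.integer(m[, 2]), target = m[, 3],
               stringsAsFactors = FALSE)
  }
  cat <- list(
    fig1_pair = network_spec(
      c("X", "Y"), edge_df("X", 1, "Y"),
      kinetics = "linear",
      inputs = list(X = list(type = "cosine", amplitude = 1, period = 1)),
      init_box = list(Y = c(-1, 1)), duration = 1, name = "fig1_pair"
    ),
    fig1_triple = network_spec(
      c("X1", "X2", "Y"), edge_df("X1", 1, "Y"),
      kinetics = "linear",
      inputs = list(
        X1 = list(type = "cosine", amplitude = 1, period = 1),
        X2 = list(type = "sine", amplitude = 1, period = 1)
      ),
      init_box = list(Y = c(-1, 1)), duration = 1, name = "fig1_triple"
    ),
    fig2_chain = network_spec(
      c("A", "B", "C"),
      edge_df("A", -1, "B", "A", 1, "C", "B", 1, "C"),
      kinetics = "linear", weights = c(1.5, 1.5, 1.5),
      inputs = list(A = list(type = "random_fourier", amplitude = 1,
                             period = 1, harmonics = 3)),
      init_box = list(B = c(-1, 1), C = c(-1, 1)), duration = 1,
      name = "fig2_chain"
    ),
    IFL = network_spec(
      c("A", "B", "C"),
      edge_df("A", -1, "B", "A", 1, "C", "B", 1, "C"),
      kinetics = "linear", weights = c(2, 1.5, 1.5),
      inputs = list(A = list(type = "random_fourier", amplitude = 1,
                             period = 1, harmonics = 3)),
      init_box = list(B = c(-1, 1), C = c(-1, 1)), duration = 1, name = "IFL"
    ),
    CFL = network_spec(
      c("A", "B", "C"),
      edge_df("A", -1, "B", "A", -1, "C", "B", 1, "C"),
      kinetics = "linear", weights = c(1.5, 2, 1.5),
      inputs = list(A = list(type = "random_fourier", amplitude = 1,
                             period = 1, harmonics = 3)),
      init_box = list(B = c(-1, 1), C = c(-1, 1)), duration = 1, name = "CFL"
    ),
    SFL = network_spec(
      c("A", "B", "C"),
      edge_df("A", -1, "B", "B", 1, "C"),
      kinetics = "linear", weights = c(1.5, 1.5),
      inputs = list(A = list(type = "random_fourier", amplitude = 1,
                             period = 1, harmonics = 3)),
      init_box = list(B = c(-1, 1), C = c(-1, 1)), duration = 1, name = "SFL"
    ),
    nfl_oscillator = network_spec(
      c("A", "B", "C"),
      edge_df("C", -1, "A", "A", 1, "B", "B", 1, "C"),
      kinetics = "hill", weights = c(2, 2, 2), hill_k = 1, hill_n = 6,
      init_box = list(A = c(0.55, 1.55), B = c(0.5, 1.5), C = c(0.5, 1.5)),
      duration = 3.52, name = "nfl_oscillator"
    ),
    repressilator = network_spec(
      c("A", "B", "C"),
      edge_df("A", -1, "B", "B", -1, "C", "C", -1, "A"),
      kinetics = "hill", weights = 3, hill_k = 1, hill_n = 4,
      init_box = list(A = c(0.6, 1.9), B = c(0.6, 1.9), C = c(0.6, 1.9)),
      duration = 3.76, name = "repressilator"
    )
  )
  if (is.null(name)) return(cat)
  if (!name %in% names(cat)) stop("unknown fixture: ", name)
  cat[[name]]
}

#' Export a synthetic dataset as CSV replicates plus a truth file
#'
#' Writes `replicate_###.csv` files in the layout [load_series()] reads (a
#' `time` column plus one column per component) and a `truth.json` edge list
#' with the noise metadata.
#'
#' @param data A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(data$replicates)) {
    rep <- data$replicates[[r]]
    df <- data.frame(time = rep$times)
    for (cp in data$spec$components) df[[cp]] <- rep$values[, cp]
    utils::write.csv(df, file.path(dir, sprintf("replicate_%03d.csv", r)),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(
      fixture = data$spec$name,
      truth = data$spec$truth,
      noise = data$noise,
      seed = data$seed
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
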