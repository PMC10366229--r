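# Literal double-loop implementation of the pair-domain definitions, used as
# the independent oracle for the vectorized region/score computations, plus
# small fixture builders.

oracle_region_score <- function(ps, cand) {
  causes <- cand$causes
  signs <- cand$signs
  if (!is.null(cand$self_sign)) {
    causes <- c(causes, cand$target)
    signs <- c(signs, cand$self_sign)
  }
  V <- ps$values
  ydot <- ps$derivatives[, cand$target]
  T <- length(ps$grid)
  # max-abs scaling of the derivative differences, by loop
  m <- 0
  for (a in seq_len(T)) {
    for (b in seq_len(T)) {
      m <- max(m, abs(ydot[a] - ydot[b]))
    }
  }
  count <- 0
  num <- 0
  den <- 0
  for (a in seq_len(T)) {
    for (b in seq_len(T)) {
      if (a == b) next
      ok <- TRUE
      prod <- 1
      for (i in seq_along(causes)) {
        xd <- signs[i] * (V[a, causes[i]] - V[b, causes[i]])
        if (xd <= 0) {
          ok <- FALSE
          break
        }
        prod <- prod * xd
      }
      if (!ok) next
      count <- count + 1
      I <- if (m == 0) 0 else prod * (ydot[a] - ydot[b]) / m
      num <- num + I
      den <- den + abs(I)
    }
  }
  list(
    size = count / T^2,
    score = if (count == 0 || den == 0) NA_real_ else unname(num / den)
  )
}

# processed replicate built directly from value/derivative matrices
make_ps <- function(values, derivatives, duration = 1) {
  values <- as.matrix(values)
  grid <- duration * (seq_len(nrow(values)) - 1) / nrow(values)
  processed_series(
    grid = grid, values = values, derivatives = as.matrix(derivatives),
    components = colnames(values), fit_method = "exact"
  )
}

# smooth random multivariate replicate with analytic derivatives
random_ps <- function(T = 24, comps = c("A", "B", "C"), seed = 1) {
  set.seed(seed)
  t <- (seq_len(T) - 1) / T
  vals <- sapply(comps, function(cp) {
    a <- stats::rnorm(3)
    b <- stats::rnorm(3)
    drop(cos(outer(t, 1:3) * 2 * pi) %*% a + sin(outer(t, 1:3) * 2 * pi) %*% b)
  })
  ders <- sapply(seq_along(comps), function(j) {
    # derivative irrelevant to region geometry; reuse another smooth signal
    a <- stats::rnorm(3)
    drop(sin(outer(t, 1:3) * 2 * pi) %*% a)
  })
  colnames(ders) <- comps
  make_ps(vals, ders)
}

noiseless_dataset <- function(fixture, n = 20, seed = 1, ...) {
  process_dataset(simulate_network(fixtures(fixture), n_replicates = n,
                                   seed = seed, ...))
}
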