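test_that("candidate construction enforces its invariants", {
  expect_error(regulation_candidate("Y", c("X", "X"), c(1, 1)))
  expect_error(regulation_candidate("Y", c("Y"), 1))
  expect_error(regulation_candidate("Y", "X", 2))
  cand <- regulation_candidate("Y", "X", -1L, self_sign = -1L)
  expect_identical(effective_causes(cand)$causes, c("X", "Y"))
})

test_that("region of a monotone series is the ordered half of the pair domain", {
  T <- 20
  ps <- make_ps(
    cbind(X = seq_len(T) / T, Y = cos(seq_len(T))),
    cbind(X = rep(1, T), Y = sin(seq_len(T)))
  )
  reg <- detection_region(ps, regulation_candidate("Y", "X", 1L))
  expect_equal(reg$size, (T^2 - T) / (2 * T^2))
  idx <- which(reg$mask, arr.ind = TRUE)
  expect_true(all(idx[, 1] > idx[, 2]))
  # opposite sign gives the transposed mask
  reg_neg <- detection_region(ps, regulation_candidate("Y", "X", -1L))
  expect_identical(reg_neg$mask, t(reg$mask))
})

test_that("cos/sin pair covers about a quarter of the pair domain", {
  t <- (0:99) / 100
  ps <- make_ps(
    cbind(X1 = cos(2 * pi * t), X2 = sin(2 * pi * t), Y = t),
    cbind(X1 = -sin(2 * pi * t), X2 = cos(2 * pi * t), Y = rep(1, 100))
  )
  cand <- regulation_candidate("Y", c("X1", "X2"), c(1L, 1L))
  reg <- detection_region(ps, cand)
  expect_equal(reg$size, oracle_region_score(ps, cand)$size)
  expect_equal(reg$size, 0.25, tolerance = 0.02)
})

test_that("region sizes over all sign patterns tile the off-tie pair domain", {
  ps <- random_ps(T = 16, seed = 5)
  for (causes in list("A", c("A", "B"))) {
    patterns <- expand.grid(rep(list(c(1L, -1L)), length(causes)))
    sizes <- apply(patterns, 1, function(sg) {
      detection_region(ps, regulation_candidate("C", causes, sg))$size
    })
    # continuous data: no exact ties off the diagonal
    expect_equal(sum(sizes), (16^2 - 16) / 16^2, tolerance = 1e-12)
  }
})

test_that("detection function is positive throughout the region of a true regulation", {
  ps <- noiseless_dataset("fig1_pair", n = 1, init_box = list(Y = c(0, 0)))[[1]]
  cand <- regulation_candidate("Y", "X", 1L, self_sign = -1L)
  vals <- detection_function(ps, cand)
  expect_true(all(vals$values > 0))
  expect_lte(max(abs(vals$values)), 1)
  expect_equal(detection_score(vals), 1)
  # the mismatched type loses positivity
  wrong <- detection_function(ps, regulation_candidate("Y", "X", -1L, self_sign = -1L))
  expect_true(any(wrong$values < 0))
  expect_lt(detection_score(wrong), 1)
})

test_that("score is the signed-to-absolute ratio and respects symmetries", {
  vals <- structure(list(values = c(2, -1)), class = "detection_values")
  expect_equal(detection_score(vals), 1 / 3)
  expect_equal(detection_score(structure(list(values = numeric(0)),
                                         class = "detection_values")), NA_real_)
  expect_equal(detection_score(structure(list(values = c(0, 0)),
                                         class = "detection_values")), NA_real_)

  ps <- random_ps(T = 20, seed = 11)
  for (sg in list(1L, -1L, c(1L, -1L))) {
    causes <- if (length(sg) == 1) "A" else c("A", "B")
    s <- regulation_score(ps, regulation_candidate("C", causes, sg))$score
    expect_gte(s, -1)
    expect_lte(s, 1)
  }
  # constant-derivative target: every I is zero, score undefined
  flat <- make_ps(
    cbind(X = (1:10) / 10, Y = (1:10) / 10),
    cbind(X = rep(1, 10), Y = rep(2, 10))
  )
  expect_true(is.na(regulation_score(flat, regulation_candidate("Y", "X", 1L))$score))
})

test_that("vectorized region and score match the literal double-loop oracle", {
  for (fx in c("fig2_chain", "CFL", "repressilator")) {
    dataset <- noiseless_dataset(fx, n = 2, seed = 3, n_samples = 24)
    comps <- dataset[[1]]$components
    cfg <- inference_config(self_sign = "negative")
    cands <- c(
      enumerate_candidates(comps, 1, inference_config(self_sign = "none")),
      enumerate_candidates(comps, 2, cfg)
    )
    for (ps in dataset) {
      for (cand in cands) {
        got <- regulation_score(ps, cand)
        want <- oracle_region_score(ps, cand)
        expect_equal(got$region_size, want$size, tolerance = 1e-12)
        expect_equal(got$score, want$score, tolerance = 1e-12)
      }
    }
  }
})

test_that("swapping a pair flips I by (-1)^(N+1) and moves it to the mirrored candidate", {
  ps <- random_ps(T = 12, seed = 2)
  for (causes in list("A", c("A", "B"))) {
    N <- length(causes)
    sg <- rep(1L, N)
    cand <- regulation_candidate("C", causes, sg)
    mirror <- regulation_candidate("C", causes, -sg)
    v1 <- detection_function(ps, cand)
    v2 <- detection_function(ps, mirror)
    # swapping (a, b) multiplies every difference by -1: I picks up (-1)^(N+1)
    expect_equal(t(v1$I), (-1)^(N + 1) * v1$I)
    # and region membership moves to the sign-flipped candidate
    expect_identical(v1$mask, t(v2$mask))
    expect_equal(v2$I, (-1)^N * v1$I)
  }
})

test_that("scores are invariant to positive affine transforms of the inputs", {
  t <- (0:49) / 50
  # asymmetric waveform: no exact pairwise ties to fall on rounding edges
  x <- cos(2 * pi * t) + 0.4 * sin(4 * pi * t + 0.7)
  base <- cbind(X = x, Y = sin(2 * pi * t + 0.3))
  ders <- cbind(X = -sin(2 * pi * t), Y = cos(2 * pi * t))
  cand <- regulation_candidate("Y", "X", 1L)
  s1 <- regulation_score(make_ps(base, ders), cand)
  s2 <- regulation_score(
    make_ps(cbind(X = 5 * base[, "X"] - 2, Y = base[, "Y"]),
            cbind(X = 5 * ders[, "X"], Y = 3 * ders[, "Y"])),
    cand
  )
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
  expect_equal(s1$region_size, s2$region_size)
})

test_that("the regulation-delta vanishes exactly for an irrelevant component", {
  ps <- noiseless_dataset("fig1_triple", n = 1, init_box = list(Y = c(0, 0)))[[1]]
  base <- regulation_candidate("Y", "X1", 1L, self_sign = -1L)
  d <- regulation_delta(ps, base, "X2")
  expect_equal(d$s_plus, 1)
  expect_equal(d$s_minus, 1)
  expect_equal(d$delta, 0)
})

test_that("the regulation-delta detects a genuinely added cause and stays in [-2, 2]", {
  dataset <- noiseless_dataset("CFL", n = 10, seed = 4)
  deltas <- vapply(dataset, function(ps) {
    regulation_delta(ps, regulation_candidate("C", "B", 1L, self_sign = -1L), "A")$delta
  }, numeric(1))
  # A represses C directly: appending it negatively must beat appending it positively
  expect_true(all(deltas < 0, na.rm = TRUE))
  expect_true(all(abs(deltas) <= 2, na.rm = TRUE))
})
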