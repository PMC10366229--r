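# Post-filtering of passing candidates: the regulation-delta test removes
# ineffective components; the surrogate-shuffle test removes indirect
# regulations induced by chains of direct ones.

#' Regulation-delta test for a component added to a base candidate
#'
#' Computes the regulation-delta (difference between the scores with the
#' component appended positively and negatively) on every replicate and
#' decides whether the component adds positive regulation, negative
#' regulation, or none. With at most 25 usable replicates the decision
#' requires a consistent sign (`delta >= 0` everywhere for positive,
#' `<= 0` for negative, and not identically zero); with more, a one-tailed
#' Wilcoxon signed-rank test at level `config$delta_alpha` is used.
#'
#' @param dataset List of [processed_series()] replicates.
#' @param base A [regulation_candidate()] the component extends.
#' @param component Component under test.
#' @param config An [inference_config()].
#' @return List of class `delta_test_result`: `decision` one of `"positive"`,
#'   `"negative"`, `"ineffective"`; `deltas` per replicate (`NA` when
#'   undefined); `p_value` (Wilcoxon, or `NA` for the small-sample rule).
#' @export
delta_test <- function(dataset, base, component, config = inference_config()) {
  deltas <- vapply(
    dataset,
    function(ps) regulation_delta(ps, base, component)$delta,
    numeric(1)
  )
  d <- deltas[!is.na(deltas)]
  res <- list(deltas = deltas, p_value = NA_real_, component = component)
  if (length(d) == 0) {
    warning("all replicates have undefined delta; component deemed ineffective")
    res$decision <- "ineffective"
  } else if (all(d == 0)) {
    res$decision <- "ineffective"
  } else if (length(d) <= 25) {
    res$decision <- if (all(d >= 0)) {
      "positive"
    } else if (all(d <= 0)) {
      "negative"
    } else {
      "ineffective"
    }
  } else {
    dz <- d[d != 0] # signed-rank convention: drop zeros
    p_pos <- suppressWarnings(
      stats::wilcox.test(dz, alternative = "greater", mu = 0,
                         exact = FALSE, correct = TRUE)$p.value
    )
    p_neg <- suppressWarnings(
      stats::wilcox.test(dz, alternative = "less", mu = 0,
                         exact = FALSE, correct = TRUE)$p.value
    )
    if (p_pos < config$delta_alpha) {
      res$decision <- "positive"
      res$p_value <- p_pos
    } else if (p_neg < config$delta_alpha) {
      res$decision <- "negative"
      res$p_value <- p_neg
    } else {
      res$decision <- "ineffective"
      res$p_value <- min(p_pos, p_neg)
    }
  }
  class(res) <- "delta_test_result"
  res
}

# all directed chains source -> ... -> target of length >= 2 through `edges`
# whose sign product equals `sign`; depth-first search on the (tiny) edge list
find_chains <- function(edges, source, target, sign, max_len = 6L) {
  if (nrow(edges) == 0) return(list())
  chains <- list()
  walk <- function(node, visited, path_edges, prod) {
    if (length(path_edges) > max_len) return()
    nxt <- which(edges$source == node)
    for (k in nxt) {
      to <- edges$target[k]
      p2 <- prod * edges$sign[k]
      if (to == target && length(path_edges) >= 1) {
        # path length >= 2 edges counting this one
        if (p2 == sign) {
          chains[[length(chains) + 1L]] <<- rbind(edges[path_edges, ], edges[k, ])
        }
      } else if (!(to %in% visited) && to != target) {
        walk(to, c(visited, to), c(path_edges, k), p2)
      }
    }
  }
  # first hop: any edge out of `source` except the direct edge to `target`
  first <- which(edges$source == source & edges$target != target)
  for (k in first) {
    walk(edges$target[k], c(source, edges$target[k]), k, edges$sign[k])
  }
  chains
}

#' Flag inferred edges that could be indirect
#'
#' For each signed edge `(X, s, Y)`, lists every directed chain
#' `X -> ... -> Y` of length at least 2 through the other inferred edges whose
#' sign product equals `s`. Such edges are candidates for the
#' [surrogate_test()].
#'
#' @param edges Data frame with columns `source`, `sign`, `target`.
#' @return Data frame of flagged edges (`source`, `sign`, `target`,
#'   `n_chains`) with the chains in attribute `"chains"`; zero rows when no
#'   edge is potentially indirect.
#' @export
find_potential_indirect <- function(edges) {
  stopifnot(all(c("source", "sign", "target") %in% names(edges)))
  flagged <- list()
  chains <- list()
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    ch <- find_chains(edges[-i, , drop = FALSE], e$source, e$target, e$sign)
    if (length(ch) > 0) {
      flagged[[length(flagged) + 1L]] <- data.frame(
        source = e$source, sign = e$sign, target = e$target,
        n_chains = length(ch)
      )
      chains[[length(chains) + 1L]] <- ch
    }
  }
  out <- do.call(rbind, c(
    list(data.frame(source = character(0), sign = integer(0),
                    target = character(0), n_chains = integer(0))),
    flagged
  ))
  rownames(out) <- NULL
  attr(out, "chains") <- chains
  out
}

#' Fisher's-method critical value
#'
#' The combined statistic is `chi^2 = -2 * sum(log(p_i))` over `k` replicate
#' p-values; the decision threshold is the statistic obtained when every
#' `p_i` equals the per-replicate significance level: `-2 * k * log(p)`.
#'
#' @param k Number of combined p-values.
#' @param p Per-replicate significance level (default 0.001).
#' @return The critical value of the combined chi-squared statistic.
#' @export
fisher_critical <- function(k, p = 0.001) {
  stopifnot(k >= 1, p > 0, p < 1)
  -2 * k * log(p)
}

#' Surrogate-shuffle test for a suspect cause
#'
#' Destroys the temporal structure of one cause by randomly permuting its
#' sampled values, recomputes the candidate's regulation-detection score for
#' each permutation, and asks whether the original score is significantly
#' larger than the shuffled-score distribution (one-tailed Z test per
#' replicate). The per-replicate p-values are combined with Fisher's method;
#' the regulation is called direct when the combined statistic exceeds the
#' critical value [fisher_critical()] evaluated at `config$surrogate_p`.
#'
#' Only the suspect's pairwise difference values enter the score, so the
#' shuffled series needs no re-differentiation; all other series are left
#' untouched. Replicates with an undefined original score are skipped; a
#' degenerate shuffled-score distribution (zero spread) yields the
#' conservative `p = 1`.
#'
#' @param dataset List of [processed_series()] replicates.
#' @param cand A [regulation_candidate()]; `suspect` must be one of its
#'   causes.
#' @param suspect The cause whose direct influence is questioned.
#' @param config An [inference_config()]; uses `surrogate_shuffles`,
#'   `surrogate_p` and `rng_seed`.
#' @return List of class `surrogate_test_result`: `decision` (`"direct"` /
#'   `"indirect"`), `p_values` per usable replicate, `chi2`, `critical`, `k`.
#' @export
surrogate_test <- function(dataset, cand, suspect, config = inference_config()) {
  stopifnot(suspect %in% cand$causes)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  eff <- effective_causes(cand)
  si <- match(suspect, eff$causes)
  s_sign <- eff$signs[si]
  p_values <- numeric(0)
  for (ps in dataset) {
    if (any(c(eff$causes, cand$target) %in% ps$degenerate)) next
    cache_others <- NULL
    # base mask and detection-function factor from everything but the suspect
    mask0 <- NULL
    prod0 <- target_deriv_diff(ps, cand$target)
    for (i in seq_along(eff$causes)[-si]) {
      xd <- pair_diff(ps$values[, eff$causes[i]]) * eff$signs[i]
      mask0 <- if (is.null(mask0)) xd > 0 else mask0 & (xd > 0)
      prod0 <- prod0 * xd
    }
    x <- ps$values[, suspect]
    score_with <- function(xs) {
      xd <- pair_diff(xs) * s_sign
      mask <- if (is.null(mask0)) xd > 0 else mask0 & (xd > 0)
      iv <- (prod0 * xd)[mask]
      if (length(iv) == 0) return(NA_real_)
      den <- sum(abs(iv))
      if (den == 0) return(NA_real_)
      sum(iv) / den
    }
    s_orig <- score_with(x)
    if (is.na(s_orig)) next
    s_shuf <- vapply(
      seq_len(config$surrogate_shuffles),
      function(b) score_with(x[sample.int(length(x))]),
      numeric(1)
    )
    s_shuf <- s_shuf[!is.na(s_shuf)]
    if (length(s_shuf) < 2 || stats::sd(s_shuf) == 0) {
      p <- 1
    } else {
      z <- (s_orig - mean(s_shuf)) / stats::sd(s_shuf)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    p_values <- c(p_values, max(p, 1e-300))
  }
  k <- length(p_values)
  chi2 <- if (k == 0) 0 else -2 * sum(log(p_values))
  critical <- fisher_critical(max(k, 1), config$surrogate_p)
  structure(
    list(
      decision = if (k > 0 && chi2 > critical) "direct" else "indirect",
      p_values = p_values, chi2 = chi2, critical = critical, k = k,
      suspect = suspect
    ),
    class = "surrogate_test_result"
  )
}
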