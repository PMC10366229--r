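# Candidate enumeration, replicate-wide scoring, TRS thresholding and network
# assembly.

#' Inference configuration
#'
#' Collects every tunable of the inference pipeline. The two score thresholds
#' fall linearly with the estimated noise level (in percent):
#' `S_thres = 0.9 - 0.005 * noise` and `TRS_thres = 0.9 - 0.01 * noise`.
#'
#' @param r_thres Minimum regulation-detection region size (fraction of the
#'   pair domain) for a replicate to count; in `[0, 0.1]`, default 0.05.
#' @param s_thres_fn Function noise_pct -> score threshold.
#' @param trs_thres_fn Function noise_pct -> TRS threshold.
#' @param max_dim Maximum regulation dimension to sweep; `NULL` means
#'   `N - 1` for `N` observed components.
#' @param self_sign `"negative"` (default) appends an assumed negative
#'   self-regulation to every candidate, the standard prior for components
#'   that are degraded in proportion to their own level; `"none"` disables
#'   the assumption; or a named vector of `+1`/`-1` per component (components
#'   not named get no assumption).
#' @param delta_alpha One-tailed significance level of the regulation-delta
#'   Wilcoxon test (default 0.01).
#' @param surrogate_p Per-replicate p-value defining the Fisher critical value
#'   of the surrogate test (default 0.001).
#' @param surrogate_shuffles Random permutations per replicate in the
#'   surrogate test (default 100).
#' @param noise_pct Noise level override; `NULL` (default) uses the mean of
#'   the per-replicate estimates carried by the processed series.
#' @param stop_early Stop the dimension sweep once no candidate at the current
#'   dimension passes the TRS threshold (default `TRUE`).
#' @param rng_seed Seed for the surrogate-test permutations.
#' @return A list of class `inference_config`.
#' @export
inference_config <- function(r_thres = 0.05,
                             s_thres_fn = function(noise_pct) 0.9 - 0.005 * noise_pct,
                             trs_thres_fn = function(noise_pct) 0.9 - 0.01 * noise_pct,
                             max_dim = NULL,
                             self_sign = "negative",
                             delta_alpha = 0.01,
                             surrogate_p = 0.001,
                             surrogate_shuffles = 100,
                             noise_pct = NULL,
                             stop_early = TRUE,
                             rng_seed = 1L) {
  stopifnot(r_thres >= 0, r_thres <= 0.1, delta_alpha > 0, surrogate_p > 0,
            surrogate_shuffles >= 1)
  structure(
    list(
      r_thres = r_thres, s_thres_fn = s_thres_fn, trs_thres_fn = trs_thres_fn,
      max_dim = max_dim, self_sign = self_sign, delta_alpha = delta_alpha,
      surrogate_p = surrogate_p, surrogate_shuffles = surrogate_shuffles,
      noise_pct = noise_pct, stop_early = stop_early, rng_seed = rng_seed
    ),
    class = "inference_config"
  )
}

# resolve the self-sign assumption for one target under a config
self_sign_for <- function(config, target) {
  ss <- config$self_sign
  if (is.null(ss) || identical(ss, "none")) return(NULL)
  if (identical(ss, "negative")) return(-1L)
  if (identical(ss, "positive")) return(1L)
  if (!is.null(names(ss)) && target %in% names(ss)) return(as.integer(ss[[target]]))
  NULL
}

dataset_noise_pct <- function(dataset, config) {
  if (!is.null(config$noise_pct)) return(config$noise_pct)
  mean(vapply(dataset, function(ps) ps$noise_level_pct, numeric(1)))
}

#' Enumerate candidate regulations of a given dimension
#'
#' All (cause set, sign vector) combinations of size `dim` for every target;
#' causes never include the target, which may enter only through the assumed
#' self-regulation sign of `config`.
#'
#' @param components Character vector of component names.
#' @param dim Regulation dimension, `1 <= dim <= length(components) - 1`.
#' @param config An [inference_config()].
#' @return List of [regulation_candidate()]s.
#' @export
enumerate_candidates <- function(components, dim, config = inference_config()) {
  n <- length(components)
  if (dim < 1 || dim >= n) stop("dim must be between 1 and components - 1")
  sign_patterns <- as.matrix(expand.grid(rep(list(c(1L, -1L)), dim)))
  out <- list()
  for (target in components) {
    others <- setdiff(components, target)
    cause_sets <- utils::combn(others, dim, simplify = FALSE)
    ss <- self_sign_for(config, target)
    for (causes in cause_sets) {
      for (r in seq_len(nrow(sign_patterns))) {
        out[[length(out) + 1L]] <- regulation_candidate(
          target, causes, sign_patterns[r, ], self_sign = ss
        )
      }
    }
  }
  out
}

#' Score every candidate on every replicate
#'
#' @param dataset List of [processed_series()] replicates.
#' @param candidates List of [regulation_candidate()]s.
#' @param config An [inference_config()] (unused beyond validation; scoring is
#'   deterministic).
#' @return A data frame of class `score_table` with one row per
#'   (candidate, replicate): `candidate` (index), `replicate`, `region_size`,
#'   `score` (`NA` when undefined). The candidate list is attached as
#'   attribute `"candidates"`.
#' @export
score_all <- function(dataset, candidates, config = inference_config()) {
  stopifnot(length(dataset) >= 1, length(candidates) >= 1)
  rows <- vector("list", length(dataset))
  for (r in seq_along(dataset)) {
    cache <- build_pair_cache(dataset[[r]])
    scores <- numeric(length(candidates))
    sizes <- numeric(length(candidates))
    for (ci in seq_along(candidates)) {
      cand <- candidates[[ci]]
      eff <- effective_causes(cand)
      sc <- score_from_cache(cache, cand$target, eff$causes, eff$signs)
      scores[ci] <- sc$score
      sizes[ci] <- sc$region_size
    }
    rows[[r]] <- data.frame(
      candidate = seq_along(candidates), replicate = r,
      region_size = sizes, score = scores
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "candidates") <- candidates
  class(out) <- c("score_table", class(out))
  out
}

#' Total regulation score per candidate
#'
#' Among the replicates whose detection region is large enough
#' (`region_size > r_thres`), the fraction whose score exceeds the
#' noise-adjusted score threshold. Candidates with no eligible replicate get
#' `NA` (they are reported in diagnostics but never inferred).
#'
#' @param table A [score_all()] result.
#' @param noise_pct Noise level in percent used to evaluate the thresholds.
#' @param config An [inference_config()].
#' @return Data frame with `candidate`, `trs`, `n_eligible`, `n_pass`.
#' @export
total_regulation_score <- function(table, noise_pct, config = inference_config()) {
  stopifnot(noise_pct >= 0)
  s_thres <- config$s_thres_fn(noise_pct)
  by_cand <- split(table, table$candidate)
  res <- lapply(by_cand, function(df) {
    eligible <- df$region_size > config$r_thres & !is.na(df$region_size)
    n_el <- sum(eligible)
    n_pass <- sum(eligible & !is.na(df$score) & df$score > s_thres)
    data.frame(
      candidate = df$candidate[1],
      trs = if (n_el == 0) NA_real_ else n_pass / n_el,
      n_eligible = n_el, n_pass = n_pass
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$candidate), , drop = FALSE]
}

# expand a candidate's effective (post-filter) causes into signed edges
candidate_edges <- function(cand, keep = cand$causes) {
  idx <- match(keep, cand$causes)
  data.frame(
    source = cand$causes[idx], sign = cand$signs[idx], target = cand$target,
    stringsAsFactors = FALSE
  )
}

#' Infer the signed regulatory network from processed replicates
#'
#' Sweeps candidate dimensions `1..max_dim`. At each dimension, candidates
#' with total regulation score above the noise-adjusted TRS threshold enter
#' post-filtering: every cause of a multi-cause candidate must pass the
#' regulation-delta test with the matching sign (ineffective causes are
#' dropped, possibly reducing the candidate); causes whose edge could be
#' explained by a chain of other surviving edges with the same sign product
#' must additionally pass the surrogate-shuffle test, otherwise they are
#' removed as indirect. When several 1D candidates with distinct causes pass
#' for one target they are set aside in favour of higher-dimensional
#' candidates (their causes act jointly, which the 1D score cannot certify).
#' Finally, for each target only the surviving candidate with the highest TRS
#' is kept (ties prefer the lower dimension).
#'
#' @param dataset List of [processed_series()] replicates.
#' @param config An [inference_config()].
#' @return An object of class `inferred_network`: list with `edges` (data
#'   frame `source`, `sign`, `target`, `dimension`, `trs`, `delta_verdict`,
#'   `surrogate_verdict`), `winners` (per-target winning candidates), and
#'   `diagnostics` (per-dimension TRS tables, deferred 1D candidates, tests).
#' @export
infer_network <- function(dataset, config = inference_config()) {
  stopifnot(length(dataset) >= 1)
  components <- dataset[[1]]$components
  noise <- dataset_noise_pct(dataset, config)
  trs_thres <- config$trs_thres_fn(noise)
  max_dim <- config$max_dim
  if (is.null(max_dim)) max_dim <- length(components) - 1L
  max_dim <- min(max_dim, length(components) - 1L)

  surviving <- list() # each: list(cand, dim, trs, keep, delta, surrogate)
  diagnostics <- list(noise_pct = noise, trs_thres = trs_thres, dims = list())

  for (d in seq_len(max_dim)) {
    cands <- enumerate_candidates(components, d, config)
    table <- score_all(dataset, cands, config)
    trs <- total_regulation_score(table, noise, config)
    pass_idx <- which(!is.na(trs$trs) & trs$trs > trs_thres)
    diagnostics$dims[[d]] <- list(trs = trs, candidates = cands,
                                  n_pass = length(pass_idx))
    for (ci in pass_idx) {
      surviving[[length(surviving) + 1L]] <- list(
        cand = cands[[ci]], dim = d, trs = trs$trs[ci],
        keep = cands[[ci]]$causes,
        delta = list(), surrogate = list()
      )
    }
    if (config$stop_early && length(pass_idx) == 0 && d >= 2) break
  }

  # defer 1D candidates when >= 2 distinct causes pass for the same target
  if (length(surviving) > 0) {
    is1d <- vapply(surviving, function(s) s$dim == 1L, logical(1))
    targets1d <- vapply(surviving, function(s) s$cand$target, character(1))
    deferred <- logical(length(surviving))
    for (tg in unique(targets1d[is1d])) {
      idx <- which(is1d & targets1d == tg)
      causes <- unique(vapply(surviving[idx], function(s) s$cand$causes, character(1)))
      if (length(causes) >= 2) deferred[idx] <- TRUE
    }
    diagnostics$deferred_1d <- lapply(surviving[deferred], function(s) s$cand)
    surviving <- surviving[!deferred]
  }

  # delta test: every cause of a multi-cause candidate must be effective with
  # the matching sign; ineffective causes are dropped
  for (i in seq_along(surviving)) {
    s <- surviving[[i]]
    if (s$dim < 2) next
    keep <- character(0)
    for (j in seq_along(s$cand$causes)) {
      base <- regulation_candidate(
        s$cand$target, s$cand$causes[-j], s$cand$signs[-j],
        self_sign = s$cand$self_sign
      )
      dt <- delta_test(dataset, base, s$cand$causes[j], config)
      s$delta[[s$cand$causes[j]]] <- dt
      want <- if (s$cand$signs[j] > 0) "positive" else "negative"
      if (dt$decision == want) keep <- c(keep, s$cand$causes[j])
    }
    s$keep <- keep
    surviving[[i]] <- s
  }
  surviving <- Filter(function(s) length(s$keep) > 0, surviving)

  # surrogate test for causes whose edge is explainable by a chain of the
  # other surviving edges
  all_edges <- do.call(rbind, c(
    list(data.frame(source = character(0), sign = integer(0), target = character(0))),
    lapply(surviving, function(s) candidate_edges(s$cand, s$keep))
  ))
  for (i in seq_along(surviving)) {
    s <- surviving[[i]]
    keep <- s$keep
    for (cause in s$keep) {
      sign <- s$cand$signs[match(cause, s$cand$causes)]
      chains <- find_chains(all_edges, cause, s$cand$target, sign)
      if (length(chains) == 0) next
      st <- surrogate_test(dataset, s$cand, cause, config)
      s$surrogate[[cause]] <- st
      if (st$decision == "indirect") keep <- setdiff(keep, cause)
    }
    s$keep <- keep
    surviving[[i]] <- s
  }
  surviving <- Filter(function(s) length(s$keep) > 0, surviving)

  # per-target merge: highest TRS wins; on exact TRS ties, the candidate whose
  # post-filtered cause set is larger explains more regulation and wins (every
  # surviving cause has already proven effective in the delta test, so the
  # extra dimension is never spurious); remaining ties prefer the lower
  # dimension
  winners <- list()
  if (length(surviving) > 0) {
    targets <- vapply(surviving, function(s) s$cand$target, character(1))
    for (tg in unique(targets)) {
      idx <- which(targets == tg)
      ord <- idx[order(-vapply(surviving[idx], function(s) s$trs, numeric(1)),
                       -vapply(surviving[idx], function(s) length(s$keep), numeric(1)),
                       vapply(surviving[idx], function(s) s$dim, numeric(1)))]
      winners[[tg]] <- surviving[[ord[1]]]
    }
  }

  edge_rows <- lapply(winners, function(s) {
    ed <- candidate_edges(s$cand, s$keep)
    ed$dimension <- s$dim
    ed$trs <- s$trs
    ed$delta_verdict <- vapply(ed$source, function(cp) {
      if (s$dim < 2) "not-applicable" else "pass"
    }, character(1))
    ed$surrogate_verdict <- vapply(ed$source, function(cp) {
      if (is.null(s$surrogate[[cp]])) "not-applicable" else "pass"
    }, character(1))
    ed
  })
  edges <- do.call(rbind, c(
    list(data.frame(
      source = character(0), sign = integer(0), target = character(0),
      dimension = integer(0), trs = numeric(0),
      delta_verdict = character(0), surrogate_verdict = character(0)
    )),
    edge_rows
  ))
  rownames(edges) <- NULL

  structure(
    list(edges = edges, winners = winners, components = components,
         diagnostics = diagnostics, config = config),
    class = "inferred_network"
  )
}

#' @export
print.inferred_network <- function(x, ...) {
  cat(sprintf(
    "<inferred_network> %d component(s), %d edge(s) [noise %.2f%%, TRS threshold %.3f]\n",
    length(x$components), nrow(x$edges),
    x$diagnostics$noise_pct, x$diagnostics$trs_thres
  ))
  if (nrow(x$edges) > 0) {
    for (i in seq_len(nrow(x$edges))) {
      e <- x$edges[i, ]
      cat(sprintf(
        "  %s %s %s  (dim %d, TRS %.3f)\n", e$source,
        if (e$sign > 0) "->" else "-|", e$target, e$dimension, e$trs
      ))
    }
  }
  invisible(x)
}
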