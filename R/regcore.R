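# Regulation-detection regions, functions, scores, and the regulation-delta.
#
# All pair quantities live on the ordered grid-index pairs (a, b), a != b, of
# one processed replicate: X^d(a, b) = X(t_a) - X(t_b) and
# Ydot^d(a, b) = Ydot(t_a) - Ydot(t_b). A candidate regulation with sign
# vector sigma detects on the region where sigma(i) * X_i^d > 0 for every
# cause i (strict; exact ties are excluded). On that region the detection
# function I = Ydot^d * prod_i sigma(i) X_i^d is positive whenever the data
# are reproducible by a monotone ODE with regulation type sigma, and the
# score S = sum(I) / sum(|I|) equals 1.

#' Construct a candidate regulation
#'
#' A candidate names a target, an ordered set of causes with signs
#' (+1 activation, -1 repression), and optionally an assumed self-regulation
#' sign, which is appended as an extra cause equal to the target (the standard
#' device for targets with degradation: their own level represses their
#' derivative).
#'
#' @param target Component name of the regulated variable.
#' @param causes Character vector of distinct cause components (the target may
#'   enter only through `self_sign`).
#' @param signs Integer vector in `{+1, -1}`, one per cause.
#' @param self_sign Optional `+1`/`-1` assumed self-regulation sign.
#' @return An object of class `regulation_candidate`.
#' @export
regulation_candidate <- function(target, causes, signs, self_sign = NULL) {
  signs <- as.integer(signs)
  stopifnot(
    length(causes) >= 1, length(signs) == length(causes),
    all(signs %in% c(-1L, 1L)), !anyDuplicated(causes),
    !(target %in% causes)
  )
  if (!is.null(self_sign)) {
    self_sign <- as.integer(self_sign)
    stopifnot(self_sign %in% c(-1L, 1L))
  }
  structure(
    list(target = target, causes = causes, signs = signs, self_sign = self_sign),
    class = "regulation_candidate"
  )
}

#' @export
print.regulation_candidate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.regulation_candidate <- function(x, ...) {
  arrows <- ifelse(x$signs > 0, "+", "-")
  lab <- paste0(x$causes, "^", arrows, collapse = " ")
  if (!is.null(x$self_sign)) {
    lab <- paste0(lab, " ", x$target, "^", if (x$self_sign > 0) "+" else "-")
  }
  paste0("[", lab, " -> ", x$target, "]")
}

# causes and signs with the assumed self-regulation appended
effective_causes <- function(cand) {
  causes <- cand$causes
  signs <- cand$signs
  if (!is.null(cand$self_sign)) {
    causes <- c(causes, cand$target)
    signs <- c(signs, cand$self_sign)
  }
  list(causes = causes, signs = signs)
}

check_candidate <- function(ps, cand) {
  eff <- effective_causes(cand)
  missing <- setdiff(c(eff$causes, cand$target), ps$components)
  if (length(missing) > 0) {
    stop("unknown component(s): ", paste(missing, collapse = ", "))
  }
  degen <- intersect(c(eff$causes, cand$target), ps$degenerate)
  if (length(degen) > 0) {
    stop("degenerate (constant) component(s): ", paste(degen, collapse = ", "))
  }
  eff
}

pair_diff <- function(x) outer(x, x, "-")

# scaled pairwise derivative differences of the target; max-abs scaling keeps
# |I| <= 1 and provably leaves S unchanged
target_deriv_diff <- function(ps, target) {
  yd <- pair_diff(ps$derivatives[, target])
  m <- max(abs(yd))
  if (m > 0) yd <- yd / m
  yd
}

#' Regulation-detection region of a candidate
#'
#' The set of ordered grid pairs `(a, b)`, `a != b`, where
#' `sigma(i) * (X_i(t_a) - X_i(t_b)) > 0` holds strictly for every cause; its
#' size is the covered fraction of the `[0, tau)^2` pair domain (count / T^2).
#'
#' @param ps A [processed_series()].
#' @param cand A [regulation_candidate()].
#' @return An object of class `region_mask`: list with `mask` (T x T logical,
#'   diagonal excluded) and `size`.
#' @export
detection_region <- function(ps, cand) {
  eff <- check_candidate(ps, cand)
  mask <- NULL
  for (i in seq_along(eff$causes)) {
    xd <- pair_diff(ps$values[, eff$causes[i]]) * eff$signs[i]
    mask <- if (is.null(mask)) xd > 0 else mask & (xd > 0)
  }
  structure(list(mask = mask, size = sum(mask) / length(mask)), class = "region_mask")
}

#' Regulation-detection function on a region
#'
#' `I(a, b) = [prod_i sigma(i) X_i^d(a, b)] * Ydot^d(a, b)` with the values in
#' normalized units and the target's derivative differences scaled by their
#' maximum absolute value over the replicate, so that `|I| <= 1`.
#'
#' @param ps A [processed_series()].
#' @param cand A [regulation_candidate()].
#' @param region The candidate's [detection_region()] (computed if omitted).
#' @return An object of class `detection_values`: list with the full `I`
#'   matrix, the region `mask`, and the masked values `values`.
#' @export
detection_function <- function(ps, cand, region = NULL) {
  eff <- check_candidate(ps, cand)
  if (is.null(region)) region <- detection_region(ps, cand)
  prod_x <- 1
  for (i in seq_along(eff$causes)) {
    prod_x <- prod_x * (pair_diff(ps$values[, eff$causes[i]]) * eff$signs[i])
  }
  I <- prod_x * target_deriv_diff(ps, cand$target)
  structure(
    list(I = I, mask = region$mask, values = I[region$mask]),
    class = "detection_values"
  )
}

#' Regulation-detection score
#'
#' `S = sum(I over region) / sum(|I| over region)`, in `[-1, 1]`; equals 1
#' exactly when `I >= 0` on the whole region with at least one positive value.
#' An empty region or an identically zero `|I|` yields the undefined score
#' `NA` (downstream aggregation treats such replicates as not counted).
#'
#' @param vals A [detection_function()] result.
#' @return Numeric score in `[-1, 1]`, or `NA` if undefined.
#' @export
detection_score <- function(vals) {
  stopifnot(inherits(vals, "detection_values"))
  iv <- vals$values
  if (length(iv) == 0) return(NA_real_)
  den <- sum(abs(iv))
  if (den == 0) return(NA_real_)
  sum(iv) / den
}

#' Score a candidate on one replicate
#'
#' Convenience wrapper: region, detection function and score in one call.
#'
#' @param ps A [processed_series()].
#' @param cand A [regulation_candidate()].
#' @return List with `score` (may be `NA`) and `region_size`.
#' @export
regulation_score <- function(ps, cand) {
  region <- detection_region(ps, cand)
  vals <- detection_function(ps, cand, region)
  list(score = detection_score(vals), region_size = region$size)
}

#' Regulation-delta of a new component against a base candidate
#'
#' Appends `new_component` to `base` once positively and once negatively and
#' returns both extended scores and their difference
#' `delta = S(+) - S(-)` (in `[-2, 2]`). A delta of zero indicates that the
#' new component plays no regulatory role in the extended candidate.
#'
#' @param ps A [processed_series()].
#' @param base A [regulation_candidate()].
#' @param new_component Component to test; must not already be a cause (or the
#'   target) of `base`.
#' @return List with `delta`, `s_plus`, `s_minus` (`NA`s when either extended
#'   region is empty or degenerate).
#' @export
regulation_delta <- function(ps, base, new_component) {
  stopifnot(!(new_component %in% base$causes), new_component != base$target)
  extend <- function(s) {
    regulation_candidate(
      base$target, c(base$causes, new_component), c(base$signs, s),
      self_sign = base$self_sign
    )
  }
  s_plus <- regulation_score(ps, extend(+1L))$score
  s_minus <- regulation_score(ps, extend(-1L))$score
  delta <- if (is.na(s_plus) || is.na(s_minus)) NA_real_ else s_plus - s_minus
  list(delta = delta, s_plus = s_plus, s_minus = s_minus)
}

# ---- cached fast path --------------------------------------------------------
# Pairwise difference matrices are reused heavily across candidates (and across
# surrogate shuffles), so score sweeps precompute them once per replicate.

build_pair_cache <- function(ps) {
  xd <- lapply(ps$components, function(cp) pair_diff(ps$values[, cp]))
  names(xd) <- ps$components
  yd <- lapply(ps$components, function(cp) target_deriv_diff(ps, cp))
  names(yd) <- ps$components
  list(xd = xd, yd = yd, degenerate = ps$degenerate, T = length(ps$grid))
}

score_from_cache <- function(cache, target, causes, signs) {
  if (any(c(causes, target) %in% cache$degenerate)) {
    return(list(score = NA_real_, region_size = NA_real_))
  }
  mask <- NULL
  prod_x <- 1
  for (i in seq_along(causes)) {
    xd <- cache$xd[[causes[i]]] * signs[i]
    mask <- if (is.null(mask)) xd > 0 else mask & (xd > 0)
    prod_x <- prod_x * xd
  }
  iv <- (prod_x * cache$yd[[target]])[mask]
  size <- sum(mask) / (cache$T^2)
  if (length(iv) == 0) return(list(score = NA_real_, region_size = size))
  den <- sum(abs(iv))
  score <- if (den == 0) NA_real_ else sum(iv) / den
  list(score = score, region_size = size)
}
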