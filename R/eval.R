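# Network evaluation: signed-edge confusion counts and the recall-weighted
# F-beta score.

#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`, the recall-weighted harmonic
#' mean of precision and recall; 0 when both are 0. The default `beta = 2`
#' weights recall four times as heavily as precision.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @param beta Weight on recall (default 2).
#' @return The F-beta score in `[0, 1]`.
#' @export
f_beta <- function(precision, recall, beta = 2) {
  if (any(c(precision, recall) < 0) || any(c(precision, recall) > 1)) {
    stop("precision and recall must be in [0, 1]")
  }
  den <- beta^2 * precision + recall
  if (den == 0) return(0)
  (1 + beta^2) * precision * recall / den
}

edge_keys <- function(edges, signed = TRUE) {
  if (nrow(edges) == 0) return(character(0))
  if (signed) {
    paste(edges$source, edges$sign, edges$target)
  } else {
    paste(edges$source, edges$target)
  }
}

#' Compare an inferred network against a ground-truth edge list
#'
#' An inferred signed edge is a true positive iff its `(source, sign, target)`
#' triple occurs in the truth; an edge with the right endpoints but the wrong
#' sign counts as both a false positive and a false negative. Set
#' `signed = FALSE` for presence-only evaluation.
#'
#' @param inferred An [infer_network()] result, or a data frame with columns
#'   `source`, `sign`, `target`.
#' @param truth Data frame with columns `source`, `sign`, `target`.
#' @param signed Compare signs (default `TRUE`).
#' @param beta F-score weight (default 2).
#' @return List of class `evaluation_report`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f_beta`, `beta`, and a per-edge classification `table`.
#' @export
compare_networks <- function(inferred, truth, signed = TRUE, beta = 2) {
  if (inherits(inferred, "inferred_network")) {
    components <- inferred$components
    inferred <- inferred$edges
    unknown <- setdiff(c(inferred$source, inferred$target), components)
    if (length(unknown) > 0) stop("unknown component(s): ", paste(unknown, collapse = ", "))
  }
  inferred <- unique(inferred[c("source", "sign", "target")])
  truth <- unique(truth[c("source", "sign", "target")])
  ik <- edge_keys(inferred, signed)
  tk <- edge_keys(truth, signed)
  tp <- sum(ik %in% tk)
  fp <- length(ik) - tp
  fn <- length(tk) - tp
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  classification <- rbind(
    if (nrow(inferred) > 0) {
      data.frame(inferred[c("source", "sign", "target")],
                 status = ifelse(ik %in% tk, "TP", "FP"))
    },
    if (nrow(truth) > 0) {
      miss <- !(tk %in% ik)
      if (any(miss)) {
        data.frame(truth[miss, c("source", "sign", "target")], status = "FN")
      }
    }
  )
  structure(
    list(
      tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
      f_beta = f_beta(precision, recall, beta), beta = beta,
      table = classification
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> TP %d, FP %d, FN %d | precision %.3f, recall %.3f, F%g %.3f\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$beta, x$f_beta
  ))
  invisible(x)
}

#' Serialize an inferred network to JSON and edge-list CSV
#'
#' @param network An [infer_network()] result.
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @return The edge data frame, invisibly.
#' @export
write_network <- function(network, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(network, "inferred_network"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        components = network$components,
        edges = network$edges,
        noise_pct = network$diagnostics$noise_pct,
        trs_thres = network$diagnostics$trs_thres
      ),
      json_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(csv_path)) {
    utils::write.csv(network$edges, csv_path, row.names = FALSE)
  }
  invisible(network$edges)
}

#' Read a serialized network's signed edge list back from JSON
#'
#' @param json_path Path written by [write_network()].
#' @return Data frame with `source`, `sign`, `target` (and the stored
#'   provenance columns).
#' @export
read_network <- function(json_path) {
  obj <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  edges <- obj$edges
  if (is.null(edges) || length(edges) == 0) {
    return(data.frame(source = character(0), sign = integer(0), target = character(0)))
  }
  edges$sign <- as.integer(edges$sign)
  edges
}
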