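#' CAFA-style evaluation of GO predictions
#'
#' `fmax()` scans a threshold grid (0.01 steps over (0, 1] by default). At
#' each threshold `t` the predicted set of a protein is its terms with score
#' `>= t`, closed under ancestor propagation (roots excluded); precision is
#' averaged over proteins with at least one predicted term, recall over all
#' benchmark proteins, and Fmax is the maximum harmonic mean over the grid.
#' The smallest maximizing threshold is reported for determinism.
#'
#' @param predictions Named list of [go_prediction()] objects (names are
#'   protein ids), or a single prediction.
#' @param truth A propagated [annotation_set()] of reference annotations;
#'   proteins with empty (namespace-filtered) truth are excluded with a
#'   warning.
#' @param ont A [load_ontology()] ontology, or `NULL` for a flat vocabulary
#'   (no propagation, no namespace structure).
#' @param namespace `"all"`, `"mf"`, `"bp"` or `"cc"`; any other value is
#'   matched against the ontology's namespace strings directly.
#' @param thresholds Score grid; default `seq(0.01, 1, by = 0.01)`.
#' @param propagate_predictions Close thresholded predicted sets under
#'   ancestors (default TRUE; ignored when `ont` is NULL).
#' @param strict_precision Average precision over all proteins rather than
#'   only those with a nonempty predicted set (default FALSE, the CAFA1
#'   convention).
#' @return For `fmax`: list with `fmax`, `threshold`, `precision`, `recall`
#'   at the optimum, the evaluated `proteins`, and the full `curve` data
#'   frame.
#' @export
fmax <- function(predictions, truth, ont = NULL, namespace = "all",
                 thresholds = seq(0.01, 1, by = 0.01),
                 propagate_predictions = TRUE, strict_precision = FALSE) {
  ev <- evaluation_inputs(predictions, truth, ont, namespace,
                          propagate_predictions)
  if (length(ev$proteins) == 0L)
    stop("no proteins with nonempty truth to evaluate", call. = FALSE)
  curve <- data.frame(threshold = thresholds, precision = NA_real_,
                      recall = NA_real_, f = NA_real_)
  for (r in seq_along(thresholds)) {
    t <- thresholds[[r]]
    pr <- c(); rc <- c()
    for (p in ev$proteins) {
      pred <- ev$pred_at(p, t)
      tp <- length(intersect(pred, ev$truth[[p]]))
      if (length(pred) > 0L) pr <- c(pr, tp / length(pred))
      else if (strict_precision) pr <- c(pr, 0)
      rc <- c(rc, tp / length(ev$truth[[p]]))
    }
    precision <- if (length(pr)) mean(pr) else 0
    recall <- mean(rc)
    f <- if (precision + recall > 0) 2 * precision * recall /
      (precision + recall) else 0
    curve[r, ] <- list(t, precision, recall, f)
  }
  best <- which.max(curve$f)   # smallest maximizing threshold
  list(fmax = curve$f[[best]], threshold = curve$threshold[[best]],
       precision = curve$precision[[best]], recall = curve$recall[[best]],
       proteins = ev$proteins, curve = curve)
}

#' @param ic Named numeric vector of per-term information content in bits
#'   (from [information_content()]); terms without an ic value are assigned
#'   the maximum observed ic as a guard, with a warning.
#' @return For `smin`: list with `smin`, `threshold`, `ru`, `mi` at the
#'   optimum, and the full `curve`.
#' @rdname fmax
#' @export
smin <- function(predictions, truth, ic, ont = NULL, namespace = "all",
                 thresholds = seq(0.01, 1, by = 0.01),
                 propagate_predictions = TRUE) {
  ev <- evaluation_inputs(predictions, truth, ont, namespace,
                          propagate_predictions)
  if (length(ev$proteins) == 0L)
    stop("no proteins with nonempty truth to evaluate", call. = FALSE)
  guard <- if (length(ic)) max(ic) else 0
  warned <- FALSE
  ic_of <- function(terms) {
    known <- terms %in% names(ic)
    if (any(!known) && !warned) {
      warning(sum(!known), " term(s) without ic assigned the guard value ",
              signif(guard, 4))
      warned <<- TRUE
    }
    sum(ic[terms[known]]) + guard * sum(!known)
  }
  curve <- data.frame(threshold = thresholds, ru = NA_real_, mi = NA_real_,
                      s = NA_real_)
  for (r in seq_along(thresholds)) {
    t <- thresholds[[r]]
    ru <- 0; mi <- 0
    for (p in ev$proteins) {
      pred <- ev$pred_at(p, t)
      ru <- ru + ic_of(setdiff(ev$truth[[p]], pred))
      mi <- mi + ic_of(setdiff(pred, ev$truth[[p]]))
    }
    ru <- ru / length(ev$proteins)
    mi <- mi / length(ev$proteins)
    curve[r, ] <- list(t, ru, mi, sqrt(ru^2 + mi^2))
  }
  best <- which.min(curve$s)   # smallest minimizing threshold
  list(smin = curve$s[[best]], threshold = curve$threshold[[best]],
       ru = curve$ru[[best]], mi = curve$mi[[best]], curve = curve)
}

# Shared preparation: namespace-filtered truth sets and a closure computing
# the thresholded, propagated predicted set of a protein.
evaluation_inputs <- function(predictions, truth, ont, namespace,
                              propagate_predictions) {
  stopifnot(inherits(truth, "annotation_set"))
  if (inherits(predictions, "go_prediction")) {
    predictions <- stats::setNames(list(predictions), predictions$query_id)
  }
  ns_terms <- namespace_terms(ont, namespace)
  filter_ns <- function(terms)
    if (is.null(ns_terms)) terms else intersect(terms, ns_terms)
  truth_sets <- lapply(truth$proteins, filter_ns)
  empty <- vapply(truth_sets, length, integer(1)) == 0L
  if (any(empty))
    warning(sum(empty), " protein(s) with empty truth excluded from evaluation")
  proteins <- names(truth_sets)[!empty]
  pred_at <- function(p, t) {
    pr <- predictions[[p]]
    if (is.null(pr) || length(pr$scores) == 0L) return(character(0))
    sel <- names(pr$scores)[pr$scores >= t]
    if (!is.null(ont) && propagate_predictions && length(sel)) {
      res <- resolve_term(ont, sel)
      res <- res[!is.na(res)]
      sel <- setdiff(unique(c(res, unlist(ont$ancestors[res],
                                          use.names = FALSE))), ont$roots)
    }
    filter_ns(sel)
  }
  list(proteins = proteins, truth = truth_sets[!empty], pred_at = pred_at)
}

# Terms belonging to a namespace, or NULL for no filtering.
namespace_terms <- function(ont, namespace) {
  if (is.null(ont) || identical(namespace, "all")) return(NULL)
  ns <- switch(namespace,
               mf = "molecular_function",
               bp = "biological_process",
               cc = "cellular_component",
               namespace)
  ont$id[ont$namespace == ns]
}

#' Per-protein F score at a fixed threshold
#'
#' Protein-level F1 of the thresholded, propagated predicted set against the
#' protein's propagated truth set, typically at the threshold that yielded
#' Fmax on the whole benchmark. Returns 0 when the predicted set is empty.
#'
#' @inheritParams fmax
#' @param t Score threshold (use the `threshold` reported by [fmax()]).
#' @return Named numeric vector of F scores, one per evaluated protein.
#' @export
per_protein_f <- function(predictions, truth, t, ont = NULL,
                          namespace = "all", propagate_predictions = TRUE) {
  ev <- evaluation_inputs(predictions, truth, ont, namespace,
                          propagate_predictions)
  out <- vapply(ev$proteins, function(p) {
    pred <- ev$pred_at(p, t)
    if (length(pred) == 0L) return(0)
    tp <- length(intersect(pred, ev$truth[[p]]))
    pr <- tp / length(pred)
    rc <- tp / length(ev$truth[[p]])
    if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  }, numeric(1))
  stats::setNames(out, ev$proteins)
}

#' Head-to-head win counts between two methods
#'
#' Counts the proteins on which each method's per-protein F score strictly
#' exceeds the other's; equal scores are ties, reported separately.
#'
#' @param f_a,f_b Named numeric vectors of per-protein F scores over the
#'   same protein universe.
#' @return List with `wins_a`, `wins_b`, `ties`.
#' @export
win_counts <- function(f_a, f_b) {
  diff_ab <- c(setdiff(names(f_a), names(f_b)),
               setdiff(names(f_b), names(f_a)))
  if (length(diff_ab))
    stop("protein universes differ; symmetric difference: ",
         paste(diff_ab, collapse = ", "), call. = FALSE)
  f_b <- f_b[names(f_a)]
  list(wins_a = sum(f_a > f_b),
       wins_b = sum(f_b > f_a),
       ties = sum(f_a == f_b))
}
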