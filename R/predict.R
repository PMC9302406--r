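#' GO term predictions for one query
#'
#' A prediction maps GO term ids to confidence scores. After top-score
#' normalization, scores lie in (0, 1] and the most confident term scores
#' exactly 1.0.
#'
#' @param query_id Query protein id.
#' @param scores Named numeric vector, term id -> score.
#' @param normalized Whether scores have been top-score normalized.
#' @return A `go_prediction`.
#' @export
go_prediction <- function(query_id, scores = numeric(0), normalized = FALSE) {
  if (length(scores) && is.null(names(scores)))
    stop("scores must be named by GO term id", call. = FALSE)
  if (normalized && length(scores)) {
    if (min(scores) <= 0 || max(scores) > 1 + 1e-9)
      stop("normalized scores must lie in (0, 1]", call. = FALSE)
    if (abs(max(scores) - 1) > 1e-9)
      stop("a nonempty normalized prediction must have top score 1.0",
           call. = FALSE)
  }
  structure(list(query_id = as.character(query_id),
                 scores = scores, normalized = normalized),
            class = "go_prediction")
}

#' @export
print.go_prediction <- function(x, ...) {
  cat(sprintf("Prediction for '%s': %d terms (%s)\n", x$query_id,
              length(x$scores),
              if (x$normalized) "normalized" else "raw"))
  if (length(x$scores)) {
    top <- sort(x$scores, decreasing = TRUE)
    print(round(utils::head(top, 8L), 3))
  }
  invisible(x)
}

#' Score GO terms from selected hits
#'
#' Each GO term annotated to a selected hit receives the sum of the graph
#' similarity scores of the hits carrying it:
#' `score(i) = sum over hits k annotated with term i of sim(k)`.
#' Terms can only come from hits. Hits absent from the annotation table
#' contribute nothing and are warned about once per id.
#'
#' @param hits A [hit_list()] already filtered by [select_hits()].
#' @param annotations An [annotation_set()] (direct by default; propagate
#'   first with [propagate_annotations()] to transfer ancestor terms too).
#' @return A raw (unnormalized) [go_prediction()].
#' @examples
#' hits <- hit_list("Q", c("H1", "H2"), c(0.733, 0.658))
#' ann <- annotation_set(list(H1 = c("GO:1", "GO:2"), H2 = c("GO:1", "GO:3")))
#' score_go_terms(hits, ann)$scores   # GO:1 = 1.391
#' @export
score_go_terms <- function(hits, annotations) {
  stopifnot(inherits(hits, "hit_list"), inherits(annotations, "annotation_set"))
  acc <- new.env(parent = emptyenv())
  missing_ids <- character(0)
  for (r in seq_len(nrow(hits$hits))) {
    id <- hits$hits$reference_id[[r]]
    s <- hits$hits$score[[r]]
    terms <- annotations$proteins[[id]]
    if (is.null(terms)) {
      missing_ids <- c(missing_ids, id)
      next
    }
    for (t in terms)
      assign(t, s + (if (exists(t, envir = acc)) get(t, envir = acc) else 0),
             envir = acc)
  }
  if (length(missing_ids))
    warning("hit id(s) without annotations contributed nothing: ",
            paste(unique(missing_ids), collapse = ", "))
  terms <- ls(acc)
  scores <- stats::setNames(
    vapply(terms, get, numeric(1), envir = acc), terms)
  go_prediction(hits$query_id, scores, normalized = FALSE)
}

#' Top-score normalization
#'
#' Divides every score by the maximum, so the most confident term scores
#' exactly 1.0. Idempotent; an empty prediction passes through.
#'
#' @param raw A [go_prediction()].
#' @return A normalized `go_prediction`.
#' @export
normalize_prediction <- function(raw) {
  stopifnot(inherits(raw, "go_prediction"))
  if (length(raw$scores) == 0L)
    return(go_prediction(raw$query_id, raw$scores, normalized = TRUE))
  go_prediction(raw$query_id, raw$scores / max(raw$scores),
                normalized = TRUE)
}

#' Uniform scoring from the top hits
#'
#' Baseline scoring mode: the union of GO terms of the top `n` hits, every
#' term assigned a score of 1.0 (mirroring how plain sequence-search
#' baselines are scored from their top 10 hits).
#'
#' @param hits A [hit_list()].
#' @param annotations An [annotation_set()].
#' @param n Number of top hits to pool (default 10).
#' @return A normalized [go_prediction()] (all scores 1.0).
#' @export
uniform_score_from_hits <- function(hits, annotations, n = 10L) {
  stopifnot(inherits(hits, "hit_list"), n >= 1L)
  top <- utils::head(hits$hits$reference_id, n)
  terms <- unique(unlist(annotations$proteins[
    intersect(top, names(annotations$proteins))], use.names = FALSE))
  scores <- stats::setNames(rep(1.0, length(terms)), terms)
  go_prediction(hits$query_id, scores, normalized = TRUE)
}

#' Average predictions from several methods
#'
#' Score-averaging ensemble: for every term appearing in any component
#' prediction, the ensemble score is the arithmetic mean of the component
#' scores with absent terms counting as 0 (the divisor is always the number
#' of methods combined). All components must be normalized predictions for
#' the same query.
#'
#' @param predictions List of normalized [go_prediction()] objects.
#' @return A `go_prediction` with scores in (0, 1]; flagged normalized only
#'   if the top score is 1.0 (i.e. some term was predicted at 1.0 by every
#'   method).
#' @export
ensemble_average <- function(predictions) {
  stopifnot(length(predictions) >= 1L)
  for (p in predictions) {
    stopifnot(inherits(p, "go_prediction"))
    if (!p$normalized)
      stop("ensemble components must be normalized predictions",
           call. = FALSE)
  }
  qids <- unique(vapply(predictions, `[[`, character(1), "query_id"))
  if (length(qids) != 1L)
    stop("cannot ensemble predictions for different queries: ",
         paste(qids, collapse = ", "), call. = FALSE)
  all_terms <- unique(unlist(lapply(predictions, function(p)
    names(p$scores)), use.names = FALSE))
  if (length(all_terms) == 0L)
    return(go_prediction(qids, numeric(0), normalized = TRUE))
  m <- vapply(predictions, function(p) {
    v <- stats::setNames(rep(0, length(all_terms)), all_terms)
    v[names(p$scores)] <- p$scores
    v
  }, numeric(length(all_terms)))
  scores <- rowMeans(matrix(m, nrow = length(all_terms)))
  names(scores) <- all_terms
  go_prediction(qids, scores,
                normalized = abs(max(scores) - 1) < 1e-9)
}

#' Read and write CAFA-style prediction files
#'
#' Tab-separated `query_id  go_id  score` rows, scores printed with three
#' decimals, ordered by descending score then term id.
#'
#' @param prediction A [go_prediction()].
#' @param path File path.
#' @export
write_prediction <- function(prediction, path) {
  stopifnot(inherits(prediction, "go_prediction"))
  s <- prediction$scores
  ord <- order(-s, names(s))
  df <- data.frame(query_id = prediction$query_id,
                   go_id = names(s)[ord],
                   score = sprintf("%.3f", s[ord]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param normalized Whether the file carries normalized scores (flag set on
#'   the returned objects).
#' @rdname write_prediction
#' @return `read_predictions` returns a named list of `go_prediction`
#'   objects, one per query id present in the file.
#' @export
read_predictions <- function(path, normalized = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("query_id", "go_id", "score"))
  out <- lapply(split(df, df$query_id), function(d) {
    s <- stats::setNames(as.numeric(d$score), d$go_id)
    go_prediction(d$query_id[[1L]], s,
                  normalized = normalized && length(s) > 0L &&
                    abs(max(s) - 1) < 1e-9)
  })
  out[order(names(out))]
}
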