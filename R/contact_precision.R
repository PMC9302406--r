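#' Precision of predicted contacts against a reference structure
#'
#' Two evaluation modes are provided. `"all"` computes the fraction of
#' predicted contacts that are present in the reference graph, both graphs
#' taken at their shared cutoff (conventionally 12 A). `"top_L5_long"`
#' restricts to long-range pairs (sequence separation >= 24), ranks candidate
#' pairs by a per-pair confidence and evaluates the `floor(L/5)`
#' highest-confidence pairs against the reference (conventionally built at
#' 8 A).
#'
#' @param predicted Predicted [contact_graph()] (mode `"all"`), or ignored in
#'   mode `"top_L5_long"` where `pair_scores` supplies the candidates.
#' @param reference Reference [contact_graph()] from the experimental
#'   structure; must have the same length as `predicted`.
#' @param mode `"all"` or `"top_L5_long"`.
#' @param pair_scores Data frame or 3-column matrix `(i, j, score)` of
#'   per-pair confidences; required for mode `"top_L5_long"`.
#' @param long_range_separation Minimum separation defining a long-range
#'   contact (default 24).
#' @return Precision as a fraction in [0, 1] (`NaN` when nothing is selected
#'   in mode `"all"`).
#' @export
contact_precision <- function(predicted, reference,
                              mode = c("all", "top_L5_long"),
                              pair_scores = NULL,
                              long_range_separation = 24L) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "contact_graph"))
  ref_keys <- edge_keys(reference)
  if (mode == "all") {
    stopifnot(inherits(predicted, "contact_graph"))
    if (predicted$length != reference$length)
      stop("predicted and reference graphs have different lengths (",
           predicted$length, " vs ", reference$length, ")", call. = FALSE)
    pred_keys <- edge_keys(predicted)
    if (length(pred_keys) == 0L) return(NaN)
    return(sum(pred_keys %in% ref_keys) / length(pred_keys))
  }
  # top_L5_long
  L <- reference$length
  n_top <- L %/% 5L
  if (n_top < 1L)
    stop("degenerate input: L/5 < 1 (L = ", L, ")", call. = FALSE)
  if (is.null(pair_scores))
    stop("mode 'top_L5_long' requires pair_scores (i, j, score)",
         call. = FALSE)
  ps <- as.data.frame(pair_scores)
  names(ps)[1:3] <- c("i", "j", "score")
  ii <- pmin(ps$i, ps$j); jj <- pmax(ps$i, ps$j)
  keep <- (jj - ii) >= long_range_separation
  ps <- data.frame(i = ii[keep], j = jj[keep], score = ps$score[keep])
  ps <- ps[!duplicated(paste(ps$i, ps$j)), , drop = FALSE]
  if (nrow(ps) < n_top)
    warning("only ", nrow(ps), " long-range candidate pairs for top ",
            n_top, " selection")
  ord <- order(-ps$score, ps$i, ps$j)
  sel <- ps[ord[seq_len(min(n_top, nrow(ps)))], , drop = FALSE]
  if (nrow(sel) == 0L) return(NaN)
  sum(paste(sel$i, sel$j) %in% ref_keys) / nrow(sel)
}
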