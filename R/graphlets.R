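#' Graphlet degree signatures (orbits 0-14)
#'
#' Counts, for every node, the number of times it touches each of the 15
#' automorphism orbits of the 9 connected graphlets on 2-4 nodes (orbit 0 is
#' the node degree; orbit 14 is a K4 position). Counting enumerates every
#' connected induced subgraph on 2-4 nodes exactly once, so the counts are
#' exact.
#'
#' @param graph A [contact_graph()].
#' @return Integer matrix `L x 15`; row `v` is the graphlet degree signature
#'   of node `v`, column `o + 1` the count of orbit `o`.
#' @examples
#' path3 <- contact_graph("p3", 3, rbind(c(1, 2), c(2, 3)), 8, min_separation = 1)
#' count_orbits(path3)
#' @export
count_orbits <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  m <- count_orbits_cpp(graph$edges, graph$length)
  colnames(m) <- paste0("O", 0:14)
  m
}

# Orbit dependency counts o_i: the number of orbits j (including i itself)
# whose representative rooted graphlet embeds as a subgraph of orbit i's
# rooted graphlet. Derived once by enumerating embeddings of the 15 orbit
# representatives; orbit 0 depends only on itself, a K4 position touches
# all 15.
orbit_dependency_counts <- function() {
  c(1L, 2L, 2L, 4L, 3L, 4L, 3L, 3L, 6L, 5L, 8L, 7L, 11L, 12L, 15L)
}

#' Per-orbit weights for the signature distance
#'
#' Higher-order orbits are progressively down-weighted because their counts
#' are partially determined by lower-order ones:
#' `w_i = 1 - log(o_i) / log(73)`, where `o_i` is the number of orbits that
#' affect orbit `i` (see `orbit_dependency_counts`). Orbit 0 (degree) gets
#' weight 1.
#'
#' @return Numeric vector of 15 weights in (0, 1].
#' @export
orbit_weights <- function() {
  1 - log(orbit_dependency_counts()) / log(73)
}

#' Similarity of two graphlet degree signatures
#'
#' One minus a weighted, log-scaled signature distance: per orbit,
#' `d_i = |log(u_i + 1) - log(v_i + 1)| / log(max(u_i, v_i) + 2)`, combined
#' as `1 - sum(w_i * d_i) / sum(w_i)`. Symmetric, in [0, 1], and 1 exactly
#' for identical signatures.
#'
#' @param sig_u,sig_v Integer vectors of length 15 (rows of
#'   [count_orbits()]).
#' @return Similarity in [0, 1].
#' @export
node_similarity <- function(sig_u, sig_v) {
  if (length(sig_u) != 15L || length(sig_v) != 15L)
    stop("graphlet signatures must have length 15", call. = FALSE)
  w <- orbit_weights()
  d <- abs(log(sig_u + 1) - log(sig_v + 1)) / log(pmax(sig_u, sig_v) + 2)
  1 - sum(w * d) / sum(w)
}

# Node-similarity matrix between all rows of two signature matrices,
# vectorized one orbit at a time.
signature_similarity_matrix <- function(sig1, sig2) {
  w <- orbit_weights()
  n1 <- nrow(sig1); n2 <- nrow(sig2)
  acc <- matrix(0, n1, n2)
  for (k in 1:15) {
    a <- sig1[, k]; b <- sig2[, k]
    num <- abs(outer(log(a + 1), log(b + 1), `-`))
    den <- log(outer(a, b, pmax) + 2)
    acc <- acc + w[k] * (num / den)
  }
  1 - acc / sum(w)
}

#' Order-preserving alignment of two contact graphs
#'
#' Nodes of both graphs are compared by graphlet-signature similarity, then
#' aligned by a global dynamic program over the two node orders (a strictly
#' increasing partial matching), maximizing the summed similarity of matched
#' pairs plus `gap_score` per unmatched node. The reported graph similarity
#' is the matched-pair similarity of the optimal alignment divided by
#' `max(L1, L2)`, so it lies in [0, 1] and equals 1.0 for identical graphs.
#' Ties in the dynamic program are resolved toward matching, then toward
#' consuming nodes of the first graph, making the mapping deterministic.
#'
#' @param g1,g2 Nonempty [contact_graph()] objects.
#' @param gap_score Score contribution of an unmatched node (default 0).
#' @param sig1,sig2 Optional precomputed [count_orbits()] matrices (used by
#'   the database search to avoid recounting).
#' @return A list of class `graph_alignment` with elements `score` (graph
#'   similarity in [0, 1]), `mapping` (k x 2 matrix of matched node indices,
#'   strictly increasing in both columns), and `objective` (raw dynamic
#'   programming optimum including gap contributions).
#' @examples
#' g <- contact_graph("t", 6, rbind(c(1, 3), c(2, 4), c(3, 5)), 12)
#' align_graphs(g, g)$score
#' @export
align_graphs <- function(g1, g2, gap_score = 0, sig1 = NULL, sig2 = NULL) {
  stopifnot(inherits(g1, "contact_graph"), inherits(g2, "contact_graph"))
  if (g1$length < 1L || g2$length < 1L)
    stop("degenerate input: cannot align an empty graph", call. = FALSE)
  if (is.null(sig1)) sig1 <- count_orbits(g1)
  if (is.null(sig2)) sig2 <- count_orbits(g2)
  sim <- signature_similarity_matrix(sig1, sig2)
  res <- align_dp_cpp(sim, gap_score)
  structure(
    list(score = res$matched_similarity / max(g1$length, g2$length),
         mapping = res$mapping,
         objective = res$objective,
         id1 = g1$protein_id, id2 = g2$protein_id),
    class = "graph_alignment")
}

#' @export
print.graph_alignment <- function(x, ...) {
  cat(sprintf("Alignment %s vs %s: score %.4f, %d matched nodes\n",
              x$id1, x$id2, x$score, nrow(x$mapping)))
  invisible(x)
}

#' Write an alignment as a two-column matched-index TSV
#'
#' A `# score <s>` header line is followed by one `i<TAB>j` row per matched
#' node pair.
#'
#' @param alignment A `graph_alignment` from [align_graphs()].
#' @param path File path.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# score %.6f", alignment$score), con)
  if (nrow(alignment$mapping))
    writeLines(paste(alignment$mapping[, 1L], alignment$mapping[, 2L],
                     sep = "\t"), con)
  invisible(path)
}
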