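#' Build a reference database of contact graphs
#'
#' The reference collection maps protein identifiers to contact graphs with
#' precomputed graphlet signatures, filtered by sequence length: entries
#' shorter than `min_len` or longer than `max_len` residues are excluded
#' (bounds inclusive, i.e. lengths of exactly `min_len` or `max_len` are
#' retained). Defaults follow the convention of excluding sequences below 20
#' and above 2000 residues.
#'
#' @param graphs List of [contact_graph()] objects (ideally all built at the
#'   same cutoff).
#' @param min_len,max_len Inclusive residue-length bounds (defaults 20 and
#'   2000).
#' @return An object of class `reference_db` with fields `entries` (named
#'   list of `graph`, `signature`, `length`, `mnemonic`), `cutoff`,
#'   `min_len`, `max_len` and `n_excluded`.
#' @export
build_reference_db <- function(graphs, min_len = 20L, max_len = 2000L) {
  ids <- vapply(graphs, function(g) g$protein_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate reference ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  lens <- vapply(graphs, function(g) g$length, integer(1))
  keep <- lens >= min_len & lens <= max_len
  n_excluded <- sum(!keep)
  graphs <- graphs[keep]
  ids <- ids[keep]
  if (length(graphs) == 0L)
    warning("reference database is empty after length filtering")
  entries <- lapply(graphs, function(g) {
    list(graph = g,
         signature = count_orbits(g),
         length = g$length,
         mnemonic = mnemonic_code(g$protein_id))
  })
  names(entries) <- ids
  structure(
    list(entries = entries,
         cutoff = if (length(graphs)) graphs[[1L]]$cutoff else NA_real_,
         min_len = as.integer(min_len),
         max_len = as.integer(max_len),
         n_excluded = n_excluded),
    class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("Reference DB: %d entries (cutoff %g A, lengths %d-%d, %d excluded at build)\n",
              length(x$entries), x$cutoff, x$min_len, x$max_len,
              x$n_excluded))
  invisible(x)
}

# CODE part of a UniProt-style entry name CODE_SPECIES; the full id when no
# underscore is present.
mnemonic_code <- function(id) sub("_.*$", "", id)

#' Deduplicate orthologs by mnemonic code
#'
#' UniProt entry names have the form `CODE_SPECIES`; orthologs across species
#' share the `CODE` prefix. One id is kept per prefix -- the
#' lexicographically smallest full id, a deterministic choice. Ids without an
#' underscore form their own group and are reported via a message.
#'
#' @param ids Character vector of entry names.
#' @return The retained ids, in the order they first appear.
#' @examples
#' dedup_by_mnemonic(c("ZRT1_YEAST", "ZRT1_SCHPO"))  # keeps ZRT1_SCHPO
#' @export
dedup_by_mnemonic <- function(ids) {
  malformed <- !grepl("_", ids)
  if (any(malformed))
    message(sum(malformed), " id(s) without an underscore kept as their own group: ",
            paste(utils::head(ids[malformed], 5L), collapse = ", "))
  codes <- ifelse(malformed, ids, mnemonic_code(ids))
  kept <- vapply(split(ids, codes), function(g) sort(g)[1L], character(1))
  ids[ids %in% kept]
}

#' Rank reference proteins by contact-graph similarity to a query
#'
#' Every database entry is aligned to the query with [align_graphs()] and
#' entries are ranked by descending similarity score, ties broken by
#' ascending reference id. Signatures stored in the database are reused, so
#' only the query's orbits are counted.
#'
#' @param query A [contact_graph()].
#' @param db A [build_reference_db()] database.
#' @param gap_score Passed to [align_graphs()].
#' @return An object of class `hit_list`: list with `query_id` and a data
#'   frame `hits` with columns `reference_id`, `score`, `rank`.
#' @export
search_reference_db <- function(query, db, gap_score = 0) {
  stopifnot(inherits(query, "contact_graph"), inherits(db, "reference_db"))
  if (length(db$entries) == 0L)
    stop("cannot search an empty reference database", call. = FALSE)
  qsig <- count_orbits(query)
  scores <- vapply(db$entries, function(e) {
    align_graphs(query, e$graph, gap_score, sig1 = qsig,
                 sig2 = e$signature)$score
  }, numeric(1))
  ids <- names(db$entries)
  ord <- order(-scores, ids)
  hit_list(query$protein_id, ids[ord], unname(scores[ord]))
}

#' Construct a hit list
#'
#' @param query_id Query identifier.
#' @param reference_id Reference ids in rank order.
#' @param score Similarity scores in [0, 1], non-increasing.
#' @return A `hit_list` object.
#' @export
hit_list <- function(query_id, reference_id, score) {
  if (length(reference_id) != length(score))
    stop("reference_id and score lengths differ", call. = FALSE)
  if (anyDuplicated(reference_id))
    stop("duplicate reference ids in hit list", call. = FALSE)
  if (length(score) && (min(score) < -1e-9 || max(score) > 1 + 1e-9))
    stop("hit scores must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(rev(score)))
    stop("hit scores must be in descending order", call. = FALSE)
  structure(
    list(query_id = as.character(query_id),
         hits = data.frame(reference_id = as.character(reference_id),
                           score = as.numeric(score),
                           rank = seq_along(score))),
    class = "hit_list")
}

#' @export
print.hit_list <- function(x, ...) {
  cat(sprintf("Hit list for '%s': %d hits\n", x$query_id, nrow(x$hits)))
  if (nrow(x$hits)) print(utils::head(x$hits, 10L))
  invisible(x)
}

#' Hit-selection policy
#'
#' Three schemes for deciding which ranked hits to transfer annotations
#' from: `"score_threshold"` keeps hits whose raw similarity is at least the
#' parameter (the classical choice being 0.5); `"top_n"` keeps the first N
#' hits regardless of score (N = 2 performing best in combination with a
#' 12 A cutoff); `"z_score"` keeps hits whose similarity is at least
#' `parameter` standard deviations above the mean of the query's score
#' distribution.
#'
#' @param scheme One of `"score_threshold"`, `"top_n"`, `"z_score"`.
#' @param parameter Threshold in [0, 1], N >= 1, or Z >= 0 respectively.
#' @return A `selection_policy` object.
#' @export
selection_policy <- function(scheme = c("top_n", "score_threshold", "z_score"),
                             parameter = 2) {
  scheme <- match.arg(scheme)
  ok <- switch(scheme,
    score_threshold = is.numeric(parameter) && parameter >= 0 && parameter <= 1,
    top_n = is.numeric(parameter) && parameter >= 1,
    z_score = is.numeric(parameter) && parameter >= 0)
  if (!ok)
    stop("invalid parameter ", parameter, " for scheme '", scheme, "'",
         call. = FALSE)
  structure(list(scheme = scheme, parameter = parameter),
            class = "selection_policy")
}

#' Select hits for annotation transfer
#'
#' Exclusions (typically the query itself and references flagged as
#' trivially identifiable, supplied as an id list) are removed first; the
#' policy then operates on the remaining ranked list. Output is always a
#' subset of the input and preserves rank order.
#'
#' @param hits A [hit_list()].
#' @param policy A [selection_policy()]; default top-2.
#' @param exclusions Character vector of reference ids to drop before
#'   selection.
#' @param min_score Optional additional raw-score floor applied under
#'   `top_n` (disabled by default: top-N selection is by rank regardless of
#'   score).
#' @return A filtered `hit_list` (ranks renumbered).
#' @export
select_hits <- function(hits, policy = selection_policy("top_n", 2),
                        exclusions = character(0), min_score = NULL) {
  stopifnot(inherits(hits, "hit_list"), inherits(policy, "selection_policy"))
  h <- hits$hits[!(hits$hits$reference_id %in% exclusions), , drop = FALSE]
  keep <- switch(policy$scheme,
    score_threshold = h$score >= policy$parameter,
    top_n = {
      k <- seq_len(nrow(h)) <= policy$parameter
      if (!is.null(min_score)) k & h$score >= min_score else k
    },
    z_score = {
      mu <- mean(h$score)
      sigma <- sqrt(mean((h$score - mu)^2))
      if (sigma == 0)
        stop("z_score selection undefined: zero score variance for this ",
             "query; use score_threshold or top_n", call. = FALSE)
      (h$score - mu) / sigma >= policy$parameter
    })
  h <- h[keep, , drop = FALSE]
  hit_list(hits$query_id, h$reference_id, h$score)
}

#' Persist and restore a reference database
#'
#' A single JSON archive carrying edge lists, precomputed orbit signatures
#' and build metadata, so that loading skips orbit recounting.
#'
#' @param db A `reference_db`.
#' @param path File path (conventionally `*.json`).
#' @export
save_reference_db <- function(db, path) {
  stopifnot(inherits(db, "reference_db"))
  payload <- list(
    format = "contactGO-refdb-1",
    cutoff = db$cutoff, min_len = db$min_len, max_len = db$max_len,
    n_excluded = db$n_excluded,
    entries = lapply(db$entries, function(e) {
      list(length = e$graph$length,
           cutoff = e$graph$cutoff,
           min_separation = e$graph$min_separation,
           edges = e$graph$edges,
           signature = e$signature)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_reference_db
#' @export
load_reference_db <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "contactGO-refdb-1"))
    stop("not a reference database archive: ", path, call. = FALSE)
  entries <- lapply(names(payload$entries), function(id) {
    e <- payload$entries[[id]]
    g <- contact_graph(id, e$length, e$edges, e$cutoff, e$min_separation)
    sig <- matrix(as.integer(e$signature), ncol = 15L,
                  dimnames = list(NULL, paste0("O", 0:14)))
    list(graph = g, signature = sig, length = g$length,
         mnemonic = mnemonic_code(id))
  })
  names(entries) <- names(payload$entries)
  structure(
    list(entries = entries, cutoff = payload$cutoff,
         min_len = as.integer(payload$min_len),
         max_len = as.integer(payload$max_len),
         n_excluded = payload$n_excluded),
    class = "reference_db")
}

#' Write a hit list as TSV
#'
#' Columns: `query_id`, `reference_id`, `rank`, `score`.
#'
#' @param hits A [hit_list()].
#' @param path File path.
#' @export
write_hit_list <- function(hits, path) {
  df <- data.frame(query_id = hits$query_id,
                   reference_id = hits$hits$reference_id,
                   rank = hits$hits$rank,
                   score = sprintf("%.6f", hits$hits$score))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
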