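#' Load a Gene Ontology from an OBO file
#'
#' Minimal OBO 1.2/1.4 stanza parser covering the fields this pipeline
#' needs: `id`, `name`, `namespace`, `alt_id`, `is_a`,
#' `relationship: part_of`, `is_obsolete`, `replaced_by`. Obsolete terms are
#' dropped (a replacement map is kept when `replaced_by` is present) and
#' `alt_id`s resolve to their canonical term. The parent relation
#' (`is_a` + `part_of`) must be acyclic; a cycle is a fatal parse error
#' naming the offending terms.
#'
#' @param obo_source Path to an OBO file, or a character vector of OBO lines.
#' @return An object of class `go_ontology` with fields `id`, `name`,
#'   `namespace` (parallel vectors), `parents` (named list), `ancestors`
#'   (named list, transitive closure excluding self), `roots` (per-namespace
#'   root ids), `alt_map`, `replaced_map`.
#' @export
load_ontology <- function(obo_source) {
  lines <- if (length(obo_source) == 1L && file.exists(obo_source))
    readLines(obo_source) else obo_source
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L)
    stop("no [Term] stanzas found", call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  terms <- list()
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[(s + 1L):e]
    block <- block[nzchar(block) & !startsWith(block, "!")]
    field <- sub(":.*$", "", block)
    value <- trimws(sub("^[^:]+:", "", block))
    value <- sub("\\s*!.*$", "", value)           # strip trailing comments
    id <- value[field == "id"][1L]
    if (is.na(id)) next
    terms[[id]] <- list(
      id = id,
      name = value[field == "name"][1L],
      namespace = value[field == "namespace"][1L],
      alt_id = value[field == "alt_id"],
      is_a = value[field == "is_a"],
      part_of = sub("^part_of\\s+", "",
                    grep("^part_of\\s", value[field == "relationship"],
                         value = TRUE)),
      obsolete = any(value[field == "is_obsolete"] == "true"),
      replaced_by = value[field == "replaced_by"][1L])
  }
  obsolete <- vapply(terms, `[[`, logical(1), "obsolete")
  replaced_map <- vapply(terms[obsolete], function(t)
    if (is.null(t$replaced_by)) NA_character_ else t$replaced_by,
    character(1))
  replaced_map <- replaced_map[!is.na(replaced_map)]
  terms <- terms[!obsolete]
  ids <- names(terms)
  alt_pairs <- lapply(terms, function(t)
    if (length(t$alt_id)) cbind(t$alt_id, t$id) else NULL)
  alt_pairs <- do.call(rbind, alt_pairs)
  alt_map <- if (is.null(alt_pairs)) character(0) else
    stats::setNames(alt_pairs[, 2L], alt_pairs[, 1L])
  parents <- lapply(terms, function(t) {
    p <- unique(c(t$is_a, t$part_of))
    p[p %in% ids]       # parents pointing at obsolete/unknown terms dropped
  })
  ont <- structure(
    list(id = ids,
         name = vapply(terms, `[[`, character(1), "name"),
         namespace = stats::setNames(
           vapply(terms, `[[`, character(1), "namespace"), ids),
         parents = parents,
         alt_map = alt_map,
         replaced_map = replaced_map),
    class = "go_ontology")
  ont$ancestors <- compute_ancestors(ont)
  ont$roots <- ids[vapply(parents, length, integer(1)) == 0L]
  ont
}

# Transitive closure of the parent relation, with DFS cycle detection.
compute_ancestors <- function(ont) {
  ids <- ont$id
  anc <- vector("list", length(ids))
  names(anc) <- ids
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 active, 2 done
  visit <- function(id, path) {
    if (state[[id]] == 1L)
      stop("cycle detected in ontology involving: ",
           paste(c(path[match(id, path):length(path)], id), collapse = " -> "),
           call. = FALSE)
    if (state[[id]] == 2L) return(anc[[id]])
    state[[id]] <<- 1L
    up <- character(0)
    for (p in ont$parents[[id]])
      up <- c(up, p, visit(p, c(path, id)))
    anc[[id]] <<- unique(up)
    state[[id]] <<- 2L
    anc[[id]]
  }
  for (id in ids) visit(id, character(0))
  anc
}

#' @export
print.go_ontology <- function(x, ...) {
  tab <- table(x$namespace)
  cat(sprintf("GO ontology: %d terms (%s), %d roots\n", length(x$id),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              length(x$roots)))
  invisible(x)
}

#' Resolve a term id (canonical, alternative, or replaced)
#'
#' @param ont A [load_ontology()] ontology.
#' @param term_ids Character vector of ids.
#' @return Canonical ids; `NA` for unresolvable ids.
#' @export
resolve_term <- function(ont, term_ids) {
  out <- term_ids
  is_alt <- out %in% names(ont$alt_map)
  out[is_alt] <- ont$alt_map[out[is_alt]]
  is_rep <- out %in% names(ont$replaced_map)
  out[is_rep] <- ont$replaced_map[out[is_rep]]
  out[!(out %in% ont$id)] <- NA_character_
  out
}

#' Ancestors of a term
#'
#' @param ont A [load_ontology()] ontology.
#' @param term_id A single term id.
#' @return Character vector of ancestor ids (self excluded).
#' @export
term_ancestors <- function(ont, term_id) {
  term_id <- resolve_term(ont, term_id)
  if (is.na(term_id)) return(character(0))
  ont$ancestors[[term_id]]
}

#' Annotation sets: protein -> GO term sets
#'
#' @param proteins Named list mapping protein ids to character vectors of GO
#'   term ids.
#' @param propagated Whether the sets are closed under ancestor relations.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(proteins, propagated = FALSE) {
  stopifnot(is.list(proteins), !is.null(names(proteins)))
  proteins <- lapply(proteins, function(x) unique(as.character(x)))
  structure(list(proteins = proteins, propagated = propagated),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d proteins, %d distinct terms (%s)\n",
              length(x$proteins),
              length(unique(unlist(x$proteins, use.names = FALSE))),
              if (x$propagated) "propagated" else "direct"))
  invisible(x)
}

# Experimental evidence codes in the usual CAFA sense.
experimental_evidence_codes <- function()
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC",
    "HTP", "HDA", "HMP", "HGI", "HEP")

#' Read a merged annotation table
#'
#' Tab-separated columns `protein_id`, `go_id`, `evidence`, `source`
#' (header optional; extra columns ignored). The evidence filter mirrors the
#' common conventions: `"all"` keeps everything including IEA (which has
#' been observed to help transfer-based prediction), `"no-iea"` drops IEA,
#' `"experimental"` keeps experimental/curated codes only.
#'
#' @param path Path to the TSV.
#' @param evidence `"all"`, `"no-iea"`, or `"experimental"`.
#' @return A direct [annotation_set()].
#' @export
read_annotation_tsv <- function(path, evidence = c("all", "no-iea",
                                                   "experimental")) {
  evidence <- match.arg(evidence)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (identical(tolower(df[1, 1]), "protein_id")) df <- df[-1, , drop = FALSE]
  names(df)[1:2] <- c("protein_id", "go_id")
  ev <- if (ncol(df) >= 3L) df[[3L]] else rep("IEA", nrow(df))
  df <- switch(evidence,
    all = df,
    `no-iea` = df[ev != "IEA", , drop = FALSE],
    experimental = df[ev %in% experimental_evidence_codes(), , drop = FALSE])
  annotation_set(split(df$go_id, df$protein_id))
}

#' Read a GAF 2.x annotation file
#'
#' Uses columns 2 (object id), 5 (GO id) and 7 (evidence code); `!` comment
#' lines and `NOT`-qualified rows are skipped.
#'
#' @inheritParams read_annotation_tsv
#' @export
read_gaf <- function(path, evidence = c("all", "no-iea", "experimental")) {
  evidence <- match.arg(evidence)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(parts, function(p)
    length(p) >= 7L && !grepl("NOT", p[[4L]]), logical(1))
  parts <- parts[keep]
  df <- data.frame(
    protein_id = vapply(parts, `[[`, character(1), 2L),
    go_id = vapply(parts, `[[`, character(1), 5L),
    evidence = vapply(parts, `[[`, character(1), 7L),
    stringsAsFactors = FALSE)
  ev <- df$evidence
  df <- switch(evidence,
    all = df,
    `no-iea` = df[ev != "IEA", , drop = FALSE],
    experimental = df[ev %in% experimental_evidence_codes(), , drop = FALSE])
  annotation_set(split(df$go_id, df$protein_id))
}

#' Propagate annotations to ancestor terms
#'
#' Each protein's term set is replaced by the union of its (resolvable)
#' terms and all their ancestors via `is_a`/`part_of`, namespace roots
#' excluded as uninformative. Idempotent. Unresolvable term ids are skipped
#' with one summary warning.
#'
#' @param direct An [annotation_set()].
#' @param ont A [load_ontology()] ontology.
#' @return A propagated `annotation_set`.
#' @export
propagate_annotations <- function(direct, ont) {
  stopifnot(inherits(direct, "annotation_set"), inherits(ont, "go_ontology"))
  n_skipped <- 0L
  out <- lapply(direct$proteins, function(terms) {
    res <- resolve_term(ont, terms)
    n_skipped <<- n_skipped + sum(is.na(res))
    res <- res[!is.na(res)]
    closed <- unique(c(res, unlist(ont$ancestors[res], use.names = FALSE)))
    setdiff(closed, ont$roots)
  })
  if (n_skipped > 0L)
    warning(n_skipped, " unresolvable term annotation(s) skipped")
  annotation_set(out, propagated = TRUE)
}

#' Per-term information content
#'
#' `ic(t) = -log2(n_t / N)` in bits, where `n_t` counts corpus proteins
#' annotated (after propagation) with term `t` and `N` counts corpus
#' proteins carrying at least one term in `t`'s namespace. Terms absent
#' from the corpus receive the add-one guard `-log2(1 / (N + 1))`. After
#' propagation, ic is non-increasing from child to parent.
#'
#' @param annotations A propagated [annotation_set()] serving as the corpus.
#' @param ont A [load_ontology()] ontology.
#' @return Named numeric vector of ic values over all non-root ontology
#'   terms.
#' @export
information_content <- function(annotations, ont) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(ont, "go_ontology"))
  if (!annotations$propagated)
    stop("information content requires propagated annotations", call. = FALSE)
  if (length(annotations$proteins) == 0L)
    stop("empty annotation corpus", call. = FALSE)
  terms <- setdiff(ont$id, ont$roots)
  ic <- stats::setNames(numeric(length(terms)), terms)
  for (ns in unique(ont$namespace)) {
    ns_terms <- terms[ont$namespace[terms] == ns]
    if (length(ns_terms) == 0L) next
    sets <- lapply(annotations$proteins, function(x)
      x[x %in% ns_terms])
    n_corpus <- sum(vapply(sets, length, integer(1)) > 0L)
    counts <- table(factor(unlist(sets, use.names = FALSE),
                           levels = ns_terms))
    if (n_corpus == 0L) {
      ic[ns_terms] <- 0
      next
    }
    v <- as.numeric(counts)
    icv <- ifelse(v > 0, -log2(v / n_corpus), log2(n_corpus + 1))
    ic[ns_terms] <- icv
  }
  ic
}

#' Write an ontology as OBO
#'
#' Serializes the term stanzas (id, name, namespace, is_a) in id order;
#' deterministic byte-for-byte for a fixed ontology. Used mainly to emit
#' synthetic fixtures.
#'
#' @param ont A `go_ontology`.
#' @param path File path.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in sort(ont$id)) {
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", ont$name[[id]]),
                 paste0("namespace: ", ont$namespace[[id]]),
                 if (length(ont$parents[[id]]))
                   paste0("is_a: ", sort(ont$parents[[id]])),
                 ""), con)
  }
  invisible(path)
}

#' Write an annotation set as a merged TSV
#'
#' Columns `protein_id`, `go_id`, `evidence`, `source` with header.
#'
#' @param annotations An [annotation_set()].
#' @param path File path.
#' @param evidence,source Values written for every row (fixtures are
#'   synthetic, so a single code applies).
#' @export
write_annotation_tsv <- function(annotations, path, evidence = "IEA",
                                 source = "synthetic") {
  rows <- lapply(sort(names(annotations$proteins)), function(p) {
    terms <- sort(annotations$proteins[[p]])
    if (length(terms) == 0L) return(NULL)
    data.frame(protein_id = p, go_id = terms, evidence = evidence,
               source = source, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
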