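#' Pipeline run configuration
#'
#' Defaults follow the best-performing configuration of the method: 12 A
#' contact cutoff, contact probability threshold 0.5, and top-2 hit
#' selection.
#'
#' @param cutoff Contact cutoff in Angstrom (default 12).
#' @param prob_threshold Distogram contact probability threshold (default
#'   0.5).
#' @param policy A [selection_policy()] (default top-2).
#' @param min_separation Minimum sequence separation (default 2).
#' @param evidence Annotation evidence filter for loading (`"all"`,
#'   `"no-iea"`, `"experimental"`).
#' @param namespace Evaluation namespace (`"all"`, `"mf"`, `"bp"`, `"cc"`).
#' @param propagate_before_scoring Propagate hit annotations to ancestors
#'   before scoring (default FALSE: transfer direct annotations).
#' @param seed Seed recorded in the run manifest.
#' @return A `run_config`.
#' @export
run_config <- function(cutoff = 12, prob_threshold = 0.5,
                       policy = selection_policy("top_n", 2),
                       min_separation = 2L,
                       evidence = "all", namespace = "all",
                       propagate_before_scoring = FALSE, seed = 1L) {
  structure(list(cutoff = cutoff, prob_threshold = prob_threshold,
                 policy = policy, min_separation = min_separation,
                 evidence = evidence, namespace = namespace,
                 propagate_before_scoring = propagate_before_scoring,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full annotation-transfer pipeline
#'
#' For each query (a contact graph, or a distogram converted using the
#' configured cutoff and probability threshold): search the reference
#' database, select hits per the configured policy (after removing any
#' per-query exclusions), score GO terms by summed hit similarity, and
#' top-score normalize. A failing query is reported and skipped; the run
#' errors only if every query fails.
#'
#' @param queries Named list of [contact_graph()] or [distogram()] objects.
#' @param db A [build_reference_db()] database.
#' @param annotations An [annotation_set()] for the database entries.
#' @param ontology Optional [load_ontology()] ontology (required when
#'   `propagate_before_scoring` is TRUE).
#' @param config A [run_config()].
#' @param exclusions Named list (by query id) of reference-id character
#'   vectors to exclude before hit selection; queries are additionally
#'   always excluded from their own hit lists by id.
#' @param out_dir Optional directory; when given, one CAFA-style prediction
#'   TSV per query plus a JSON run manifest are written.
#' @return Named list of normalized [go_prediction()] objects, with the run
#'   manifest attached as attribute `"manifest"`.
#' @export
run_pipeline <- function(queries, db, annotations, ontology = NULL,
                         config = run_config(), exclusions = list(),
                         out_dir = NULL) {
  stopifnot(inherits(db, "reference_db"),
            inherits(annotations, "annotation_set"),
            inherits(config, "run_config"))
  if (config$propagate_before_scoring) {
    if (is.null(ontology))
      stop("propagate_before_scoring requires an ontology", call. = FALSE)
    annotations <- propagate_annotations(annotations, ontology)
  }
  if (is.null(names(queries)))
    names(queries) <- vapply(queries, `[[`, character(1), "protein_id")
  predictions <- list()
  failures <- character(0)
  timings <- numeric(0)
  for (qid in names(queries)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      q <- queries[[qid]]
      if (inherits(q, "distogram"))
        q <- contacts_from_distogram(q, config$cutoff,
                                     config$prob_threshold,
                                     config$min_separation)
      hits <- search_reference_db(q, db)
      excl <- unique(c(qid, q$protein_id, exclusions[[qid]]))
      sel <- select_hits(hits, config$policy, exclusions = excl)
      normalize_prediction(score_go_terms(sel, annotations))
    }, error = function(e) e)
    timings[[qid]] <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      warning("query '", qid, "' failed: ", conditionMessage(res))
      failures <- c(failures, qid)
    } else {
      predictions[[qid]] <- res
    }
  }
  if (length(predictions) == 0L)
    stop("all ", length(queries), " queries failed", call. = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("contactGO")),
    config = config[setdiff(names(config), "policy")],
    policy = unclass(config$policy),
    n_queries = length(queries),
    n_failed = length(failures),
    failed = failures,
    db_entries = length(db$entries),
    timings_sec = as.list(round(timings, 4)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (qid in names(predictions))
      write_prediction(predictions[[qid]],
                       file.path(out_dir, paste0(qid, ".pred.tsv")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  attr(predictions, "manifest") <- manifest
  predictions
}
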