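#' Specification for synthetic fixtures
#'
#' Controls the seeded generator that emulates every input of the pipeline:
#' contact graphs with helix-like (`"band"`), sheet-like
#' (`"antidiagonal"`) or random topology, distograms concentrated
#' below/above a cutoff, a small GO-style ontology, and family-structured
#' annotations so that function transfer from structural neighbours is
#' learnable. One global seed fans out to per-component streams, so outputs
#' are reproducible bit-for-bit.
#'
#' @param seed Global integer seed.
#' @param length_range Inclusive residue-count range proteins are drawn
#'   from.
#' @param topology `"band"`, `"antidiagonal"` or `"random"`.
#' @param band_width Band half-width for the structured topologies.
#' @param density Edge density over eligible pair slots for `"random"`.
#' @param perturbation Default edge-flip rate for derived copies, in [0, 1].
#' @param min_separation Minimum sequence separation of generated edges.
#' @param cutoff Contact cutoff (A) recorded on generated graphs and used
#'   when building distograms.
#' @param terms_per_namespace,depth Ontology size and depth per namespace.
#' @param annotations_per_protein Direct GO terms per protein and namespace
#'   family signature.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           length_range = c(40L, 60L),
                           topology = c("random", "band", "antidiagonal"),
                           band_width = 4L,
                           density = 0.1,
                           perturbation = 0.02,
                           min_separation = 2L,
                           cutoff = 12,
                           terms_per_namespace = 20L,
                           depth = 3L,
                           annotations_per_protein = 3L) {
  topology <- match.arg(topology)
  stopifnot(perturbation >= 0, perturbation <= 1, density > 0, density <= 1,
            length_range[1L] >= 3L, depth >= 1L, terms_per_namespace >= 2L)
  structure(list(seed = as.integer(seed), length_range = length_range,
                 topology = topology, band_width = as.integer(band_width),
                 density = density, perturbation = perturbation,
                 min_separation = as.integer(min_separation),
                 cutoff = cutoff,
                 terms_per_namespace = as.integer(terms_per_namespace),
                 depth = as.integer(depth),
                 annotations_per_protein = as.integer(annotations_per_protein)),
            class = "synthetic_spec")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fan one global seed out into independent per-component streams
# (kept below 2^31 - 1).
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) * 10007 + stream) %% 2147483646
  as.integer(s) + 1L
}

# All residue pairs i < j with j - i >= min_separation.
eligible_pairs <- function(L, min_separation) {
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] >= min_separation, , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Generate a synthetic contact graph
#'
#' Band topology connects residues `min_separation <= j - i <= band_width`
#' (helix-like near-diagonal contacts); antidiagonal topology connects pairs
#' near the antidiagonal `i + j = L + 1` (sheet-like); random topology
#' fills eligible slots independently with probability `density`.
#'
#' @param spec A [synthetic_spec()].
#' @param protein_id Identifier for the graph.
#' @param length Residue count; default drawn from `spec$length_range`.
#' @param seed Stream seed; defaults to `spec$seed`.
#' @return A [contact_graph()].
#' @export
generate_contact_graph <- function(spec, protein_id = "synthetic",
                                   length = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    L <- if (is.null(length)) {
      rng <- spec$length_range
      rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, 1L) - 1L
    } else as.integer(length)
    if (L < 3L) stop("synthetic graphs need length >= 3", call. = FALSE)
    slots <- eligible_pairs(L, spec$min_separation)
    keep <- switch(spec$topology,
      band = (slots[, 2L] - slots[, 1L]) <= spec$band_width,
      antidiagonal = abs(slots[, 1L] + slots[, 2L] - (L + 1L)) <=
        spec$band_width,
      random = stats::runif(nrow(slots)) < spec$density)
    contact_graph(protein_id, L, slots[keep, , drop = FALSE], spec$cutoff,
                  spec$min_separation)
  })
}

#' Randomly flip contact slots of a graph
#'
#' Every eligible pair slot (respecting the graph's minimum separation) is
#' flipped independently with probability `rate`: present edges are removed
#' and absent ones added. `rate = 0` returns an identical graph; `rate = 1`
#' the complement within eligible slots.
#'
#' @param g A [contact_graph()].
#' @param rate Flip probability in [0, 1].
#' @param seed Integer seed.
#' @return A perturbed [contact_graph()].
#' @export
perturb_graph <- function(g, rate, seed) {
  stopifnot(inherits(g, "contact_graph"), rate >= 0, rate <= 1)
  with_seed(seed, {
    slots <- eligible_pairs(g$length, g$min_separation)
    flip <- stats::runif(nrow(slots)) < rate
    keys <- paste(slots[, 1L], slots[, 2L])
    present <- keys %in% edge_keys(g)
    keep <- xor(present, flip)
    contact_graph(g$protein_id, g$length, slots[keep, , drop = FALSE],
                  g$cutoff, g$min_separation)
  })
}

#' Build a distogram concentrated around a graph's contacts
#'
#' Residue pairs that are edges of `g` receive total probability
#' `contact_prob` spread uniformly over the bins at or below `cutoff`, the
#' remainder spread over the bins above; non-edges the converse with
#' `noncontact_prob`. Converting back with [contacts_from_distogram()] at a
#' threshold between `noncontact_prob` and `contact_prob` (inclusive)
#' recovers `g` exactly.
#'
#' @param g A [contact_graph()].
#' @param cutoff Cutoff (A) the contact mass is placed below; must be a bin
#'   edge. Defaults to the graph's cutoff.
#' @param contact_prob Probability mass below the cutoff for contact pairs
#'   (default 0.9).
#' @param noncontact_prob Same for non-contact pairs (default 0.1).
#' @param bin_edges Distance bin edges; default [trrosetta_bins()].
#' @return A [distogram()].
#' @export
generate_distogram <- function(g, cutoff = g$cutoff, contact_prob = 0.9,
                               noncontact_prob = 0.1,
                               bin_edges = trrosetta_bins()) {
  stopifnot(inherits(g, "contact_graph"))
  if (contact_prob < 0 || contact_prob > 1 ||
      noncontact_prob < 0 || noncontact_prob > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  k <- match_bin_edge(bin_edges, cutoff)
  n_below <- k - 1L
  n_total <- length(bin_edges) - 1L + 1L
  n_above <- n_total - n_below
  if (n_below == 0L)
    stop("cutoff leaves no bins for the contact mass", call. = FALSE)
  slice <- function(p_close) c(rep(p_close / n_below, n_below),
                               rep((1 - p_close) / n_above, n_above))
  L <- g$length
  probs <- array(rep(slice(noncontact_prob), each = L * L), c(L, L, n_total))
  if (nrow(g$edges)) {
    cs <- slice(contact_prob)
    for (b in seq_len(n_total)) {
      layer <- probs[, , b]
      layer[g$edges] <- cs[[b]]
      layer[g$edges[, c(2L, 1L), drop = FALSE]] <- cs[[b]]
      probs[, , b] <- layer
    }
  }
  distogram(g$protein_id, probs, bin_edges)
}

#' Generate a synthetic ontology and family-structured annotations
#'
#' Builds one rooted `is_a` DAG per GO namespace (`depth` levels below the
#' root, single root each) with synthetic term ids, then assigns each
#' protein the leaf-biased term signature of its family: proteins of the
#' same family share their direct terms by construction, so annotation
#' transfer between structurally similar (same-family) proteins is
#' learnable, while different families overlap only by chance.
#'
#' @param spec A [synthetic_spec()].
#' @param family_of Named character vector mapping protein ids to family
#'   labels.
#' @return List with `ontology` (a `go_ontology`) and `annotations` (a
#'   direct [annotation_set()]).
#' @export
generate_ontology_and_annotations <- function(spec, family_of) {
  stopifnot(inherits(spec, "synthetic_spec"), !is.null(names(family_of)))
  namespaces <- c("molecular_function", "biological_process",
                  "cellular_component")
  ont <- with_seed(derive_seed(spec$seed, 101L), {
    ids <- character(0); names_ <- character(0); ns_ <- character(0)
    parents <- list()
    counter <- 0L
    for (ni in seq_along(namespaces)) {
      ns <- namespaces[[ni]]
      n_terms <- spec$terms_per_namespace
      level_sizes <- term_levels(n_terms, spec$depth)
      prev_level <- character(0)
      for (lev in seq_along(level_sizes)) {
        level_ids <- character(0)
        for (m in seq_len(level_sizes[[lev]])) {
          counter <- counter + 1L
          id <- sprintf("GO:%07d", 9000000L + counter)
          ids <- c(ids, id); ns_ <- c(ns_, ns)
          names_ <- c(names_, sprintf("synthetic %s term %d", ns, counter))
          parents[[id]] <- if (lev == 1L) character(0) else
            unique(sample(prev_level, min(length(prev_level),
                                          sample(1:2, 1L)), replace = FALSE))
          level_ids <- c(level_ids, id)
        }
        prev_level <- level_ids
      }
    }
    o <- structure(list(id = ids,
                        name = stats::setNames(names_, ids),
                        namespace = stats::setNames(ns_, ids),
                        parents = parents,
                        alt_map = character(0),
                        replaced_map = character(0)),
                   class = "go_ontology")
    o$ancestors <- compute_ancestors(o)
    o$roots <- ids[vapply(parents, length, integer(1)) == 0L]
    o
  })
  # leaf-biased family signatures: deeper terms are more likely to be drawn
  depth_of <- vapply(ont$ancestors, length, integer(1))
  candidates <- setdiff(ont$id, ont$roots)
  weights <- (depth_of[candidates] + 1)^2
  annotations <- with_seed(derive_seed(spec$seed, 102L), {
    fams <- unique(family_of)
    fam_terms <- lapply(seq_along(fams), function(i)
      sample(candidates, min(spec$annotations_per_protein,
                             length(candidates)),
             prob = weights))
    names(fam_terms) <- fams
    sets <- lapply(names(family_of), function(p) {
      base <- fam_terms[[family_of[[p]]]]
      extra <- if (stats::runif(1) < 0.3) sample(candidates, 1L) else NULL
      unique(c(base, extra))
    })
    names(sets) <- names(family_of)
    annotation_set(sets)
  })
  list(ontology = ont, annotations = annotations)
}

# Split n terms below the root into `depth` levels of growing size.
term_levels <- function(n_terms, depth) {
  n_below <- n_terms - 1L
  w <- seq_len(depth)
  sizes <- pmax(1L, round(n_below * w / sum(w)))
  sizes[depth] <- max(1L, n_below - sum(sizes[-depth]))
  c(1L, sizes)   # root level first
}

#' Generate a full synthetic benchmark
#'
#' Builds `n_families` structural families: a random template graph per
#' family, `members_per_family` database members perturbed from the template
#' at `member_perturbation`, and one query per family perturbed at the
#' spec's `perturbation` rate. All proteins of a family share their direct
#' GO terms (see [generate_ontology_and_annotations()]).
#'
#' @param spec A [synthetic_spec()].
#' @param n_families Number of template families (default 30).
#' @param members_per_family Database members per family (default 2).
#' @param member_perturbation Edge-flip rate of database members relative to
#'   their template (default 0.05).
#' @return List with `db_graphs`, `query_graphs`, `family_of` (covering
#'   members and queries), `ontology`, `annotations` (direct, database
#'   members), `truth` (direct, queries).
#' @export
generate_benchmark <- function(spec, n_families = 30L,
                               members_per_family = 2L,
                               member_perturbation = 0.05) {
  stopifnot(inherits(spec, "synthetic_spec"))
  db_graphs <- list(); query_graphs <- list(); family_of <- character(0)
  for (f in seq_len(n_families)) {
    fam <- sprintf("FAM%03d", f)
    template <- generate_contact_graph(
      spec, protein_id = fam, seed = derive_seed(spec$seed, 1000L + f))
    for (m in seq_len(members_per_family)) {
      id <- sprintf("%sM%d_SYN", fam, m)
      g <- perturb_graph(template, member_perturbation,
                         derive_seed(spec$seed, 2000L + f * 10L + m))
      g$protein_id <- id
      db_graphs[[id]] <- g
      family_of[[id]] <- fam
    }
    qid <- sprintf("%sQ_SYN", fam)
    q <- perturb_graph(template, spec$perturbation,
                       derive_seed(spec$seed, 3000L + f))
    q$protein_id <- qid
    query_graphs[[qid]] <- q
    family_of[[qid]] <- fam
  }
  oa <- generate_ontology_and_annotations(spec, family_of)
  member_ids <- names(db_graphs)
  query_ids <- names(query_graphs)
  list(db_graphs = db_graphs,
       query_graphs = query_graphs,
       family_of = family_of,
       ontology = oa$ontology,
       annotations = annotation_set(oa$annotations$proteins[member_ids]),
       truth = annotation_set(oa$annotations$proteins[query_ids]))
}

#' Write a complete fixture directory
#'
#' Emits, under `out_dir`: one edge-list and one CASP-RR file per database
#' member (`graphs/`), one distogram per query (`distograms/`), the
#' ontology (`ontology.obo`), the database annotations
#' (`annotations.tsv`) and the query truth (`truth.tsv`).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed (default 7).
#' @param n_families Number of families (default 30).
#' @param spec Optional [synthetic_spec()]; defaults to
#'   `synthetic_spec(seed = seed)`.
#' @return The benchmark list from [generate_benchmark()], invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 7L, n_families = 30L,
                          spec = synthetic_spec(seed = seed)) {
  bench <- generate_benchmark(spec, n_families = n_families)
  gdir <- file.path(out_dir, "graphs")
  ddir <- file.path(out_dir, "distograms")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(bench$db_graphs)) {
    write_contact_graph(bench$db_graphs[[id]],
                        file.path(gdir, paste0(id, ".edges")))
    write_casp_rr(bench$db_graphs[[id]],
                  file.path(gdir, paste0(id, ".rr")))
  }
  for (id in names(bench$query_graphs))
    write_distogram(generate_distogram(bench$query_graphs[[id]]),
                    file.path(ddir, paste0(id, ".distogram")))
  write_obo(bench$ontology, file.path(out_dir, "ontology.obo"))
  write_annotation_tsv(bench$annotations, file.path(out_dir, "annotations.tsv"))
  write_annotation_tsv(bench$truth, file.path(out_dir, "truth.tsv"))
  invisible(bench)
}
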