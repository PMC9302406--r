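#' Contact graph of a protein
#'
#' A contact graph has one node per residue (1-based sequence order) and an
#' undirected edge for every residue pair whose representative atoms (C-beta;
#' C-alpha for glycine) lie within a distance cutoff. Edges are stored
#' canonically as a two-column integer matrix with `i < j`, sorted by `(i, j)`.
#'
#' @param protein_id Identifier of the protein.
#' @param length Number of residues `L` (nodes), `>= 1`.
#' @param edges Two-column integer matrix (or 2-column data frame) of residue
#'   index pairs; order within a pair is irrelevant. May have zero rows.
#' @param cutoff Distance cutoff in Angstrom that defines a contact
#'   (typically 8, 10 or 12).
#' @param min_separation Minimum sequence separation `|i - j|` an edge must
#'   satisfy. Defaults to 2, which excludes trivially adjacent residues.
#' @return An object of class `contact_graph`.
#' @examples
#' g <- contact_graph("toy", 5, rbind(c(1, 3), c(2, 5)), cutoff = 8)
#' g
#' @export
contact_graph <- function(protein_id, length, edges, cutoff,
                          min_separation = 2L) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("contact graph needs at least one residue (L >= 1)", call. = FALSE)
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("cutoff must be a positive distance in Angstrom", call. = FALSE)
  edges <- canonical_edges(edges, length, min_separation)
  structure(
    list(protein_id = as.character(protein_id),
         length = length,
         cutoff = as.numeric(cutoff),
         min_separation = as.integer(min_separation),
         edges = edges),
    class = "contact_graph")
}

# Canonicalize an edge matrix: i < j, unique, sorted, validated.
canonical_edges <- function(edges, length, min_separation) {
  if (is.null(edges) || NROW(edges) == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L)
    stop("edges must have two columns (i, j)", call. = FALSE)
  storage.mode(edges) <- "integer"
  i <- pmin(edges[, 1L], edges[, 2L])
  j <- pmax(edges[, 1L], edges[, 2L])
  if (anyNA(i) || anyNA(j))
    stop("edges contain missing indices", call. = FALSE)
  if (any(i < 1L) || any(j > length))
    stop("edge indices must lie in [1, L]", call. = FALSE)
  if (any(i == j))
    stop("self-edges are not allowed", call. = FALSE)
  if (any(j - i < min_separation))
    stop("edges violate the minimum sequence separation of ",
         min_separation, call. = FALSE)
  keep <- !duplicated(cbind(i, j))
  i <- i[keep]; j <- j[keep]
  ord <- order(i, j)
  matrix(c(i[ord], j[ord]), ncol = 2L,
         dimnames = list(NULL, c("i", "j")))
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("Contact graph '%s': %d residues, %d contacts (cutoff %g A, min separation %d)\n",
              x$protein_id, x$length, nrow(x$edges), x$cutoff,
              x$min_separation))
  invisible(x)
}

#' @export
format.contact_graph <- function(x, ...) {
  sprintf("<contact_graph %s: L=%d, |E|=%d, cutoff=%g>",
          x$protein_id, x$length, nrow(x$edges), x$cutoff)
}

#' Edge set of a contact graph as "i j" character keys
#'
#' Convenience accessor for set arithmetic on edge sets.
#'
#' @param g A [contact_graph()].
#' @return Character vector, one `"i j"` key per edge.
#' @export
edge_keys <- function(g) {
  if (nrow(g$edges) == 0L) return(character(0))
  paste(g$edges[, 1L], g$edges[, 2L])
}

# Dense symmetric logical adjacency matrix (small graphs only).
adjacency_matrix <- function(g) {
  a <- matrix(FALSE, g$length, g$length)
  if (nrow(g$edges)) {
    a[g$edges] <- TRUE
    a[g$edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  a
}

#' Build a contact graph from residue coordinates
#'
#' One representative 3D point per residue (conventionally the C-beta atom,
#' C-alpha for glycine). Residues with missing coordinates (`NA` rows)
#' contribute no edges.
#'
#' @param coords Numeric matrix with `L` rows and 3 columns (x, y, z); rows of
#'   `NA` mark unresolved residues.
#' @param cutoff Contact distance cutoff in Angstrom.
#' @param min_separation Minimum sequence separation (default 2).
#' @param protein_id Identifier for the resulting graph.
#' @return A [contact_graph()].
#' @examples
#' xyz <- cbind(c(0, 6, 12, 18), 0, 0)
#' contacts_from_coordinates(xyz, cutoff = 12, protein_id = "line")
#' @export
contacts_from_coordinates <- function(coords, cutoff, min_separation = 2L,
                                      protein_id = "query") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must be an L x 3 matrix", call. = FALSE)
  L <- nrow(coords)
  resolved <- stats::complete.cases(coords)
  if (sum(resolved) < 2L)
    stop("degenerate input: fewer than 2 residues with coordinates",
         call. = FALSE)
  if (any(!resolved))
    warning(sum(!resolved), " residue(s) without coordinates excluded from edge formation")
  idx <- which(resolved)
  d <- as.matrix(stats::dist(coords[idx, , drop = FALSE]))
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  i <- idx[sel[, 1L]]
  j <- idx[sel[, 2L]]
  keep <- abs(j - i) >= min_separation
  contact_graph(protein_id, L, cbind(i[keep], j[keep]), cutoff,
                min_separation)
}

#' Build a contact graph from a PDB or mmCIF structure file
#'
#' Extracts one representative atom per residue (C-beta, falling back to
#' C-alpha for glycine and for residues without a C-beta) via the bio3d
#' package, then applies [contacts_from_coordinates()].
#'
#' @param file Path to a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param cutoff,min_separation See [contacts_from_coordinates()].
#' @param chain Optional chain identifier; default uses the first chain.
#' @param protein_id Identifier; defaults to the file name.
#' @return A [contact_graph()].
#' @export
contacts_from_pdb <- function(file, cutoff, min_separation = 2L,
                              chain = NULL, protein_id = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading structure files requires the 'bio3d' package", call. = FALSE)
  pdb <- if (grepl("\\.cif$", file, ignore.case = TRUE))
    bio3d::read.cif(file) else bio3d::read.pdb(file)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- atoms$chain[1L]
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no atoms found for chain ", chain, call. = FALSE)
  res <- unique(atoms$resno)
  res <- sort(res)
  coords <- matrix(NA_real_, length(res), 3L)
  for (k in seq_along(res)) {
    a <- atoms[atoms$resno == res[k], , drop = FALSE]
    pick <- if (any(a$elety == "CB")) which(a$elety == "CB")[1L]
            else if (any(a$elety == "CA")) which(a$elety == "CA")[1L]
            else NA_integer_
    if (!is.na(pick))
      coords[k, ] <- as.numeric(a[pick, c("x", "y", "z")])
  }
  if (is.null(protein_id)) protein_id <- sub("\\.(pdb|cif)$", "", basename(file))
  contacts_from_coordinates(coords, cutoff, min_separation, protein_id)
}

#' Write and read plain edge-list graph files
#'
#' The format is one header line `protein_id<TAB>L<TAB>cutoff` followed by one
#' `i j` residue pair per line.
#'
#' @param g A [contact_graph()].
#' @param path File path.
#' @return `write_contact_graph` returns `path` invisibly;
#'   `read_contact_graph` returns a [contact_graph()].
#' @export
write_contact_graph <- function(g, path) {
  stopifnot(inherits(g, "contact_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(g$protein_id, g$length, g$cutoff, sep = "\t"), con)
  if (nrow(g$edges))
    writeLines(paste(g$edges[, 1L], g$edges[, 2L]), con)
  invisible(path)
}

#' @param min_separation Separation recorded on the graph read back (edges in
#'   the file are taken as-is and must satisfy it).
#' @rdname write_contact_graph
#' @export
read_contact_graph <- function(path, min_separation = 2L) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty graph file: ", path, call. = FALSE)
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) != 3L)
    stop("malformed header in ", path,
         " (expected protein_id<TAB>L<TAB>cutoff)", call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  edges <- if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "[ \t]+"))
    cbind(as.integer(parts[, 1L]), as.integer(parts[, 2L]))
  } else NULL
  contact_graph(hdr[[1L]], as.integer(hdr[[2L]]), edges,
                as.numeric(hdr[[3L]]), min_separation)
}

#' Read a CASP-RR residue contact file
#'
#' Contact rows are `i j d_low d_high probability`; header lines (`PFRMAT`,
#' `TARGET`, `MODEL`, sequence lines, `END`) are skipped. Pairs whose
#' probability is at least `prob_threshold` and whose sequence separation is
#' at least `min_separation` become edges.
#'
#' @param path Path to the RR file.
#' @param length Residue count of the protein (RR files do not state it
#'   reliably); required.
#' @param prob_threshold Minimum contact probability, default 0.5.
#' @param min_separation Minimum sequence separation, default 2.
#' @param cutoff Cutoff recorded on the graph; defaults to the maximum
#'   `d_high` present in the file.
#' @param protein_id Identifier; defaults to the `TARGET` header or file name.
#' @return A [contact_graph()].
#' @export
read_casp_rr <- function(path, length, prob_threshold = 0.5,
                         min_separation = 2L, cutoff = NULL,
                         protein_id = NULL) {
  lines <- readLines(path)
  target <- sub("^TARGET\\s+", "", grep("^TARGET\\s", lines, value = TRUE)[1L])
  data_lines <- grep("^\\s*\\d+\\s+\\d+\\s", lines, value = TRUE)
  if (length(data_lines) == 0L)
    stop("no contact records found in ", path, call. = FALSE)
  parts <- do.call(rbind, strsplit(trimws(data_lines), "\\s+"))
  if (ncol(parts) < 5L)
    stop("RR records must have 5 fields: i j d_low d_high probability",
         call. = FALSE)
  i <- as.integer(parts[, 1L]); j <- as.integer(parts[, 2L])
  d_high <- as.numeric(parts[, 4L]); p <- as.numeric(parts[, 5L])
  if (is.null(cutoff)) cutoff <- max(d_high)
  keep <- p >= prob_threshold & abs(j - i) >= min_separation
  if (is.null(protein_id))
    protein_id <- if (!is.na(target)) target else
      sub("\\.rr$", "", basename(path))
  contact_graph(protein_id, length, cbind(i[keep], j[keep]), cutoff,
                min_separation)
}

#' Write a contact graph as a CASP-RR file
#'
#' Each edge is written as `i j 0 <cutoff> 1.00`; used chiefly by the
#' synthetic fixture generator.
#'
#' @inheritParams write_contact_graph
#' @export
write_casp_rr <- function(g, path) {
  stopifnot(inherits(g, "contact_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("PFRMAT RR", paste("TARGET", g$protein_id)), con)
  if (nrow(g$edges))
    writeLines(sprintf("%d %d 0 %g 1.00", g$edges[, 1L], g$edges[, 2L],
                       g$cutoff), con)
  writeLines("END", con)
  invisible(path)
}
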