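#' Binned residue-residue distance probability map (distogram)
#'
#' Distograms are the raw output of modern structure predictors: for every
#' residue pair, a probability distribution over binned C-beta distances.
#' The default binning follows the trRosetta convention: 0.5-Angstrom bins
#' spanning 2-20 A (36 closed bins) plus one open "no contact" bin (> 20 A),
#' stored as the last slice of the probability array.
#'
#' @param protein_id Identifier.
#' @param probabilities Numeric array `L x L x B` where `B` equals
#'   `length(bin_edges) - 1 + 1`: one slice per closed bin
#'   `[bin_edges[k], bin_edges[k + 1])` followed by the open bin.
#' @param bin_edges Ascending distances in Angstrom delimiting the closed
#'   bins; default `seq(2, 20, by = 0.5)`.
#' @param check Validate symmetry and per-pair normalization (default TRUE).
#' @return An object of class `distogram`.
#' @export
distogram <- function(protein_id, probabilities,
                      bin_edges = trrosetta_bins(), check = TRUE) {
  dm <- dim(probabilities)
  if (length(dm) != 3L || dm[1L] != dm[2L])
    stop("probabilities must be an L x L x B array", call. = FALSE)
  L <- dm[1L]
  if (L < 1L) stop("distogram needs L >= 1", call. = FALSE)
  nbins <- length(bin_edges) - 1L + 1L  # closed bins + open "no contact" bin
  if (dm[3L] != nbins)
    stop("expected ", nbins, " probability slices (",
         length(bin_edges) - 1L, " closed bins + 1 open bin), got ", dm[3L],
         call. = FALSE)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly ascending", call. = FALSE)
  if (check) {
    if (any(probabilities < -1e-12))
      stop("negative bin probabilities", call. = FALSE)
    sums <- apply(probabilities, c(1L, 2L), sum)
    if (max(abs(sums - 1)) > 1e-4)
      stop("per-pair bin probabilities must sum to 1 (tolerance 1e-4)",
           call. = FALSE)
    asym <- max(abs(probabilities - aperm(probabilities, c(2L, 1L, 3L))))
    if (asym > 1e-6)
      stop("probabilities are asymmetric beyond tolerance (max deviation ",
           signif(asym, 3), ")", call. = FALSE)
  }
  structure(
    list(protein_id = as.character(protein_id),
         length = L,
         bin_edges = as.numeric(bin_edges),
         probabilities = probabilities),
    class = "distogram")
}

#' @rdname distogram
#' @export
trrosetta_bins <- function() seq(2, 20, by = 0.5)

#' @export
print.distogram <- function(x, ...) {
  cat(sprintf("Distogram '%s': %d residues, %d bins (%g-%g A + open bin)\n",
              x$protein_id, x$length, length(x$bin_edges),
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Convert a distogram to a contact graph
#'
#' A residue pair is declared in contact when the probability that its
#' distance is at or below the cutoff -- the summed mass of all bins whose
#' upper edge is `<= cutoff` -- reaches `prob_threshold`. The default
#' threshold of 0.5 declares a contact when the pair is at least as likely
#' as not to be within the cutoff.
#'
#' @param map A [distogram()].
#' @param cutoff Contact cutoff in Angstrom; must coincide with one of the
#'   distogram's bin edges.
#' @param prob_threshold Probability threshold in (0, 1]; the comparison is
#'   inclusive (`>=`). Default 0.5.
#' @param min_separation Minimum sequence separation, default 2.
#' @return A [contact_graph()].
#' @examples
#' g <- generate_contact_graph(synthetic_spec(seed = 1, length_range = c(30, 30)))
#' d <- generate_distogram(g, cutoff = 12)
#' identical(edge_keys(contacts_from_distogram(d, 12)), edge_keys(g))
#' @export
contacts_from_distogram <- function(map, cutoff, prob_threshold = 0.5,
                                    min_separation = 2L) {
  stopifnot(inherits(map, "distogram"))
  if (!is.numeric(prob_threshold) || prob_threshold <= 0 || prob_threshold > 1)
    stop("prob_threshold must lie in (0, 1]", call. = FALSE)
  k <- match_bin_edge(map$bin_edges, cutoff)
  # mass of all closed bins with upper edge <= cutoff: slices 1..(k-1)
  L <- map$length
  p_contact <- if (k == 1L) matrix(0, L, L) else
    contact_probability(map, cutoff)
  # inclusive threshold with a small numerical guard so that bin masses
  # summing to the threshold (e.g. exactly 0.5) are kept
  sel <- which(upper.tri(p_contact) & p_contact >= prob_threshold - 1e-9,
               arr.ind = TRUE)
  keep <- (sel[, 2L] - sel[, 1L]) >= min_separation
  contact_graph(map$protein_id, L, sel[keep, , drop = FALSE], cutoff,
                min_separation)
}

#' @rdname contacts_from_distogram
#' @return `contact_probability` returns the `L x L` matrix of
#'   `P(distance <= cutoff)`.
#' @export
contact_probability <- function(map, cutoff) {
  stopifnot(inherits(map, "distogram"))
  k <- match_bin_edge(map$bin_edges, cutoff)
  if (k == 1L) return(matrix(0, map$length, map$length))
  slices <- seq_len(k - 1L)
  apply(map$probabilities[, , slices, drop = FALSE], c(1L, 2L), sum)
}

# Index of `cutoff` within bin_edges, with an informative configuration
# error naming the nearest edges when it falls between bins.
match_bin_edge <- function(bin_edges, cutoff) {
  k <- which(abs(bin_edges - cutoff) < 1e-9)
  if (length(k) != 1L) {
    below <- suppressWarnings(max(bin_edges[bin_edges < cutoff]))
    above <- suppressWarnings(min(bin_edges[bin_edges > cutoff]))
    stop("configuration error: cutoff ", cutoff,
         " A does not coincide with a distogram bin edge (nearest edges: ",
         below, " and ", above, ")", call. = FALSE)
  }
  k
}

#' Write and read distograms as plain text
#'
#' Long-format TSV: a `# protein_id L` header, a `# bins e1,e2,...` header,
#' then one row `i j b probability` per upper-triangle pair and bin with
#' nonzero mass (the symmetric lower triangle is implied).
#'
#' @param map A [distogram()].
#' @param path File path.
#' @export
write_distogram <- function(map, path) {
  stopifnot(inherits(map, "distogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#", map$protein_id, map$length),
               paste0("# bins ", paste(map$bin_edges, collapse = ","))), con)
  L <- map$length
  B <- dim(map$probabilities)[3L]
  for (i in seq_len(L)) for (j in i:L) {
    p <- map$probabilities[i, j, ]
    nz <- which(p > 0)
    if (length(nz))
      writeLines(sprintf("%d\t%d\t%d\t%.10g", i, j, nz, p[nz]), con)
  }
  invisible(path)
}

#' @rdname write_distogram
#' @export
read_distogram <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[[1L]]), " ")[[1L]]
  protein_id <- hdr[[1L]]
  L <- as.integer(hdr[[2L]])
  bins <- as.numeric(strsplit(sub("^# bins ", "", lines[[2L]]), ",")[[1L]])
  body <- lines[-(1:2)]
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  i <- as.integer(parts[, 1L]); j <- as.integer(parts[, 2L])
  b <- as.integer(parts[, 3L]); p <- as.numeric(parts[, 4L])
  B <- length(bins) - 1L + 1L
  probs <- array(0, c(L, L, B))
  probs[cbind(i, j, b)] <- p
  probs[cbind(j, i, b)] <- p
  distogram(protein_id, probs, bins)
}
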