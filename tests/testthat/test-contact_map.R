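# Distogram-to-graph conversion, coordinate-based graphs, precision metrics,
# and the plain-text graph formats.

# Distogram with a given P(d <= cutoff) on selected pairs: the close mass
# sits in the first bin, the remainder in the open bin.
make_distogram <- function(L, pairs, p_close, id = "toy") {
  bins <- trrosetta_bins()
  B <- length(bins) - 1L + 1L
  probs <- array(0, c(L, L, B))
  probs[, , B] <- 1
  if (NROW(pairs)) for (r in seq_len(NROW(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]; p <- p_close[min(r, length(p_close))]
    probs[i, j, 1L] <- p; probs[j, i, 1L] <- p
    probs[i, j, B] <- 1 - p; probs[j, i, B] <- 1 - p
  }
  distogram(id, probs, bins)
}

random_distogram <- function(L, seed) {
  set.seed(seed)
  bins <- trrosetta_bins()
  B <- length(bins) - 1L + 1L
  probs <- array(0, c(L, L, B))
  for (i in seq_len(L)) for (j in i:L) {
    v <- stats::runif(B)
    v <- v / sum(v)
    probs[i, j, ] <- v
    probs[j, i, ] <- v
  }
  distogram("rnd", probs, bins)
}

test_that("contact declaration thresholds the cumulative probability inclusively", {
  d <- make_distogram(10, rbind(c(3, 9)), 0.6)
  g <- contacts_from_distogram(d, 12)
  expect_equal(edge_keys(g), "3 9")

  # boundary: P(d <= cutoff) exactly 0.5 is a contact
  d <- make_distogram(10, rbind(c(3, 9)), 0.5)
  expect_equal(edge_keys(contacts_from_distogram(d, 12)), "3 9")

  # just below threshold: no contact
  d <- make_distogram(10, rbind(c(3, 9)), 0.49)
  expect_equal(nrow(contacts_from_distogram(d, 12)$edges), 0L)
})

test_that("all-contact map yields every pair at the minimum separation", {
  pairs <- t(utils::combn(5, 2))
  d <- make_distogram(5, pairs, rep(1, nrow(pairs)))
  g <- contacts_from_distogram(d, 8, min_separation = 2)
  expect_equal(edge_keys(g),
               c("1 3", "1 4", "1 5", "2 4", "2 5", "3 5"))
})

test_that("a cutoff off the bin grid is a configuration error naming the nearest edges", {
  d <- make_distogram(5, rbind(c(1, 4)), 0.9)
  expect_error(contacts_from_distogram(d, 9.25), "9 and 9.5")
  expect_error(contacts_from_distogram(d, 9.25), "configuration error")
})

test_that("invalid distograms are rejected", {
  bins <- trrosetta_bins()
  B <- length(bins)
  probs <- array(1 / B, c(3, 3, B))
  probs[1, 2, 1] <- probs[1, 2, 1] + 0.5   # breaks both sum and symmetry
  expect_error(distogram("bad", probs, bins), "sum to 1")
  probs <- array(1 / B, c(3, 3, B))        # sums to 1 exactly
  probs[1, 2, 1] <- probs[1, 2, 1] + 1e-5
  probs[1, 2, 2] <- probs[1, 2, 2] - 1e-5
  expect_error(distogram("asym", probs, bins), "asymmetric")
})

test_that("coordinate-based contacts respect cutoff and separation", {
  two <- function(d) cbind(c(0, d), 0, 0)
  expect_equal(nrow(contacts_from_coordinates(two(7.9), 8,
                                              min_separation = 1)$edges), 1L)
  expect_equal(nrow(contacts_from_coordinates(two(8.1), 8,
                                              min_separation = 1)$edges), 0L)

  collinear <- cbind(c(0, 6, 12, 18), 0, 0)
  g <- contacts_from_coordinates(collinear, 12, min_separation = 2)
  expect_equal(edge_keys(g), c("1 3", "2 4"))
})

test_that("missing residues are excluded and degenerate input errors", {
  xyz <- cbind(c(0, NA, 6), c(0, NA, 0), c(0, NA, 0))
  expect_warning(g <- contacts_from_coordinates(xyz, 8), "without coordinates")
  expect_equal(edge_keys(g), "1 3")
  expect_error(
    suppressWarnings(contacts_from_coordinates(cbind(0, 0, 0), 8)),
    "degenerate")
})

test_that("contact precision counts overlap fractions in both modes", {
  ref <- contact_graph("r", 10, rbind(c(1, 4), c(2, 6), c(3, 8)), 12)
  expect_equal(contact_precision(ref, ref, mode = "all"), 1.0)

  pred <- contact_graph("p", 10,
                        rbind(c(1, 4), c(2, 6), c(3, 8), c(1, 9)), 12)
  expect_equal(contact_precision(pred, ref, mode = "all"), 0.75)

  short <- contact_graph("s", 9, rbind(c(1, 4)), 12)
  expect_error(contact_precision(short, ref, mode = "all"),
               "different lengths")

  # top-L/5 long-range: L = 100 -> 20 selected, 18 in the reference
  set.seed(7)
  i <- sample(1:50, 30, replace = TRUE)
  j <- i + sample(24:45, 30, replace = TRUE)
  pairs <- unique(cbind(i, j))[1:25, ]
  scores <- seq(1, 0.04, length.out = 25)
  ref_edges <- pairs[c(1:18, 21:23), , drop = FALSE]  # 18 of the top 20
  ref100 <- contact_graph("r", 100, ref_edges, 8)
  prec <- contact_precision(NULL, ref100, mode = "top_L5_long",
                            pair_scores = cbind(pairs, scores))
  expect_equal(prec, 0.9)

  tiny <- contact_graph("t", 4, rbind(c(1, 4)), 8)
  expect_error(contact_precision(NULL, tiny, mode = "top_L5_long",
                                 pair_scores = cbind(1, 4, 1)),
               "L/5")
})

test_that("edge sets are nested across the 8/10/12 A cutoffs", {
  for (seed in 1:5) {
    d <- random_distogram(12, seed)
    e8 <- edge_keys(contacts_from_distogram(d, 8, prob_threshold = 0.3))
    e10 <- edge_keys(contacts_from_distogram(d, 10, prob_threshold = 0.3))
    e12 <- edge_keys(contacts_from_distogram(d, 12, prob_threshold = 0.3))
    expect_true(all(e8 %in% e10))
    expect_true(all(e10 %in% e12))
  }
})

test_that("graph outputs are canonical: i < j, no self edges, separation respected", {
  for (seed in 1:5) {
    g <- random_graph(15, 0.3, seed, min_separation = 2L)
    expect_true(all(g$edges[, 1] < g$edges[, 2]))
    expect_true(all(g$edges[, 2] - g$edges[, 1] >= 2))
  }
  expect_error(contact_graph("x", 5, rbind(c(2, 2)), 8), "self-edges")
  expect_error(contact_graph("x", 5, rbind(c(1, 6)), 8), "\\[1, L\\]")
})

test_that("edge-list and CASP-RR files round trip", {
  g <- random_graph(20, 0.2, 3, min_separation = 2L, id = "IOTEST_SYN")
  path <- withr::local_tempfile(fileext = ".edges")
  write_contact_graph(g, path)
  g2 <- read_contact_graph(path)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$protein_id, g$protein_id)
  expect_equal(g2$cutoff, g$cutoff)

  rr <- withr::local_tempfile(fileext = ".rr")
  write_casp_rr(g, rr)
  g3 <- read_casp_rr(rr, length = 20)
  expect_equal(g3$edges, g$edges)
  expect_equal(g3$protein_id, g$protein_id)
})

test_that("distogram text serialization round trips", {
  g <- random_graph(10, 0.3, 5, min_separation = 2L)
  d <- generate_distogram(g, cutoff = 12)
  path <- withr::local_tempfile(fileext = ".distogram")
  write_distogram(d, path)
  d2 <- read_distogram(path)
  expect_equal(d2$bin_edges, d$bin_edges)
  expect_equal(d2$probabilities, d$probabilities, tolerance = 1e-9)
})
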