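# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use naive enumeration (combn over node subsets, explicit
# matching enumeration, exhaustive threshold scans) rather than the package's
# own algorithms.

random_graph <- function(n, p, seed, min_separation = 1L, id = "rnd") {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2L))
  pairs <- pairs[pairs[, 2L] - pairs[, 1L] >= min_separation, , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < p
  contact_graph(id, n, pairs[keep, , drop = FALSE], cutoff = 8,
                min_separation = min_separation)
}

# Exact orbit counts by enumerating every 2/3/4-node subset, testing
# connectivity of the induced subgraph, and classifying it by its degree
# sequence.
oracle_orbits <- function(g) {
  n <- g$length
  A <- matrix(FALSE, n, n)
  if (nrow(g$edges)) {
    A[g$edges] <- TRUE
    A[g$edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  orb <- matrix(0L, n, 15L)
  connected <- function(nodes) {
    sub <- A[nodes, nodes, drop = FALSE]
    reach <- c(TRUE, rep(FALSE, length(nodes) - 1L))
    repeat {
      new <- reach | apply(sub[reach, , drop = FALSE], 2L, any)
      if (all(new == reach)) break
      reach <- new
    }
    all(reach)
  }
  if (n >= 2) for (c2 in utils::combn(n, 2L, simplify = FALSE)) {
    if (A[c2[1], c2[2]]) orb[c2, 1] <- orb[c2, 1] + 1L
  }
  if (n >= 3) for (c3 in utils::combn(n, 3L, simplify = FALSE)) {
    sub <- A[c3, c3]
    deg <- rowSums(sub)
    m <- sum(deg) / 2
    if (m == 2) {
      orb[c3[deg == 2], 3] <- orb[c3[deg == 2], 3] + 1L
      orb[c3[deg == 1], 2] <- orb[c3[deg == 1], 2] + 1L
    } else if (m == 3) {
      orb[c3, 4] <- orb[c3, 4] + 1L
    }
  }
  if (n >= 4) for (c4 in utils::combn(n, 4L, simplify = FALSE)) {
    sub <- A[c4, c4]
    deg <- rowSums(sub)
    m <- sum(deg) / 2
    if (m < 3 || !connected(c4)) next
    add <- function(nodes, o) orb[nodes, o + 1L] <<- orb[nodes, o + 1L] + 1L
    if (m == 3) {
      if (max(deg) == 3) { add(c4[deg == 1], 6); add(c4[deg == 3], 7) }
      else { add(c4[deg == 1], 4); add(c4[deg == 2], 5) }
    } else if (m == 4) {
      if (max(deg) == 3) {
        add(c4[deg == 1], 9); add(c4[deg == 2], 10); add(c4[deg == 3], 11)
      } else add(c4, 8)
    } else if (m == 5) {
      add(c4[deg == 2], 12); add(c4[deg == 3], 13)
    } else add(c4, 14)
  }
  colnames(orb) <- paste0("O", 0:14)
  orb
}

# Maximum matched-similarity over ALL order-preserving partial matchings,
# by explicit enumeration of equal-size ordered subsets of both node sets.
oracle_align_score <- function(g1, g2) {
  s1 <- count_orbits(g1)
  s2 <- count_orbits(g2)
  n1 <- g1$length; n2 <- g2$length
  sim <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    sim[i, j] <- node_similarity(s1[i, ], s2[j, ])
  best <- 0
  for (k in seq_len(min(n1, n2))) {
    rows <- utils::combn(n1, k, simplify = FALSE)
    cols <- utils::combn(n2, k, simplify = FALSE)
    for (r in rows) for (cc in cols) {
      v <- sum(sim[cbind(r, cc)])   # both ascending: order-preserving
      if (v > best) best <- v
    }
  }
  best / max(n1, n2)
}

# Exhaustive Fmax over every threshold where the predicted sets can change
# (the distinct prediction scores), flat vocabulary (no propagation).
oracle_fmax <- function(predictions, truth_sets) {
  scores <- unlist(lapply(predictions, function(p) p$scores))
  thresholds <- sort(unique(scores))
  best <- 0
  for (t in thresholds) {
    pr <- c(); rc <- c()
    for (p in names(truth_sets)) {
      pred <- names(predictions[[p]]$scores)[predictions[[p]]$scores >= t]
      tp <- length(intersect(pred, truth_sets[[p]]))
      if (length(pred)) pr <- c(pr, tp / length(pred))
      rc <- c(rc, tp / length(truth_sets[[p]]))
    }
    precision <- if (length(pr)) mean(pr) else 0
    recall <- mean(rc)
    f <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    best <- max(best, f)
  }
  best
}

# Exhaustive Smin over the distinct prediction scores plus a supra-maximal
# threshold (empty predictions), flat vocabulary.
oracle_smin <- function(predictions, truth_sets, ic) {
  scores <- unlist(lapply(predictions, function(p) p$scores))
  thresholds <- c(sort(unique(scores)), max(scores) + 1)
  best <- Inf
  for (t in thresholds) {
    ru <- 0; mi <- 0
    for (p in names(truth_sets)) {
      pred <- names(predictions[[p]]$scores)[predictions[[p]]$scores >= t]
      ru <- ru + sum(ic[setdiff(truth_sets[[p]], pred)])
      mi <- mi + sum(ic[setdiff(pred, truth_sets[[p]])])
    }
    ru <- ru / length(truth_sets)
    mi <- mi / length(truth_sets)
    best <- min(best, sqrt(ru^2 + mi^2))
  }
  best
}
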