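# The seeded synthetic generator: topologies, perturbation, distograms,
# ontologies and the fixture writer.

test_that("band topology produces its closed-form edge set", {
  spec <- synthetic_spec(seed = 1, topology = "band", band_width = 4L)
  g <- generate_contact_graph(spec, length = 10)
  expected <- t(utils::combn(10, 2))
  expected <- expected[expected[, 2] - expected[, 1] >= 2 &
                       expected[, 2] - expected[, 1] <= 4, ]
  expect_equal(edge_keys(g), paste(expected[, 1], expected[, 2]))
})

test_that("generation is deterministic per seed and errors on tiny lengths", {
  spec <- synthetic_spec(seed = 17)
  g1 <- generate_contact_graph(spec)
  g2 <- generate_contact_graph(spec)
  expect_identical(g1, g2)
  g3 <- generate_contact_graph(spec, seed = 18)
  expect_false(identical(g1$edges, g3$edges))
  expect_error(generate_contact_graph(spec, length = 2), "length >= 3")
})

test_that("perturbation flips the expected fraction of slots", {
  spec <- synthetic_spec(seed = 2)
  g <- generate_contact_graph(spec, length = 40)
  expect_identical(perturb_graph(g, 0, 1)$edges, g$edges)

  # rate 1 complements the eligible slots
  comp <- perturb_graph(g, 1, 1)
  n_slots <- sum(upper.tri(matrix(0, 40, 40)) &
                 outer(1:40, 1:40, function(i, j) j - i >= 2))
  expect_equal(nrow(comp$edges), n_slots - nrow(g$edges))
  expect_equal(length(intersect(edge_keys(comp), edge_keys(g))), 0L)

  # binomial check: flipped fraction within 3 standard errors of the rate
  rate <- 0.1
  flips <- sapply(1:30, function(k) {
    p <- perturb_graph(g, rate, 100 + k)
    length(c(setdiff(edge_keys(p), edge_keys(g)),
             setdiff(edge_keys(g), edge_keys(p))))
  })
  total <- n_slots * 30
  se <- sqrt(rate * (1 - rate) / total)
  expect_lt(abs(sum(flips) / total - rate), 3 * se)
})

test_that("distograms concentrate mass so conversion recovers the graph", {
  spec <- synthetic_spec(seed = 3)
  g <- generate_contact_graph(spec)
  for (p_close in c(0.9, 0.5)) {       # 0.5: boundary-inclusive recovery
    d <- generate_distogram(g, contact_prob = p_close, noncontact_prob = 0.1)
    back <- contacts_from_distogram(d, g$cutoff, prob_threshold = 0.5,
                                    min_separation = g$min_separation)
    expect_equal(edge_keys(back), edge_keys(g), info = paste("p", p_close))
  }
  sums <- apply(generate_distogram(g)$probabilities, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_error(generate_distogram(g, contact_prob = 1.2), "\\[0, 1\\]")
})

test_that("same-family proteins share direct terms and the ontology is reproducible", {
  spec <- synthetic_spec(seed = 23)
  fam <- c(A1_SYN = "F1", A2_SYN = "F1", B1_SYN = "F2", B2_SYN = "F2")
  oa1 <- generate_ontology_and_annotations(spec, fam)
  oa2 <- generate_ontology_and_annotations(spec, fam)
  expect_identical(oa1$annotations$proteins, oa2$annotations$proteins)
  expect_gte(length(intersect(oa1$annotations$proteins$A1_SYN,
                              oa1$annotations$proteins$A2_SYN)), 1L)
  # single root per namespace, acyclic by construction
  ns <- oa1$ontology$namespace[oa1$ontology$roots]
  expect_equal(sort(unname(ns)),
               sort(c("biological_process", "cellular_component",
                      "molecular_function")))
  # byte-identical OBO for a fixed seed
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_obo(oa1$ontology, p1)
  write_obo(oa2$ontology, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the fixture writer emits every artifact and they read back", {
  dir <- withr::local_tempdir()
  bench <- make_fixtures(dir, seed = 7, n_families = 3)
  ids <- names(bench$db_graphs)
  expect_true(all(file.exists(
    file.path(dir, "graphs", paste0(ids, ".edges")))))
  expect_true(all(file.exists(
    file.path(dir, "graphs", paste0(ids, ".rr")))))
  expect_true(file.exists(file.path(dir, "ontology.obo")))
  expect_true(file.exists(file.path(dir, "annotations.tsv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  g <- read_contact_graph(file.path(dir, "graphs",
                                    paste0(ids[1], ".edges")))
  expect_equal(g$edges, bench$db_graphs[[ids[1]]]$edges)
  qid <- names(bench$query_graphs)[1]
  d <- read_distogram(file.path(dir, "distograms",
                                paste0(qid, ".distogram")))
  back <- contacts_from_distogram(d, 12)
  expect_equal(edge_keys(back), edge_keys(bench$query_graphs[[qid]]))
  ann <- read_annotation_tsv(file.path(dir, "annotations.tsv"))
  expect_setequal(names(ann$proteins), ids)
})

test_that("retrieval of the source family degrades as perturbation rises", {
  rates <- c(0.02, 0.25)
  recovered <- sapply(rates, function(r) {
    spec <- synthetic_spec(seed = 37, perturbation = r)
    bench <- generate_benchmark(spec, n_families = 12)
    db <- build_reference_db(bench$db_graphs)
    hits_first <- vapply(names(bench$query_graphs), function(qid) {
      h <- search_reference_db(bench$query_graphs[[qid]], db)
      fam <- bench$family_of[[qid]]
      any(bench$family_of[h$hits$reference_id[1:2]] == fam)
    }, logical(1))
    mean(hits_first)
  })
  expect_gt(recovered[1], recovered[2])
})
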