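# Reference database construction, ortholog deduplication, search ranking
# and the three hit-selection schemes.

graph_of_length <- function(L, id) {
  contact_graph(id, L, rbind(c(1L, 3L), c(2L, L)), cutoff = 12)
}

test_that("length bounds are inclusive and exclusions are counted", {
  graphs <- lapply(c(19, 20, 2000, 2001), function(L)
    graph_of_length(L, paste0("L", L)))
  db <- build_reference_db(graphs)
  expect_setequal(names(db$entries), c("L20", "L2000"))
  expect_equal(db$n_excluded, 2L)

  expect_warning(empty <- build_reference_db(list()), "empty")
  expect_equal(length(empty$entries), 0L)

  five <- lapply(1:5, function(k) graph_of_length(100, paste0("G", k)))
  expect_equal(length(build_reference_db(five)$entries), 5L)
})

test_that("duplicate ids abort the build with their names", {
  graphs <- list(graph_of_length(50, "DUP_A"), graph_of_length(60, "DUP_A"))
  expect_error(build_reference_db(graphs), "DUP_A")
})

test_that("ortholog dedup keeps one lexicographically smallest id per mnemonic code", {
  expect_setequal(dedup_by_mnemonic(c("ZRT1_SCHPO", "ZRT1_YEAST")),
                  "ZRT1_SCHPO")
  expect_setequal(dedup_by_mnemonic(c("A_X", "B_Y")), c("A_X", "B_Y"))
  expect_setequal(dedup_by_mnemonic(c("Q_C", "Q_A", "Q_B")), "Q_A")
  expect_message(kept <- dedup_by_mnemonic(c("NOUND", "NOUND2", "AB_C")),
                 "without an underscore")
  expect_setequal(kept, c("NOUND", "NOUND2", "AB_C"))
})

test_that("an entry identical to the query ranks first with score 1 and search is deterministic", {
  spec <- synthetic_spec(seed = 21)
  graphs <- lapply(1:10, function(k) {
    g <- generate_contact_graph(spec, seed = 100 + k)
    g$protein_id <- sprintf("REF%02d_SYN", k)
    g
  })
  db <- build_reference_db(graphs)
  q <- graphs[[4]]
  h1 <- search_reference_db(q, db)
  expect_equal(h1$hits$reference_id[1], "REF04_SYN")
  expect_equal(h1$hits$score[1], 1.0)
  h2 <- search_reference_db(q, db)
  expect_identical(h1$hits, h2$hits)
})

test_that("a slightly perturbed copy of the query ranks first in a background database", {
  spec <- synthetic_spec(seed = 31)
  graphs <- lapply(1:20, function(k) {
    g <- generate_contact_graph(spec, seed = 300 + k)
    g$protein_id <- sprintf("BG%02d_SYN", k)
    g
  })
  query <- generate_contact_graph(spec, seed = 999)
  query$protein_id <- "QUERY_SYN"
  near <- perturb_graph(query, 0.02, 555)
  near$protein_id <- "NEAR_SYN"
  db <- build_reference_db(c(graphs, list(near)))
  hits <- search_reference_db(query, db)
  expect_equal(hits$hits$reference_id[1], "NEAR_SYN")
})

test_that("the three selection schemes keep the specified hits", {
  h <- hit_list("q", c("a", "b", "c"), c(0.9, 0.6, 0.4))
  kept <- select_hits(h, selection_policy("score_threshold", 0.5))
  expect_equal(kept$hits$reference_id, c("a", "b"))

  kept <- select_hits(h, selection_policy("top_n", 2))
  expect_equal(kept$hits$score, c(0.9, 0.6))

  hz <- hit_list("q", letters[1:6], c(0.8, rep(0.2, 5)))
  kept <- select_hits(hz, selection_policy("z_score", 2))
  expect_equal(kept$hits$reference_id, "a")

  flat <- hit_list("q", c("a", "b"), c(0.5, 0.5))
  expect_error(select_hits(flat, selection_policy("z_score", 1)),
               "zero score variance")
})

test_that("selection is a rank-preserving subset and exclusions come first", {
  h <- hit_list("q", letters[1:8], seq(0.9, 0.2, by = -0.1))
  for (policy in list(selection_policy("score_threshold", 0.45),
                      selection_policy("top_n", 3),
                      selection_policy("z_score", 0.5))) {
    kept <- select_hits(h, policy)
    expect_true(all(kept$hits$reference_id %in% h$hits$reference_id))
    expect_false(is.unsorted(rev(kept$hits$score)))
  }
  # top_n with N = |db| returns everything minus exclusions
  kept <- select_hits(h, selection_policy("top_n", 8),
                      exclusions = c("a", "d"))
  expect_equal(kept$hits$reference_id, setdiff(letters[1:8], c("a", "d")))
  # the optional raw-score floor under top_n
  kept <- select_hits(h, selection_policy("top_n", 8), min_score = 0.5)
  expect_equal(kept$hits$reference_id, letters[1:5])
})

test_that("invalid policies and malformed hit lists are rejected", {
  expect_error(selection_policy("score_threshold", 1.4), "invalid parameter")
  expect_error(selection_policy("top_n", 0), "invalid parameter")
  expect_error(hit_list("q", c("a", "b"), c(0.3, 0.6)), "descending")
  expect_error(hit_list("q", c("a", "a"), c(0.6, 0.3)), "duplicate")
})

test_that("the JSON archive round trips database contents and search results", {
  spec <- synthetic_spec(seed = 41)
  graphs <- lapply(1:6, function(k) {
    g <- generate_contact_graph(spec, seed = 400 + k)
    g$protein_id <- sprintf("AR%02d_SYN", k)
    g
  })
  db <- build_reference_db(graphs)
  path <- withr::local_tempfile(fileext = ".json")
  save_reference_db(db, path)
  db2 <- load_reference_db(path)
  expect_equal(names(db2$entries), names(db$entries))
  expect_equal(db2$entries[[3]]$graph$edges, db$entries[[3]]$graph$edges)
  expect_equal(db2$entries[[3]]$signature, db$entries[[3]]$signature)
  q <- generate_contact_graph(spec, seed = 477)
  expect_equal(search_reference_db(q, db2)$hits,
               search_reference_db(q, db)$hits)
})
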