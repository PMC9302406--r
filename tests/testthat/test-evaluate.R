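# Fmax, Smin, per-protein F and head-to-head win counts, validated against
# exhaustive threshold enumeration on handcrafted fixtures.

flat_truth <- function(sets) annotation_set(sets, propagated = TRUE)

test_that("a perfect prediction at score 1.0 reaches Fmax 1 and Smin 0", {
  truth <- flat_truth(list(P = paste0("T", 1:8)))
  pred <- list(P = go_prediction("P", stats::setNames(rep(1, 8),
                                                      paste0("T", 1:8)),
                                 normalized = TRUE))
  fm <- fmax(pred, truth)
  expect_equal(fm$fmax, 1.0)
  ic <- stats::setNames(rep(2, 8), paste0("T", 1:8))
  sm <- smin(pred, truth, ic)
  expect_equal(sm$smin, 0)
  expect_equal(sm$threshold, 0.01)  # smallest minimizing threshold
})

test_that("thresholding trades precision against recall as expected", {
  truth <- flat_truth(list(P = c("A", "B")))
  pred <- list(P = go_prediction("P", c(A = 1.0, C = 0.6),
                                 normalized = TRUE))
  fm <- fmax(pred, truth)
  expect_equal(fm$fmax, 2 / 3)
  expect_gt(fm$threshold, 0.6)
  # empty predictions everywhere give Fmax 0
  none <- list(P = go_prediction("P", numeric(0), normalized = TRUE))
  expect_equal(fmax(none, truth)$fmax, 0)
})

test_that("Smin reflects information-content-weighted misses", {
  truth <- flat_truth(list(P = c("A", "B")))
  pred <- list(P = go_prediction("P", c(A = 1.0), normalized = TRUE))
  ic <- c(A = 2, B = 3)
  sm <- smin(pred, truth, ic)
  expect_equal(sm$smin, 3)   # ru = 3 (B missed), mi = 0, at every threshold
  # over-predicting the whole vocabulary cannot beat the perfect prediction
  all_pred <- list(P = go_prediction("P", c(A = 1.0, B = 1.0, X = 1.0),
                                     normalized = TRUE))
  ic2 <- c(A = 2, B = 3, X = 1)
  expect_gte(smin(all_pred, truth, ic2)$smin, 0)
})

test_that("Fmax and Smin match exhaustive enumeration on a 3-protein fixture", {
  truth_sets <- list(P1 = c("A", "B", "C"),
                     P2 = c("B", "D"),
                     P3 = c("E"))
  preds <- list(
    P1 = go_prediction("P1", c(A = 1.0, B = 0.70, X = 0.40),
                       normalized = TRUE),
    P2 = go_prediction("P2", c(B = 1.0, D = 0.30, E = 0.20),
                       normalized = TRUE),
    P3 = go_prediction("P3", c(E = 0.50, A = 0.50, B = 1.0),
                       normalized = TRUE))
  ic <- c(A = 1.5, B = 0.8, C = 2.2, D = 1.9, E = 2.6, X = 3.1)
  fm <- fmax(preds, flat_truth(truth_sets))
  expect_equal(fm$fmax, oracle_fmax(preds, truth_sets), tolerance = 1e-12)
  sm <- smin(preds, flat_truth(truth_sets), ic)
  expect_equal(sm$smin, oracle_smin(preds, truth_sets, ic),
               tolerance = 1e-12)
})

test_that("recall is non-increasing in the threshold", {
  truth_sets <- list(P1 = c("A", "B"), P2 = c("C"))
  preds <- list(
    P1 = go_prediction("P1", c(A = 1.0, B = 0.35), normalized = TRUE),
    P2 = go_prediction("P2", c(C = 0.8, A = 1.0), normalized = TRUE))
  curve <- fmax(preds, flat_truth(truth_sets))$curve
  expect_true(all(diff(curve$recall) <= 1e-12))
})

test_that("evaluation propagates predicted terms through the ontology", {
  obo <- c("[Term]", "id: ROOT", "name: r",
           "namespace: molecular_function", "",
           "[Term]", "id: MID", "name: m",
           "namespace: molecular_function", "is_a: ROOT", "",
           "[Term]", "id: LEAF", "name: l",
           "namespace: molecular_function", "is_a: MID", "")
  ont <- load_ontology(obo)
  truth <- propagate_annotations(annotation_set(list(P = "LEAF")), ont)
  pred <- list(P = go_prediction("P", c(LEAF = 1.0), normalized = TRUE))
  fm <- fmax(pred, truth, ont)
  expect_equal(fm$fmax, 1.0)  # MID reached by propagating the prediction
  fm_flat <- fmax(pred, truth, ont, propagate_predictions = FALSE)
  expect_lt(fm_flat$fmax, 1.0)
})

test_that("per-protein F matches precision/recall arithmetic at a fixed threshold", {
  truth <- flat_truth(list(P = paste0("T", 1:8), Q = c("A")))
  preds <- list(
    P = go_prediction("P", stats::setNames(rep(1, 4), paste0("T", 1:4)),
                      normalized = TRUE),
    Q = go_prediction("Q", numeric(0), normalized = TRUE))
  f <- per_protein_f(preds, truth, t = 0.5)
  expect_equal(unname(f["P"]), 2 / 3)  # precision 1, recall 0.5
  expect_equal(unname(f["Q"]), 0)      # empty prediction
  ident <- list(P = go_prediction("P", stats::setNames(rep(1, 8),
                                                       paste0("T", 1:8)),
                                  normalized = TRUE),
                Q = go_prediction("Q", c(A = 1), normalized = TRUE))
  expect_true(all(per_protein_f(ident, truth, t = 0.5) == 1))
})

test_that("win counts use strict inequality with separate ties", {
  a <- c(P1 = 0.9, P2 = 0.1, P3 = 0.5)
  b <- c(P1 = 0.5, P2 = 0.5, P3 = 0.5)
  w <- win_counts(a, b)
  expect_equal(w$wins_a, 1)
  expect_equal(w$wins_b, 1)
  expect_equal(w$ties, 1)
  expect_equal(win_counts(a, a),
               list(wins_a = 0, wins_b = 0, ties = 3))
  expect_error(win_counts(a, b[1:2]), "P3")
})

test_that("proteins with empty truth are excluded with a warning", {
  truth <- flat_truth(list(P = c("A"), Q = character(0)))
  pred <- list(P = go_prediction("P", c(A = 1), normalized = TRUE))
  expect_warning(fm <- fmax(pred, truth), "empty truth")
  expect_equal(fm$proteins, "P")
})
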