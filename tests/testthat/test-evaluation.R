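# A small fixed reference taxonomy:  root -> {A, B}; A -> {A1, A2}; A1 -> A1a
toy_taxonomy <- function() {
  reference_taxonomy(parent = c("root", "root", "A", "A", "A1"),
                     child = c("A", "B", "A1", "A2", "A1a"))
}

# A labeled hierarchy skeleton (no models needed for the metrics).
toy_hierarchy <- function(labels) {
  nodes <- list()
  mk <- function(id, parent, children, label_ids) {
    list(id = id, parent = parent, children = children,
         members = "m", depth = 0L,
         labels = if (length(label_ids)) {
           data.frame(term_id = label_ids, term_name = label_ids,
                      score = rev(seq_along(label_ids)))
         })
  }
  nodes$root <- mk("root", NA_character_, c("n1", "n2"), labels$root)
  nodes$n1 <- mk("n1", "root", "n3", labels$n1)
  nodes$n2 <- mk("n2", "root", character(0), labels$n2)
  nodes$n3 <- mk("n3", "n1", character(0), labels$n3)
  structure(list(root = "root", nodes = nodes, config = run_config()),
            class = "qa_hierarchy")
}

test_that("ancestry weights follow 1/2^p with directed paths", {
  tax <- toy_taxonomy()
  expect_equal(relation_weight("A", "A1", tax), 0.5)      # direct child
  expect_equal(relation_weight("A", "A1a", tax), 0.25)    # grandchild
  expect_equal(relation_weight("root", "A1a", tax), 0.125)
  expect_equal(relation_weight("A1", "A", tax), 0)        # reversed
  expect_equal(relation_weight("A", "B", tax), 0)         # unrelated
  expect_equal(relation_weight("A", "Z", tax), 0)         # absent
  expect_error(reference_taxonomy(c("a", "b"), c("b", "a")), "cycle")
})

test_that("tuple accuracy counts direct reference edges among labeled pairs", {
  tax <- toy_taxonomy()
  # 3 edges with top labels: root->n1 (root,A: correct), root->n2 (root,A1a:
  # wrong), n1->n3 (A,A2: correct) -> 2/3
  h <- toy_hierarchy(list(root = "root", n1 = "A", n2 = "A1a", n3 = "A2"))
  ta <- tuple_accuracy(h, tax)
  expect_equal(ta$total, 3L)
  expect_equal(ta$correct, 2L)
  expect_equal(ta$accuracy, 2 / 3)
  # a hierarchy labeled exactly by reference edges is fully correct
  h2 <- toy_hierarchy(list(root = "root", n1 = "A", n2 = "B", n3 = "A1"))
  expect_equal(tuple_accuracy(h2, tax)$accuracy, 1)
  # unlabeled everywhere -> no tuples, accuracy undefined
  h3 <- toy_hierarchy(list(root = character(0), n1 = character(0),
                           n2 = character(0), n3 = character(0)))
  ta3 <- tuple_accuracy(h3, tax)
  expect_equal(ta3$total, 0L)
  expect_true(is.na(ta3$accuracy))
  expect_equal(ta3$skipped, 3L)
})

test_that("cohesiveness averages ancestry weights over adjacent label pairs", {
  tax <- toy_taxonomy()
  # single parent term, two child terms with weights 0.5 and 0 -> 0.25
  h <- toy_hierarchy(list(root = character(0), n1 = c("A1", "B"), n2 = character(0),
                          n3 = character(0)))
  h$nodes$n1$children <- character(0)
  h$nodes$root$labels <- data.frame(term_id = "A", term_name = "A", score = 1)
  h$nodes$root$children <- "n1"
  expect_equal(cohesiveness(h, tax), 0.25)
  # a reference-mirroring hierarchy with single labels scores exactly 0.5
  h2 <- toy_hierarchy(list(root = "root", n1 = "A", n2 = "B", n3 = "A1"))
  expect_equal(cohesiveness(h2, tax), 0.5)
  # random shuffles of the labels score strictly lower
  h3 <- toy_hierarchy(list(root = "A1", n1 = "B", n2 = "root", n3 = "A2"))
  expect_lt(cohesiveness(h3, tax), 0.5)
  expect_true(is.na(cohesiveness(toy_hierarchy(
    list(root = character(0), n1 = character(0), n2 = character(0),
         n3 = character(0))), tax)))
})

test_that("S@K and P@K follow their definitions", {
  expect_equal(s_at_k(c("A", "B", "C"), "B", 1), 0)
  expect_equal(s_at_k(c("A", "B", "C"), "B", 2), 1)
  expect_equal(p_at_k(c("A", "B", "C"), "B", 3), 1 / 3)
  expect_equal(p_at_k(c("A", "B"), c("A", "B"), 2), 1)
  expect_equal(s_at_k(c("A", "B"), character(0), 2), 0)
  expect_equal(p_at_k(c("A", "B"), character(0), 2), 0)
  expect_equal(s_at_k(character(0), "A", 3), 0)
  expect_error(s_at_k("A", "A", 0), "positive")
})

test_that("NDCG uses exponential gains with a log2 discount", {
  expect_equal(ndcg_at_n(c(2, 1, 0), 3), 1)           # ideal ordering
  expect_equal(ndcg_at_n(c(0, 0, 0), 3), 0)           # nothing relevant
  expect_equal(ndcg_at_n(c(0, 2), 2), (3 / log2(3)) / 3, tolerance = 1e-6)
  # permutation-invariant at full depth under ideal reordering
  withr::with_seed(12, {
    g <- sample(0:2, 8, TRUE)
    expect_equal(ndcg_at_n(sort(g, decreasing = TRUE), 8), if (sum(g)) 1 else 0)
  })
  # missing relevant records are penalized through the ideal pool
  expect_lt(ndcg_at_n(c(1, 0), 2, ideal_gains = c(2, 1, 0)), 1)
})
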