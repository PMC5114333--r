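test_that("the random walk matches its closed forms and the direct solve", {
  ybar <- c(0.9, 0.4, 0.1, 0.7)
  lam <- 0.8
  # W = 0 (bypass disabled): fixed point (lambda / (1 + lambda)) * ybar
  y0 <- random_walk_rank(matrix(0, 4, 4), ybar, lambda = lam,
                         bypass_isolated = FALSE)
  expect_equal(as.numeric(y0), lam / (1 + lam) * ybar, tolerance = 1e-7)
  # W = 0 with bypass: initial scores survive untouched
  y0b <- random_walk_rank(matrix(0, 4, 4), ybar, lambda = lam)
  expect_equal(as.numeric(y0b), ybar)
  # enormous lambda pins y to ybar
  withr::with_seed(8, {
    W <- matrix(runif(16), 4, 4); W <- (W + t(W)) / 2; diag(W) <- 0
    yl <- random_walk_rank(W, ybar, lambda = 1e6)
    expect_lt(max(abs(as.numeric(yl) - ybar)), 1e-4)
    # iterate agrees with the direct linear solve on random instances
    for (i in 1:20) {
      n <- sample(5:50, 1)
      Wr <- matrix(runif(n * n), n, n); Wr <- (Wr + t(Wr)) / 2; diag(Wr) <- 0
      yb <- runif(n)
      lam_i <- runif(1, 0.2, 3)
      y <- random_walk_rank(Wr, yb, lambda = lam_i, tol = 1e-12)
      a <- 1 / (1 + lam_i)
      direct <- solve(diag(n) - a * Wr %*% diag(1 / rowSums(Wr)),
                      (lam_i / (1 + lam_i)) * yb)
      expect_lt(max(abs(as.numeric(y) - direct)), 1e-6)
    }
  })
  expect_error(random_walk_rank(matrix(0, 2, 2), c(1, 1), lambda = 0),
               "positive")
})

test_that("residuals contract and isolated candidates keep initial scores", {
  withr::with_seed(9, {
    W <- matrix(runif(25), 5, 5); W <- (W + t(W)) / 2; diag(W) <- 0
    W[5, ] <- 0; W[, 5] <- 0  # isolate candidate 5
    yb <- runif(5)
    y <- random_walk_rank(W, yb, lambda = 0.5)
    expect_equal(as.numeric(y)[5], yb[5])
    expect_true(attr(y, "converged"))
    expect_lt(attr(y, "residual"), 1e-8)
  })
})

test_that("queries route to leaves and search returns ranked members", {
  b <- small_build()
  h <- b$h; w <- b$w
  corpus <- w$corpus
  leaves <- hierarchy_leaves(h)
  withr::with_seed(10, ids <- sample(corpus_ids(corpus), 8))
  for (id in ids) {
    q <- qa_query(corpus$records[[id]]$question)
    reached <- route_query(h, q, lexicon = w$planted$lexicon)
    expect_true(all(reached %in% leaves))  # never an internal node
  }
  # self-retrieval: an indexed record issued as its own query ranks first
  firsts <- vapply(ids, function(id) {
    res <- search_hierarchy(h, corpus, corpus$records[[id]]$question,
                            n = 10, lexicon = w$planted$lexicon)
    identical(res$id[1L], id)
  }, logical(1))
  expect_gte(sum(firsts), 7L)
  res <- search_hierarchy(h, corpus, corpus$records[[ids[1]]]$question,
                          n = 5, lexicon = w$planted$lexicon)
  expect_lte(nrow(res), 5L)
  expect_true(all(diff(res$score) <= 1e-12))  # scores non-increasing
})

test_that("initial scores reduce to the fused kernel against the query", {
  b <- small_build()
  h <- b$h; w <- b$w
  corpus <- w$corpus
  id <- corpus_ids(corpus)[1L]
  leaf <- hierarchy_leaves(h)[vapply(hierarchy_leaves(h), function(l) {
    id %in% h$nodes[[l]]$members
  }, logical(1))][1L]
  # candidate identical to the query scores 1 under the lexical kernel
  h1 <- h; h1$config$initial_score_kernel <- "phi1"
  q_full <- contextualize(corpus$records[[id]])
  sc <- initial_scores(q_full, id, leaf, h1, corpus, w$planted$lexicon)
  expect_equal(unname(sc), 1)
  # a candidate with no shared vocabulary scores 0
  qz <- qa_query("plainly unrelated zebra xylophone")
  scz <- initial_scores(qz, id, leaf, h1, corpus)
  expect_equal(unname(scz), 0)
  # fused initial scores match per-pair hand fusion for a few candidates
  cands <- h$nodes[[leaf]]$members[1:5]
  q <- qa_query(corpus$records[[id]]$question)
  sc5 <- initial_scores(q, cands, rep(leaf, 5), h, corpus, w$planted$lexicon)
  parent <- h$nodes[[leaf]]$parent
  model <- h$nodes[[parent]]$model
  qmix <- infer_mixture(model, q)
  boosted <- qatopics:::boosted_tokens(w$planted$lexicon,
                                       h$config$boosted_groups)
  for (i in seq_along(cands)) {
    phi1 <- qatopics:::cosine_bags(
      qatopics:::weighted_bag(q$tokens, boosted, h$config$boost),
      qatopics:::weighted_bag(corpus$records[[cands[i]]]$tokens, boosted,
                              h$config$boost))
    th <- model$doc_topic[cands[i], ]
    js <- topic_kernel(qmix, th / sum(th))
    expected <- (0.5 * phi1 + 0.5 * (1 - js / log(2))) / 1
    expect_equal(unname(sc5[i]), expected, tolerance = 1e-10)
  }
})

test_that("the flat baseline ranks by lexical similarity over the corpus", {
  w <- small_world()
  id <- corpus_ids(w$corpus)[3L]
  res <- flat_search(w$corpus, w$corpus$records[[id]]$question, n = 10,
                     lexicon = w$planted$lexicon)
  expect_equal(res$id[1L], id)
  expect_lte(nrow(res), 10L)
})
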