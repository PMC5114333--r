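two_cat_prior <- function(n_seeds = 10L, seed = 1L) {
  withr::with_seed(seed, {
    heart <- lapply(seq_len(n_seeds), function(i) {
      make_record(paste0("h", i),
                  paste(sample(c("heart", "chest", "pressure", "artery",
                                 "pulse"), 6, TRUE), collapse = " "))
    })
    skin <- lapply(seq_len(n_seeds), function(i) {
      make_record(paste0("s", i),
                  paste(sample(c("skin", "rash", "itch", "acne", "eczema"),
                               6, TRUE), collapse = " "))
    })
    domain_prior(list(cardio = heart, derma = skin))
  })
}

test_that("category classifiers separate disjoint-vocabulary seed sets", {
  prior <- two_cat_prior()
  clfs <- train_category_classifiers(prior, seed = 3L)
  # training accuracy 1.0 on both categories
  for (cat in names(prior$categories)) {
    for (r in prior$categories[[cat]]) {
      sc <- qatopics:::classifier_scores(clfs, r$tokens)
      expect_equal(names(which.max(sc)), cat)
      expect_gt(sc[[cat]], 0)
    }
  }
  clfs2 <- train_category_classifiers(prior, seed = 3L)
  expect_identical(clfs, clfs2)
  expect_error(domain_prior(list(a = list(qa_record("1", "q")),
                                 b = list(qa_record("2", "q"),
                                          qa_record("3", "q")))),
               ">= 2 seed")
})

test_that("the first layer covers the corpus with multi-membership", {
  prior <- two_cat_prior()
  clfs <- train_category_classifiers(prior, seed = 3L)
  corpus <- qa_corpus(list(
    make_record("r1", "heart pressure pulse"),
    make_record("r2", "skin rash itch acne"),
    make_record("r3", "heart rash skin artery itch pulse"),  # both
    make_record("r4", "unrelated words entirely")))          # fallback
  fl <- build_first_layer(corpus, clfs)
  expect_setequal(unique(unlist(fl)), corpus_ids(corpus))
  expect_true("r1" %in% fl$cardio && !("r1" %in% fl$derma))
  expect_true("r2" %in% fl$derma)
  # a record with no firing classifier lands in exactly one (best) category
  expect_equal(sum(vapply(fl, function(m) "r4" %in% m, logical(1))), 1L)
  # multi-label contract, pinned with hand-built hyperplanes: a record firing
  # two classifiers becomes a member of both
  manual <- structure(list(
    cardio = list(name = "cardio", vocab = c("heart", "skin"),
                  w = c(heart = 1, skin = 0), rho = 0.1),
    derma = list(name = "derma", vocab = c("heart", "skin"),
                 w = c(heart = 0, skin = 1), rho = 0.1)),
    class = "category_classifiers")
  fl2 <- build_first_layer(qa_corpus(list(
    make_record("b1", "heart skin"),
    make_record("b2", "heart heart"))), manual)
  expect_true("b1" %in% fl2$cardio && "b1" %in% fl2$derma)
  expect_true("b2" %in% fl2$cardio && !("b2" %in% fl2$derma))
  # single-membership mode keeps only the best-scoring category
  fl3 <- build_first_layer(qa_corpus(list(make_record("b1", "heart skin skin"))),
                           manual, multi = FALSE)
  expect_true("b1" %in% fl3$derma && is.null(fl3$cardio))
})

test_that("built hierarchies are valid trees and seed-reproducible", {
  b <- small_build()
  h <- b$h
  expect_true(validate_hierarchy(h))
  expect_setequal(h$nodes$root$members, corpus_ids(b$w$corpus))
  depths <- vapply(h$nodes, `[[`, integer(1), "depth")
  expect_gte(max(depths), 2L)  # the first layer expanded into subtopics
  # every expanded node carries a model with >= 2 children
  for (n in h$nodes) {
    if (!is.null(n$model)) expect_gte(length(n$children), 2L)
  }
  # every category found at least the planted number of subtopics to split
  # into (tight +/-1 recovery needs the full-scale corpus; see the
  # acceptance suite)
  ks <- vapply(h$nodes[h$nodes$root$children],
               function(n) if (is.null(n$model)) NA_integer_ else n$model$k,
               integer(1))
  expect_true(all(ks >= 3L, na.rm = TRUE))
  # rebuild with identical seeds gives the identical hierarchy
  rc <- run_config(k_range = c(2L, 5L), gibbs_iter = 100L, seed = 17L)
  h2 <- build_hierarchy(b$w$corpus, b$w$prior, rc,
                        lexicon = b$w$planted$lexicon,
                        tagger = dictionary_tagger(b$w$planted$tag_dict))
  expect_identical(lapply(h$nodes, `[[`, "members"),
                   lapply(h2$nodes, `[[`, "members"))
  expect_identical(lapply(h$nodes, `[[`, "labels"),
                   lapply(h2$nodes, `[[`, "labels"))
})

test_that("children are more compact than their parents", {
  # monotone specialization: child intra-similarity >= parent's, measured by
  # the lexical kernel on a seeded subsample
  b <- small_build()
  h <- b$h
  corpus <- b$w$corpus
  mean_sim <- function(ids) {
    ids <- withr::with_seed(1, sample(ids, min(40L, length(ids))))
    toks <- lapply(corpus$records[ids], `[[`, "tokens")
    W <- qatopics:::phi1_matrix(toks)
    mean(W[upper.tri(W)])
  }
  for (nid in h$nodes$root$children) {
    n <- h$nodes[[nid]]
    if (!length(n$children)) next
    parent_sim <- mean_sim(n$members)
    kids <- vapply(n$children, function(cid) {
      mean_sim(h$nodes[[cid]]$members)
    }, numeric(1))
    big <- vapply(n$children, function(cid) {
      length(h$nodes[[cid]]$members) >= 20L
    }, logical(1))
    expect_true(all(kids[big] >= parent_sim))
  }
})

test_that("a homogeneous first layer yields a two-level hierarchy", {
  cfg <- generator_config(branching = 2L, docs_per_leaf = 60L,
                          seeds_per_category = 15L, mixture_rate = 0,
                          seed = 71L)
  tree <- generate_topic_tree(cfg)
  pl <- generate_lexicon_and_reference(tree)
  gen <- generate_corpus(tree, pl, cfg)
  corpus <- contextualize_corpus(gen$corpus)
  rc <- run_config(k_range = c(2L, 4L), gibbs_iter = 80L, seed = 5L)
  h <- build_hierarchy(corpus, gen$prior, rc, lexicon = pl$lexicon,
                       tagger = dictionary_tagger(pl$tag_dict))
  # each first-layer category is a single planted topic: no expansion
  expect_equal(max(vapply(h$nodes, `[[`, integer(1), "depth")), 1L)
})

test_that("hierarchy stores round-trip through JSON", {
  b <- small_build()
  path <- withr::local_tempfile(fileext = ".json")
  write_hierarchy(b$h, path)
  h2 <- read_hierarchy(path)
  expect_identical(names(h2$nodes), names(b$h$nodes))
  for (nid in names(b$h$nodes)) {
    expect_identical(h2$nodes[[nid]]$members, b$h$nodes[[nid]]$members)
    expect_identical(h2$nodes[[nid]]$children, b$h$nodes[[nid]]$children)
    expect_equal(h2$nodes[[nid]]$labels, b$h$nodes[[nid]]$labels)
    if (!is.null(b$h$nodes[[nid]]$model)) {
      expect_equal(h2$nodes[[nid]]$model$topic_word,
                   b$h$nodes[[nid]]$model$topic_word)
    }
  }
  expect_equal(h2$config$delta, b$h$config$delta)
  # writing the reloaded store reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".json")
  write_hierarchy(h2, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})
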