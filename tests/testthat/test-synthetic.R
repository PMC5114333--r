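test_that("the topic tree has the configured shape and determinism", {
  cfg <- generator_config(branching = c(3L, 3L), seed = 2L)
  tree <- generate_topic_tree(cfg)
  depths <- vapply(tree$topics, `[[`, integer(1), "depth")
  expect_equal(sum(depths == 1L), 3L)
  expect_equal(sum(depths == 2L), 9L)
  expect_equal(length(tree$topics), 13L)  # root + 3 + 9
  tree2 <- generate_topic_tree(cfg)
  expect_identical(tree, tree2)
  # first-level siblings with zero shared fraction have disjoint supports
  cfg0 <- generator_config(branching = 2L, shared_fraction = 0, seed = 2L)
  tr0 <- generate_topic_tree(cfg0)
  s1 <- names(which(tr0$topics$t1$dist > 0))
  s2 <- names(which(tr0$topics$t2$dist > 0))
  expect_length(intersect(s1, s2), 0L)
  # children's support contains the parent block (specialization)
  tree_d <- generate_topic_tree(generator_config(seed = 3L))
  leaf <- tree_d$topics[["t1.1"]]
  expect_true(all(tree_d$topics$t1$block %in% names(which(leaf$dist > 0))))
  expect_error(generator_config(branching = 1L), "branching")
  expect_error(generator_config(mixture_rate = 1.5), "rates")
})

test_that("corpus generation honors counts, mixtures and memberships", {
  cfg <- generator_config(branching = c(2L, 2L), docs_per_leaf = 25L,
                          mixture_rate = 0, seeds_per_category = 5L, seed = 4L)
  tree <- generate_topic_tree(cfg)
  pl <- generate_lexicon_and_reference(tree)
  gen <- generate_corpus(tree, pl, cfg)
  expect_equal(length(gen$corpus), 4L * 25L)
  expect_true(all(lengths(gen$truth$memberships) == 1L))
  cfg1 <- generator_config(branching = c(2L, 2L), docs_per_leaf = 25L,
                           mixture_rate = 1, seeds_per_category = 5L, seed = 4L)
  gen1 <- generate_corpus(tree, pl, cfg1)
  expect_true(all(lengths(gen1$truth$memberships) == 2L))
  # determinism
  gen2 <- generate_corpus(tree, pl, cfg)
  expect_identical(write_lines <- lapply(gen$corpus$records, `[[`, "question"),
                   lapply(gen2$corpus$records, `[[`, "question"))
  # prior: one category per first-level topic, with the configured seeds
  expect_equal(names(gen$prior$categories), c("cat_t1", "cat_t2"))
  expect_true(all(lengths(gen$prior$categories) == 5L))
})

test_that("planted lexicon and reference taxonomy align with the tree", {
  tree <- generate_topic_tree(generator_config(seed = 6L))
  pl <- generate_lexicon_and_reference(tree)
  for (id in names(tree$topics)) {
    tid <- paste0("T_", id)
    expect_true(tid %in% pl$lexicon$table$term_id)
    expect_true(tid %in% pl$taxonomy$terms)
    # all surface variants of one concept map to one terminology
    v <- pl$concepts[[id]]$variants
    hits <- lexicon_lookup(pl$lexicon,
                           vapply(v, paste, character(1), collapse = " "))
    expect_equal(unique(hits$term_id), tid)
  }
  # taxonomy depth equals tree depth
  depth_of <- function(t) {
    d <- 0L
    while (t %in% names(pl$taxonomy$parent_of)) {
      t <- pl$taxonomy$parent_of[[t]]
      d <- d + 1L
    }
    d
  }
  expect_equal(max(vapply(pl$taxonomy$terms, depth_of, integer(1))),
               max(vapply(tree$topics, `[[`, integer(1), "depth")))
})

test_that("paraphrased queries keep the topic but swap the vocabulary", {
  w <- small_world()
  cfg0 <- w$cfg; cfg0$paraphrase_rate <- 0
  qs0 <- generate_queries(w$corpus, w$truth, w$tree, cfg0, n_queries = 5L)
  for (q in qs0) {
    expect_equal(strsplit(q$text, " ")[[1L]],
                 tokenize(w$corpus$records[[q$source_id]]$question,
                          stopwords = character(0)))
    expect_equal(sum(q$gains == 2), 1L)
    expect_equal(unname(q$gains[q$source_id]), 2)
  }
  cfg1 <- w$cfg; cfg1$paraphrase_rate <- 1
  qs1 <- generate_queries(w$corpus, w$truth, w$tree, cfg1, n_queries = 5L)
  for (q in qs1) {
    src <- tokenize(w$corpus$records[[q$source_id]]$question,
                    stopwords = character(0))
    qt <- strsplit(q$text, " ")[[1L]]
    swappable <- src %in% names(w$tree$synonyms)
    expect_true(all(qt[swappable] != src[swappable]))
    expect_identical(qt[!swappable], src[!swappable])
  }
})

test_that("all synthetic artifacts round-trip from disk", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(branching = 2L, docs_per_leaf = 15L,
                          seeds_per_category = 4L, seed = 8L)
  out <- write_synthetic(cfg, dir, n_queries = 4L)
  for (f in c("corpus.jsonl", "lexicon.tsv", "reference.tsv", "prior.json",
              "queries.jsonl", "truth.json", "tags.tsv")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  corpus <- read_corpus(file.path(dir, "corpus.jsonl"))
  expect_equal(length(corpus), length(out$corpus))
  lex <- read_lexicon(file.path(dir, "lexicon.tsv"))
  expect_setequal(lex$table$term_id, out$planted$lexicon$table$term_id)
  tax <- read_taxonomy(file.path(dir, "reference.tsv"))
  expect_setequal(tax$terms, out$planted$taxonomy$terms)
  prior <- read_prior(file.path(dir, "prior.json"))
  expect_equal(names(prior$categories), names(out$prior$categories))
})
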