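# Shared fixtures built in code. The "small world" is one modest synthetic
# study corpus reused by several test files; building it once keeps the suite
# fast without any stored data.

make_record <- function(id, question, answers = character(0),
                        tags = character(0), stopwords = character(0)) {
  contextualize(qa_record(id, question, answers = answers, tags = tags),
                stopwords = stopwords)
}

# Token-list documents drawn from disjoint-vocabulary planted topics.
planted_docs <- function(n_per_topic, topics = 3L, words_per_topic = 20L,
                         doc_len = 25L, seed = 1L) {
  vocabs <- lapply(seq_len(topics), function(t) {
    sprintf("k%dw%02d", t, seq_len(words_per_topic))
  })
  withr::with_seed(seed, {
    docs <- list()
    truth <- integer(0)
    for (t in seq_len(topics)) {
      for (i in seq_len(n_per_topic)) {
        id <- sprintf("d%d_%d", t, i)
        docs[[id]] <- sample(vocabs[[t]], doc_len, replace = TRUE)
        truth[id] <- t
      }
    }
    list(docs = docs, truth = truth, vocabs = vocabs)
  })
}

small_world_cache <- new.env(parent = emptyenv())

# One default-shaped (but smaller) synthetic study: tree (3,3), 40 docs/leaf.
small_world <- function() {
  if (is.null(small_world_cache$w)) {
    cfg <- generator_config(docs_per_leaf = 40L, seeds_per_category = 20L,
                            seed = 303L)
    tree <- generate_topic_tree(cfg)
    planted <- generate_lexicon_and_reference(tree)
    gen <- generate_corpus(tree, planted, cfg)
    corpus <- contextualize_corpus(gen$corpus)
    small_world_cache$w <- list(cfg = cfg, tree = tree, planted = planted,
                                corpus = corpus, prior = gen$prior,
                                truth = gen$truth)
  }
  small_world_cache$w
}

# The small world plus a built + labeled hierarchy (cached).
small_build <- function() {
  if (is.null(small_world_cache$h)) {
    w <- small_world()
    rc <- run_config(k_range = c(2L, 5L), gibbs_iter = 100L, seed = 17L)
    small_world_cache$h <- build_hierarchy(
      w$corpus, w$prior, rc, lexicon = w$planted$lexicon,
      tagger = dictionary_tagger(w$planted$tag_dict))
  }
  list(h = small_world_cache$h, w = small_world())
}
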