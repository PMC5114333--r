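# Synthetic study corpus: a known topic tree generating QA records as topic
# mixtures, an aligned toy concept lexicon and reference taxonomy, and
# paraphrased queries emulating the vocabulary gap. Everything is seeded and
# deterministic, so every pipeline stage is testable offline.

#' Generator configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a two-level tree of 3 categories with 3 leaf topics each,
#' mostly-private topic vocabularies, short records (negative-binomial
#' lengths around 30 tokens), a 20% rate of two-sibling mixture records, and
#' paraphrased queries replacing half the tokens with same-topic synonyms.
#'
#' @param branching Children per level, root first (entries `>= 2`).
#' @param vocab_per_topic Private vocabulary words per topic (even; words are
#'   paired into synonyms).
#' @param shared_fraction Probability mass every topic puts on the shared
#'   vocabulary block.
#' @param docs_per_leaf Records generated per leaf topic.
#' @param doc_length_mean,doc_length_dispersion Negative-binomial token count
#'   per record (mean, size).
#' @param mixture_rate Fraction of records drawn 50/50 from two sibling
#'   leaves.
#' @param paraphrase_rate Fraction of query tokens substituted by synonyms.
#' @param concept_rate Probability a record gets its leaf's planted concept
#'   phrase injected.
#' @param category_concept_rate Probability a record gets its first-level
#'   category's concept phrase injected.
#' @param seeds_per_category Seed exemplar records per first-layer category.
#' @param seed Integer seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(branching = c(3L, 3L),
                             vocab_per_topic = 40L,
                             shared_fraction = 0.1,
                             docs_per_leaf = 120L,
                             doc_length_mean = 30,
                             doc_length_dispersion = 10,
                             mixture_rate = 0.2,
                             paraphrase_rate = 0.5,
                             concept_rate = 0.8,
                             category_concept_rate = 0.4,
                             seeds_per_category = 50L,
                             seed = 1L) {
  if (any(branching < 2L)) stop_qa("branching entries must be >= 2")
  for (r in c(shared_fraction, mixture_rate, paraphrase_rate, concept_rate,
              category_concept_rate)) {
    if (r < 0 || r > 1) stop_qa("generator rates must lie in [0, 1]")
  }
  if (vocab_per_topic %% 2L != 0L || vocab_per_topic < 4L) {
    stop_qa("vocab_per_topic must be an even integer >= 4")
  }
  structure(list(branching = as.integer(branching),
                 vocab_per_topic = as.integer(vocab_per_topic),
                 shared_fraction = shared_fraction,
                 docs_per_leaf = as.integer(docs_per_leaf),
                 doc_length_mean = doc_length_mean,
                 doc_length_dispersion = doc_length_dispersion,
                 mixture_rate = mixture_rate,
                 paraphrase_rate = paraphrase_rate,
                 concept_rate = concept_rate,
                 category_concept_rate = category_concept_rate,
                 seeds_per_category = as.integer(seeds_per_category),
                 seed = as.integer(seed)),
            class = "generator_config")
}

topic_word_name <- function(id, j) {
  sprintf("%sw%02d", gsub("\\.", "x", id), j)
}

#' Generate the true topic tree
#'
#' Builds the configured tree and gives every topic a word distribution: its
#' private block, a refinement share on its parent's private block (children
#' specialize parents), and the shared block. Private words are paired into
#' a synonym table used for query paraphrasing.
#'
#' @param config A [generator_config()].
#' @return List of class `topic_tree`: `topics` (named list with `id`,
#'   `parent`, `children`, `depth`, `is_leaf`, `block`, `dist`), `shared`,
#'   `synonyms`, `vocab`, `config`.
#' @export
generate_topic_tree <- function(config = generator_config()) {
  topics <- list(root = list(id = "root", parent = NA_character_,
                             children = character(0), depth = 0L))
  level <- "root"
  for (d in seq_along(config$branching)) {
    nxt <- character(0)
    for (pid in level) {
      for (b in seq_len(config$branching[d])) {
        id <- if (pid == "root") paste0("t", b) else paste0(pid, ".", b)
        topics[[id]] <- list(id = id, parent = pid, children = character(0),
                             depth = d)
        topics[[pid]]$children <- c(topics[[pid]]$children, id)
        nxt <- c(nxt, id)
      }
    }
    level <- nxt
  }
  for (id in names(topics)) {
    topics[[id]]$is_leaf <- length(topics[[id]]$children) == 0L
    topics[[id]]$block <- topic_word_name(id, seq_len(config$vocab_per_topic))
  }
  shared <- sprintf("sharedw%02d", seq_len(config$vocab_per_topic))
  # synonym pairs: consecutive private-block words of every non-root topic
  syn <- character(0)
  for (id in setdiff(names(topics), "root")) {
    blk <- topics[[id]]$block
    odd <- blk[seq(1L, length(blk), 2L)]
    even <- blk[seq(2L, length(blk), 2L)]
    syn[odd] <- even
    syn[even] <- odd
  }
  vocab <- c(unlist(lapply(topics, `[[`, "block"), use.names = FALSE), shared)
  sf <- config$shared_fraction
  for (id in setdiff(names(topics), "root")) {
    t <- topics[[id]]
    topics[[id]]$dist <- local({
      w <- stats::setNames(numeric(0), character(0))
      if (t$parent != "root") {
        w[t$block] <- 0.8 * (1 - sf) / length(t$block)
        pb <- topics[[t$parent]]$block
        w[pb] <- 0.2 * (1 - sf) / length(pb)
      } else {
        w[t$block] <- (1 - sf) / length(t$block)
      }
      w[shared] <- sf / length(shared)
      w / sum(w)
    })
  }
  structure(list(topics = topics, shared = shared, synonyms = syn,
                 vocab = vocab, config = config),
            class = "topic_tree")
}

#' Generate the planted lexicon and reference taxonomy
#'
#' Plants one terminology per topic with several surface phrase variants
#' (adjective+noun, noun+noun, bare noun, and a plural), all mapping to the
#' same terminology id, and a reference taxonomy that mirrors the true topic
#' tree over the terminology ids. The returned tag dictionary drives the
#' bundled dictionary tagger.
#'
#' @param tree A [generate_topic_tree()] result.
#' @return List: `lexicon` (a `concept_lexicon`), `taxonomy` (a
#'   `reference_taxonomy`), `concepts` (per topic: `term_id`, `term_name`,
#'   `variants` as token-vector list), `tag_dict` (word -> POS class).
#' @export
generate_lexicon_and_reference <- function(tree) {
  topics <- tree$topics
  concepts <- list()
  phrases <- character(0); term_ids <- character(0); term_names <- character(0)
  for (id in names(topics)) {
    stem <- paste0("c", gsub("\\.", "x", id))
    term_id <- paste0("T_", id)
    term_name <- paste("condition", id)
    variants <- list(c(stem),
                     c("chronic", stem),
                     c(stem, "ache"),
                     c(paste0(stem, "s")))
    concepts[[id]] <- list(term_id = term_id, term_name = term_name,
                           stem = stem, variants = variants)
    phr <- vapply(variants, paste, character(1), collapse = " ")
    phrases <- c(phrases, phr)
    term_ids <- c(term_ids, rep(term_id, length(phr)))
    term_names <- c(term_names, rep(term_name, length(phr)))
  }
  lexicon <- concept_lexicon(phrases, term_ids, term_names,
                             rep("disease or syndrome", length(phrases)))
  non_root <- setdiff(names(topics), "root")
  taxonomy <- reference_taxonomy(
    parent = vapply(non_root, function(id) paste0("T_", topics[[id]]$parent),
                    character(1)),
    child = paste0("T_", non_root),
    names = stats::setNames(
      vapply(concepts, `[[`, character(1), "term_name"),
      vapply(concepts, `[[`, character(1), "term_id")))
  # alternate noun/other tags over the topic vocabulary so noun-phrase spans
  # stay short, as in natural text where roughly half the tokens are not
  # nominal
  vocab_tags <- rep(c("N", "O"), length.out = length(tree$vocab))
  tag_dict <- c(stats::setNames(vocab_tags, tree$vocab),
                chronic = "A", ache = "N")
  stems <- vapply(concepts, `[[`, character(1), "stem")
  tag_dict[stems] <- "N"
  tag_dict[paste0(stems, "s")] <- "N"
  list(lexicon = lexicon, taxonomy = taxonomy, concepts = concepts,
       tag_dict = tag_dict)
}

sample_dist <- function(dist, n) {
  if (n <= 0L) return(character(0))
  sample(names(dist), n, replace = TRUE, prob = dist)
}

# One synthetic record's texts from a token budget and topic distribution(s).
compose_record <- function(id, dists, concepts_to_inject, config) {
  len <- max(8L, stats::rnbinom(1L, mu = config$doc_length_mean,
                                size = config$doc_length_dispersion))
  draw <- function(n) {
    if (length(dists) == 1L) return(sample_dist(dists[[1L]], n))
    # 50/50 blend of two sibling leaves
    pick <- stats::rbinom(n, 1L, 0.5)
    out <- character(n)
    out[pick == 1L] <- sample_dist(dists[[1L]], sum(pick))
    out[pick == 0L] <- sample_dist(dists[[2L]], n - sum(pick))
    out
  }
  q_len <- max(4L, round(0.4 * len))
  q <- draw(q_len)
  # concept phrases are injected as their own clause so they surface as
  # noun-phrase spans rather than fusing with neighboring tokens
  for (ph in concepts_to_inject) {
    pos <- sample.int(length(q) + 1L, 1L) - 1L
    q <- append(q, c(".", ph, "."), after = pos)
  }
  n_ans <- sample(0:2, 1L)
  remaining <- max(0L, len - q_len)
  answers <- character(0)
  if (n_ans > 0L && remaining > 0L) {
    per <- ceiling(remaining / n_ans)
    answers <- vapply(seq_len(n_ans), function(i) {
      paste(draw(per), collapse = " ")
    }, character(1))
  }
  tags <- draw(sample(1:3, 1L))
  qa_record(id, paste(q, collapse = " "), answers = answers, tags = tags)
}

#' Generate the synthetic corpus, ground truth and domain prior
#'
#' Each leaf topic emits `docs_per_leaf` records; a `mixture_rate` fraction
#' are 50/50 blends of two sibling leaves (two true memberships). Planted
#' concept phrases are injected into the question at the configured rates.
#' Seed exemplars for the domain prior are generated per first-level category
#' from pure records of its leaves.
#'
#' @param tree A [generate_topic_tree()] result.
#' @param planted A [generate_lexicon_and_reference()] result.
#' @param config A [generator_config()]; the seed controls everything.
#' @return List: `corpus` (a `qa_corpus`), `prior` (a [domain_prior()]),
#'   `truth` (per-record true leaf memberships and categories, per-topic
#'   planted terminology).
#' @export
generate_corpus <- function(tree, planted, config = generator_config()) {
  topics <- tree$topics
  leaves <- names(Filter(function(t) t$is_leaf, topics))
  categories <- topics$root$children
  with_seed(derive_seed(config$seed, "corpus"), {
    records <- list()
    memberships <- list()
    category_of <- list()
    idx <- 0L
    for (leaf in leaves) {
      cat1 <- node_category(topics, leaf)
      sibs <- setdiff(topics[[topics[[leaf]]$parent]]$children, leaf)
      for (j in seq_len(config$docs_per_leaf)) {
        idx <- idx + 1L
        id <- sprintf("r%05d", idx)
        mixed <- length(sibs) > 0L && stats::runif(1L) < config$mixture_rate
        mem <- leaf
        dists <- list(topics[[leaf]]$dist)
        if (mixed) {
          other <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
          mem <- c(leaf, other)
          dists <- list(topics[[leaf]]$dist, topics[[other]]$dist)
        }
        inject <- list()
        if (stats::runif(1L) < config$concept_rate) {
          v <- planted$concepts[[leaf]]$variants
          inject <- c(inject, list(v[[sample.int(length(v), 1L)]]))
        }
        if (stats::runif(1L) < config$category_concept_rate) {
          v <- planted$concepts[[cat1]]$variants
          inject <- c(inject, list(v[[sample.int(length(v), 1L)]]))
        }
        records[[id]] <- compose_record(id, dists, inject, config)
        memberships[[id]] <- mem
        category_of[[id]] <- unique(vapply(mem, function(m) {
          node_category(topics, m)
        }, character(1)))
      }
    }
    corpus <- qa_corpus(records)
    prior_cats <- stats::setNames(vector("list", length(categories)),
                                  paste0("cat_", categories))
    for (cat in categories) {
      cat_leaves <- leaves[vapply(leaves, function(l) {
        node_category(topics, l) == cat
      }, logical(1))]
      seeds <- lapply(seq_len(config$seeds_per_category), function(s) {
        leaf <- if (length(cat_leaves) == 1L) cat_leaves else sample(cat_leaves, 1L)
        inject <- list()
        if (stats::runif(1L) < config$concept_rate) {
          v <- planted$concepts[[leaf]]$variants
          inject <- list(v[[sample.int(length(v), 1L)]])
        }
        compose_record(sprintf("seed_%s_%03d", cat, s),
                       list(topics[[leaf]]$dist), inject, config)
      })
      prior_cats[[paste0("cat_", cat)]] <- seeds
    }
    truth <- list(
      memberships = memberships,
      categories = category_of,
      concepts = stats::setNames(
        vapply(planted$concepts, `[[`, character(1), "term_id"),
        names(planted$concepts)),
      leaves = leaves)
    list(corpus = corpus, prior = domain_prior(prior_cats), truth = truth)
  })
}

# First-level category ancestor of a topic id.
node_category <- function(topics, id) {
  while (!is.na(topics[[id]]$parent) && topics[[id]]$parent != "root") {
    id <- topics[[id]]$parent
  }
  id
}

#' Generate paraphrased queries with graded relevance
#'
#' Samples source records and paraphrases their question part by substituting
#' the configured fraction of tokens with their same-topic synonyms
#' (emulating the vocabulary gap). Gains: 2 for the source record, 1 for
#' records sharing a true leaf with it, 0 otherwise.
#'
#' @param corpus The generated `qa_corpus`.
#' @param truth The `truth` element of [generate_corpus()].
#' @param tree The [generate_topic_tree()] result (synonym table).
#' @param config A [generator_config()].
#' @param n_queries Number of queries.
#' @return List of queries: `id`, `text`, `source_id`, `gains` (named vector
#'   over all corpus record ids, exactly one 2).
#' @export
generate_queries <- function(corpus, truth, tree, config = generator_config(),
                             n_queries = 50L) {
  ids <- corpus_ids(corpus)
  with_seed(derive_seed(config$seed, "queries"), {
    src <- sample(ids, n_queries)
    lapply(seq_len(n_queries), function(qi) {
      rid <- src[qi]
      toks <- tokenize(corpus$records[[rid]]$question,
                       stopwords = character(0))
      has_syn <- which(toks %in% names(tree$synonyms))
      n_sub <- round(config$paraphrase_rate * length(has_syn))
      if (n_sub > 0L) {
        sub_at <- if (length(has_syn) == 1L) has_syn else
          sample(has_syn, n_sub)
        toks[sub_at] <- unname(tree$synonyms[toks[sub_at]])
      }
      src_leaves <- truth$memberships[[rid]]
      gains <- stats::setNames(rep(0, length(ids)), ids)
      same_leaf <- vapply(ids, function(i) {
        length(intersect(truth$memberships[[i]], src_leaves)) > 0L
      }, logical(1))
      gains[same_leaf] <- 1
      gains[rid] <- 2
      list(id = sprintf("q%03d", qi), text = paste(toks, collapse = " "),
           source_id = rid, gains = gains)
    })
  })
}

#' Write all synthetic artifacts to a directory
#'
#' Emits `corpus.jsonl`, `lexicon.tsv`, `reference.tsv`, `prior.json`,
#' `queries.jsonl` and `truth.json`.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if missing).
#' @param n_queries Number of paraphrased queries.
#' @return Invisibly, the list of generated objects.
#' @export
write_synthetic <- function(config = generator_config(), out_dir,
                            n_queries = 50L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- generate_topic_tree(config)
  planted <- generate_lexicon_and_reference(tree)
  gen <- generate_corpus(tree, planted, config)
  queries <- generate_queries(gen$corpus, gen$truth, tree, config, n_queries)
  write_corpus(gen$corpus, file.path(out_dir, "corpus.jsonl"))
  write_lexicon(planted$lexicon, file.path(out_dir, "lexicon.tsv"))
  utils::write.table(data.frame(word = names(planted$tag_dict),
                                tag = unname(planted$tag_dict)),
                     file.path(out_dir, "tags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_taxonomy(planted$taxonomy, file.path(out_dir, "reference.tsv"))
  write_prior(gen$prior, file.path(out_dir, "prior.json"))
  qlines <- vapply(queries, function(q) {
    jsonlite::toJSON(list(id = q$id, text = q$text, source_id = q$source_id,
                          relevant = names(q$gains)[q$gains == 1]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(qlines, file.path(out_dir, "queries.jsonl"), useBytes = TRUE)
  jsonlite::write_json(list(memberships = gen$truth$memberships,
                            categories = gen$truth$categories,
                            concepts = as.list(gen$truth$concepts),
                            leaves = gen$truth$leaves,
                            tag_dict = as.list(planted$tag_dict),
                            synonyms = as.list(tree$synonyms)),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(tree = tree, planted = planted, corpus = gen$corpus,
                 prior = gen$prior, truth = gen$truth, queries = queries))
}
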