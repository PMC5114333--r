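# Hierarchy construction: the prior-knowledge first layer (per-category
# margin classifiers over the weighted-term representation), then a
# breadth-first alternation of the shrinkage test and perplexity-tuned
# expansion, with multi-leaf record assignment.

#' Construct a domain prior
#'
#' Prior knowledge for the first layer: an ordered list of category names,
#' each with seed example records (positives) standing in for exemplars
#' harvested from a live service.
#'
#' @param categories Named list: one list of `qa_record` seeds per category
#'   name. At least 2 categories with at least 2 seeds each.
#' @return Object of class `domain_prior`.
#' @export
domain_prior <- function(categories) {
  if (length(categories) < 2L) stop_qa("domain prior needs >= 2 categories")
  if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stop_qa("categories must be named")
  }
  for (nm in names(categories)) {
    if (length(categories[[nm]]) < 2L) {
      stop_qa("category '%s' needs >= 2 seed examples", nm)
    }
  }
  structure(list(categories = categories), class = "domain_prior")
}

#' Read a domain prior from JSON
#'
#' Format: `{"categories": [{"name": ..., "seeds": [{record}, ...]}, ...]}`.
#'
#' @param path Path to a JSON file.
#' @return A `domain_prior`.
#' @export
read_prior <- function(path) {
  if (!file.exists(path)) stop_qa("prior file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cats <- list()
  for (cat in obj$categories) {
    cats[[cat$name]] <- lapply(cat$seeds, function(s) {
      qa_record(s$id, s$question,
                answers = unlist(s$answers %||% character(0)),
                tags = unlist(s$tags %||% character(0)))
    })
  }
  domain_prior(cats)
}

#' Write a domain prior to JSON
#' @param prior A `domain_prior`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prior <- function(prior, path) {
  obj <- list(categories = lapply(names(prior$categories), function(nm) {
    list(name = nm, seeds = lapply(prior$categories[[nm]], function(r) {
      list(id = r$id, question = r$question, answers = r$answers, tags = r$tags)
    }))
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the per-category first-layer classifiers
#'
#' For each category, trains a linear margin classifier (support-vector
#' machine) on its seed examples as positives against an equal-size seeded
#' random sample of the other categories' seeds as negatives, over the
#' l2-normalized weighted-term representation. The fitted hyperplane
#' (weights, offset) is extracted so classifiers serialize as plain numbers.
#'
#' @param prior A [domain_prior()].
#' @param config A [run_config()] (boost settings).
#' @param seed Integer seed for the negative sampling.
#' @param lexicon Optional `concept_lexicon` for term boosting.
#' @return Named list of class `category_classifiers`: per category a list
#'   `name`, `vocab`, `w`, `rho` with decision score `x . w - rho`.
#' @export
train_category_classifiers <- function(prior, config = run_config(),
                                       seed = 1L, lexicon = NULL) {
  boosted <- boosted_tokens(lexicon, config$boosted_groups)
  cats <- names(prior$categories)
  seed_tokens <- lapply(prior$categories, function(seeds) {
    lapply(seeds, function(r) {
      if (is.null(r$tokens)) r <- contextualize(r)
      r$tokens
    })
  })
  clfs <- vector("list", length(cats))
  names(clfs) <- cats
  for (ci in seq_along(cats)) {
    pos <- seed_tokens[[ci]]
    others <- unlist(seed_tokens[-ci], recursive = FALSE)
    n_neg <- min(length(pos), length(others))
    neg_idx <- with_seed(derive_seed(seed, paste0("neg-", cats[ci])),
                         sort(sample.int(length(others), n_neg)))
    neg <- others[neg_idx]
    docs <- c(pos, neg)
    vocab <- sort(unique(unlist(docs)))
    X <- matrix(0, length(docs), length(vocab),
                dimnames = list(NULL, vocab))
    for (i in seq_along(docs)) {
      w <- weighted_bag(docs[[i]], boosted, config$boost)
      if (length(w)) X[i, names(w)] <- w / sqrt(sum(w^2))
    }
    y <- factor(rep(c("pos", "neg"), c(length(pos), length(neg))),
                levels = c("pos", "neg"))
    fit <- e1071::svm(X, y, kernel = "linear", scale = FALSE)
    w_vec <- as.numeric(t(fit$coefs) %*% fit$SV)
    names(w_vec) <- vocab
    rho <- fit$rho
    # libsvm orients the decision toward the first label it meets; flip so
    # positives score > 0.
    dv <- X %*% w_vec - rho
    if (mean(dv[y == "pos"]) < mean(dv[y == "neg"])) {
      w_vec <- -w_vec; rho <- -rho
    }
    clfs[[ci]] <- list(name = cats[ci], vocab = vocab, w = w_vec, rho = rho)
  }
  structure(clfs, class = "category_classifiers")
}

# Decision scores of one token vector under every classifier.
classifier_scores <- function(classifiers, tokens, boosted = character(0),
                              boost = 2) {
  vapply(classifiers, function(clf) {
    w <- weighted_bag(tokens, boosted, boost)
    w <- w[names(w) %in% clf$vocab]
    if (!length(w)) return(-clf$rho)
    x <- w / sqrt(sum(w^2))
    sum(x * clf$w[names(x)]) - clf$rho
  }, numeric(1))
}

#' Categorize the corpus into the first layer
#'
#' Each record joins every category whose classifier fires (positive decision
#' score); a record firing none goes to its best-scoring category, so the
#' first layer always covers the corpus. With `multi = FALSE` only the
#' best-scoring fired category is kept.
#'
#' @param corpus A contextualized `qa_corpus`.
#' @param classifiers From [train_category_classifiers()].
#' @param multi Allow multi-category membership (default `TRUE`).
#' @param lexicon,config Term-boost settings matching training.
#' @return Named list: record ids per category (empty categories dropped).
#' @export
build_first_layer <- function(corpus, classifiers, multi = TRUE,
                              lexicon = NULL, config = run_config()) {
  boosted <- boosted_tokens(lexicon, config$boosted_groups)
  ids <- corpus_ids(corpus)
  members <- stats::setNames(vector("list", length(classifiers)),
                             names(classifiers))
  for (id in ids) {
    sc <- classifier_scores(classifiers, corpus$records[[id]]$tokens,
                            boosted, config$boost)
    fired <- which(sc > 0)
    if (!length(fired)) fired <- which.max(sc)
    if (!multi && length(fired) > 1L) fired <- fired[which.max(sc[fired])]
    for (f in fired) members[[f]] <- c(members[[f]], id)
  }
  members[lengths(members) > 0L]
}

new_node <- function(id, parent, members, depth, name = NULL) {
  list(id = id, parent = parent, name = name, children = character(0),
       members = members, depth = depth, model = NULL, child_topics = NULL,
       labels = NULL, stats = NULL)
}

#' Build the full topic hierarchy
#'
#' Constructs the profiled hierarchy top-down: the domain-prior first layer,
#' then a breadth-first traversal where each node is (1) kept as a leaf if it
#' is smaller than `min_node_size`, at the depth cap, or fails the shrinkage
#' test; or (2) expanded by fitting a topic model whose child count minimizes
#' held-out perplexity, with each record assigned to its leading child
#' topics. If a lexicon and tagger are supplied every node is then labeled
#' with ranked terminologies.
#'
#' @param corpus A `qa_corpus` (contextualized automatically if needed).
#' @param prior A [domain_prior()].
#' @param config A [run_config()].
#' @param lexicon Optional `concept_lexicon` (boosting + labeling).
#' @param tagger Optional POS tagger for labeling.
#' @return Object of class `qa_hierarchy`: `root`, `nodes` (named list),
#'   `classifiers`, `config`.
#' @export
build_hierarchy <- function(corpus, prior, config = run_config(),
                            lexicon = NULL, tagger = NULL) {
  if (!length(corpus$records)) stop_qa("empty corpus")
  if (is.null(corpus$records[[1L]]$tokens)) {
    corpus <- contextualize_corpus(corpus)
  }
  seed <- config$seed
  classifiers <- train_category_classifiers(prior, config,
                                            seed = derive_seed(seed, "svm"),
                                            lexicon = lexicon)
  nodes <- list(root = new_node("root", NA_character_, corpus_ids(corpus), 0L))
  first <- build_first_layer(corpus, classifiers,
                             multi = config$multi_membership,
                             lexicon = lexicon, config = config)
  queue <- character(0)
  for (i in seq_along(first)) {
    id <- paste0("root.", i)
    nodes[[id]] <- new_node(id, "root", first[[i]], 1L, name = names(first)[i])
    nodes$root$children <- c(nodes$root$children, id)
    queue <- c(queue, id)
  }
  while (length(queue)) {
    nid <- queue[[1L]]
    queue <- queue[-1L]
    node <- nodes[[nid]]
    if (length(node$members) < config$min_node_size) next
    if (node$depth >= config$depth_cap) next
    docs <- record_tokens(corpus, node$members)
    node_seed <- derive_seed(seed, paste0("node-", nid))
    dec <- should_expand(docs, delta = config$delta, config = config,
                         seed = node_seed, lexicon = lexicon)
    nodes[[nid]]$stats <- dec$stats
    if (!dec$expand) next
    kmax <- min(config$k_range[2], length(docs) - 2L)
    if (kmax < config$k_range[1]) next
    rep_k <- select_child_count(docs, k_range = c(config$k_range[1], kmax),
                                holdout_fraction = config$holdout_fraction,
                                seed = node_seed, alpha = config$alpha,
                                eta = config$eta, n_iter = config$gibbs_iter)
    model <- fit_topic_model(docs, rep_k$selected_k, alpha = config$alpha,
                             eta = config$eta, n_iter = config$gibbs_iter,
                             seed = derive_seed(node_seed, "full-fit"))
    membership <- assign_records(model, multi = config$multi_membership)
    if (length(membership) < 2L) next  # degenerate expansion: stay a leaf
    nodes[[nid]]$model <- model
    nodes[[nid]]$child_topics <- as.integer(names(membership))
    for (j in seq_along(membership)) {
      cid <- paste0(nid, ".", j)
      nodes[[cid]] <- new_node(cid, nid, membership[[j]], node$depth + 1L)
      nodes[[nid]]$children <- c(nodes[[nid]]$children, cid)
      queue <- c(queue, cid)
    }
  }
  h <- structure(list(root = "root", nodes = nodes, classifiers = classifiers,
                      config = config), class = "qa_hierarchy")
  if (!is.null(lexicon) && !is.null(tagger)) {
    h <- label_hierarchy(h, corpus, lexicon, tagger)
  }
  h
}

#' @export
print.qa_hierarchy <- function(x, ...) {
  depths <- vapply(x$nodes, function(n) n$depth, integer(1))
  leaves <- vapply(x$nodes, function(n) length(n$children) == 0L, logical(1))
  cat(sprintf("<qa_hierarchy> %d nodes (%d leaves), depth %d\n",
              length(x$nodes), sum(leaves), max(depths)))
  invisible(x)
}

#' Leaf node ids of a hierarchy
#' @param hierarchy A `qa_hierarchy`.
#' @return Character vector of node ids with no children.
#' @export
hierarchy_leaves <- function(hierarchy) {
  names(Filter(function(n) length(n$children) == 0L, hierarchy$nodes))
}

#' Validate the tree structure of a hierarchy
#'
#' Checks the structural invariants: a single root, acyclic parent links,
#' parent/child consistency, child membership contained in the parent's, and
#' children jointly covering the parent.
#'
#' @param hierarchy A `qa_hierarchy`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_hierarchy <- function(hierarchy) {
  nodes <- hierarchy$nodes
  roots <- names(Filter(function(n) is.na(n$parent), nodes))
  if (!identical(roots, hierarchy$root)) stop_qa("hierarchy must have exactly one root")
  for (nid in names(nodes)) {
    n <- nodes[[nid]]
    for (cid in n$children) {
      child <- nodes[[cid]]
      if (is.null(child)) stop_qa("node %s lists missing child %s", nid, cid)
      if (!identical(child$parent, nid)) stop_qa("parent link broken at %s", cid)
      if (!all(child$members %in% n$members)) {
        stop_qa("child %s has members outside its parent", cid)
      }
    }
    if (length(n$children)) {
      cover <- unique(unlist(lapply(nodes[n$children], `[[`, "members")))
      if (!setequal(cover, n$members)) {
        stop_qa("children of %s do not cover it", nid)
      }
    }
    # walk to root: cycle check
    seen <- character(0); cur <- nid
    while (!is.na(nodes[[cur]]$parent)) {
      if (cur %in% seen) stop_qa("cycle at %s", cur)
      seen <- c(seen, cur)
      cur <- nodes[[cur]]$parent
    }
  }
  invisible(TRUE)
}

# ---- serialization -------------------------------------------------------

model_to_list <- function(m) {
  if (is.null(m)) return(NULL)
  list(k = m$k, vocab = m$vocab,
       topic_word = unname(m$topic_word),
       doc_ids = rownames(m$doc_topic),
       doc_topic = unname(m$doc_topic),
       alpha = m$alpha, eta = m$eta, seed = m$seed)
}

model_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  tw <- do.call(rbind, lapply(l$topic_word, unlist))
  colnames(tw) <- unlist(l$vocab)
  dt <- do.call(rbind, lapply(l$doc_topic, unlist))
  rownames(dt) <- unlist(l$doc_ids)
  structure(list(k = as.integer(l$k), vocab = unlist(l$vocab),
                 topic_word = tw, doc_topic = dt,
                 alpha = l$alpha, eta = l$eta, seed = as.integer(l$seed)),
            class = "topic_model")
}

#' Write a hierarchy store to JSON
#'
#' Single JSON document holding the tree (parents, children, members,
#' labels), the per-node model checkpoints, the extracted first-layer
#' classifiers and the configuration snapshot. Full double precision is
#' retained, so a rebuild under the same seed round-trips byte-identically.
#'
#' @param hierarchy A `qa_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, path) {
  nodes <- lapply(hierarchy$nodes, function(n) {
    list(id = n$id, parent = if (!is.na(n$parent)) n$parent,
         name = n$name, children = n$children,
         members = n$members, depth = n$depth,
         child_topics = n$child_topics,
         labels = n$labels,
         model = model_to_list(n$model))
  })
  clfs <- lapply(hierarchy$classifiers, function(c) {
    list(name = c$name, vocab = c$vocab, w = unname(c$w), rho = c$rho)
  })
  obj <- list(root = hierarchy$root, nodes = nodes, classifiers = clfs,
              config = config_snapshot(hierarchy$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a hierarchy store from JSON
#' @param path Path written by [write_hierarchy()].
#' @return A `qa_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop_qa("hierarchy store not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- lapply(obj$nodes, function(n) {
    nd <- new_node(n$id, n$parent %||% NA_character_,
                   unlist(n$members) %||% character(0),
                   as.integer(n$depth), name = n$name)
    nd$children <- unlist(n$children) %||% character(0)
    nd$child_topics <- if (!is.null(n$child_topics)) as.integer(unlist(n$child_topics))
    nd$labels <- if (!is.null(n$labels)) {
      do.call(rbind, lapply(n$labels, function(l) {
        data.frame(term_id = l$term_id, term_name = l$term_name,
                   score = l$score, stringsAsFactors = FALSE)
      }))
    }
    nd$model <- model_from_list(n$model)
    nd
  })
  names(nodes) <- vapply(nodes, `[[`, character(1), "id")
  clfs <- lapply(obj$classifiers, function(c) {
    w <- unlist(c$w); names(w) <- unlist(c$vocab)
    list(name = c$name, vocab = unlist(c$vocab), w = w, rho = c$rho)
  })
  names(clfs) <- vapply(clfs, `[[`, character(1), "name")
  structure(list(root = obj$root, nodes = nodes,
                 classifiers = structure(clfs, class = "category_classifiers"),
                 config = config_from_snapshot(obj$config)),
            class = "qa_hierarchy")
}
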