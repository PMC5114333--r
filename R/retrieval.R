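# Hierarchy-routed retrieval: treat the query as a QA record, route it from
# the first layer down to leaves via the per-node topic models, pool the leaf
# members, and rerank them by a graph random walk over the fused similarity.

#' Turn a query string into a contextualized record
#'
#' A newly incoming query carries only a question part.
#'
#' @param text Query text.
#' @param stopwords Stop-word list for normalization.
#' @return A contextualized `qa_record` with id `"query"`.
#' @export
qa_query <- function(text, stopwords = default_stopwords()) {
  contextualize(qa_record("query", text), stopwords = stopwords)
}

# Ancestor chain of a node, root first.
node_chain <- function(hierarchy, nid) {
  chain <- character(0)
  while (!is.na(nid)) {
    chain <- c(nid, chain)
    nid <- hierarchy$nodes[[nid]]$parent
  }
  chain
}

#' Route a query to leaf nodes
#'
#' First layer: categories whose classifier fires (best-scoring category when
#' none fires). Below that, at every node with a model the query's topic
#' mixture is inferred and the leading child topics decide which children to
#' descend into. Returns all reached leaves.
#'
#' @param hierarchy A built `qa_hierarchy` with per-node models.
#' @param query A contextualized `qa_record` (see [qa_query()]).
#' @param lexicon Optional `concept_lexicon` (classifier term boosting).
#' @return Character vector of leaf node ids.
#' @export
route_query <- function(hierarchy, query, lexicon = NULL) {
  config <- hierarchy$config
  boosted <- boosted_tokens(lexicon, config$boosted_groups)
  first_ids <- hierarchy$nodes[[hierarchy$root]]$children
  if (!length(first_ids)) return(hierarchy$root)
  sc <- classifier_scores(hierarchy$classifiers, query$tokens, boosted,
                          config$boost)
  vocab_all <- unique(unlist(lapply(hierarchy$classifiers, `[[`, "vocab")))
  if (!any(query$tokens %in% vocab_all)) {
    warning("query shares no vocabulary with the first-layer classifiers; ",
            "routing to all first-layer branches")
    entry <- seq_along(first_ids)
  } else {
    fired <- which(sc > 0)
    if (!length(fired)) fired <- which.max(sc)
    if (!config$multi_membership && length(fired) > 1L) {
      fired <- fired[which.max(sc[fired])]
    }
    # first-layer nodes are ordered like the classifier list, but empty
    # categories were dropped; map by stored category name
    cat_names <- vapply(hierarchy$nodes[first_ids], function(n) n$name %||% "",
                        character(1))
    entry <- match(names(hierarchy$classifiers)[fired], cat_names)
    entry <- entry[!is.na(entry)]
    if (!length(entry)) entry <- seq_along(first_ids)
  }
  leaves <- character(0)
  queue <- first_ids[entry]
  while (length(queue)) {
    nid <- queue[[1L]]; queue <- queue[-1L]
    node <- hierarchy$nodes[[nid]]
    if (!length(node$children)) {
      leaves <- c(leaves, nid)
      next
    }
    post <- infer_mixture(node$model, query)
    lead <- leading_nodes(post)
    sel <- which(node$child_topics %in% lead)
    if (!length(sel)) {
      # every leading topic's child was dropped as empty: take the best
      # surviving child topic
      sel <- which.max(post[node$child_topics])
    }
    queue <- c(queue, node$children[sel])
  }
  unique(leaves)
}

# Deepest ancestor of `nid` (inclusive) that carries a model; NA when none.
deepest_model_node <- function(hierarchy, nid) {
  chain <- rev(node_chain(hierarchy, nid))
  for (id in chain) {
    if (!is.null(hierarchy$nodes[[id]]$model)) return(id)
  }
  NA_character_
}

#' Initial relevance scores of candidates for a query
#'
#' The initialized score of each candidate is its fused kernel similarity to
#' the query: the weighted-term cosine plus, when weighted, the topical
#' component computed under the model of the deepest ancestor node of the
#' candidate's leaf that carries one (0 when none exists). With
#' `config$initial_score_kernel = "phi1"` only the lexical kernel is used.
#'
#' @param query A contextualized `qa_record`.
#' @param candidates Character vector of candidate record ids.
#' @param cand_leaf Leaf node id each candidate was pooled from.
#' @param hierarchy The `qa_hierarchy`.
#' @param corpus The `qa_corpus`.
#' @param lexicon Optional `concept_lexicon`.
#' @return Named numeric vector of scores, clipped to `>= 0`.
#' @export
initial_scores <- function(query, candidates, cand_leaf, hierarchy, corpus,
                           lexicon = NULL) {
  config <- hierarchy$config
  betas <- config$betas
  boosted <- boosted_tokens(lexicon, config$boosted_groups)
  qbag <- weighted_bag(query$tokens, boosted, config$boost)
  phi1 <- vapply(candidates, function(id) {
    cosine_bags(qbag, weighted_bag(corpus$records[[id]]$tokens, boosted,
                                   config$boost))
  }, numeric(1))
  if (config$initial_score_kernel == "phi1" || betas$beta3 == 0) {
    y <- phi1
  } else {
    model_node <- vapply(cand_leaf, function(l) deepest_model_node(hierarchy, l),
                         character(1))
    qmix <- list()
    phi3_sim <- numeric(length(candidates))
    for (i in seq_along(candidates)) {
      mn <- model_node[i]
      if (is.na(mn)) { phi3_sim[i] <- 0; next }
      model <- hierarchy$nodes[[mn]]$model
      if (is.null(qmix[[mn]])) qmix[[mn]] <- infer_mixture(model, query)
      theta_c <- model$doc_topic[candidates[i], ]
      phi3_sim[i] <- js_to_similarity(topic_kernel(qmix[[mn]],
                                                   theta_c / sum(theta_c)))
    }
    # the syntactic component of an initial score is omitted unless tuned in:
    # query-side parses are config-dependent and beta2 defaults to 0
    wsum <- betas$beta1 + betas$beta3
    y <- (betas$beta1 * phi1 + betas$beta3 * phi3_sim) / max(wsum, 1e-12)
  }
  y[y < 0] <- 0
  stats::setNames(y, candidates)
}

#' Graph random-walk reranking
#'
#' Fixed-point iteration of
#' `y = W D^{-1} y / (1 + lambda) + lambda ybar / (1 + lambda)`
#' starting from `y = ybar`, until the max-norm change drops below `tol` or
#' `max_iter` sweeps. The iteration is a contraction for `lambda > 0` (the
#' column-normalized `W D^{-1}` has unit norm), so it matches the direct
#' solution of the underlying regularized objective. Isolated candidates
#' (zero row sum) bypass the walk and keep their initial score.
#'
#' @param W Symmetric nonnegative similarity matrix (zero diagonal).
#' @param y_bar Initial relevance scores.
#' @param lambda Positive weighting parameter.
#' @param tol Max-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @param bypass_isolated Keep `y = y_bar` for zero-degree candidates
#'   (default `TRUE`; disable to exercise the pure fixed point).
#' @return Numeric vector `y` with attributes `iterations`, `residual`,
#'   `converged`.
#' @export
random_walk_rank <- function(W, y_bar, lambda = 0.1, tol = 1e-8,
                             max_iter = 500L, bypass_isolated = TRUE) {
  if (lambda <= 0) stop_qa("lambda must be positive")
  n <- length(y_bar)
  stopifnot(nrow(W) == n, ncol(W) == n)
  d <- rowSums(W)
  active <- if (bypass_isolated) which(d > 0) else seq_len(n)
  y <- y_bar
  iters <- 0L
  res <- 0
  if (length(active)) {
    Wa <- W[active, active, drop = FALSE]
    da <- d[active]
    da[da == 0] <- 1  # only reachable with bypass disabled
    ya <- y_bar[active]
    yc <- ya
    a <- 1 / (1 + lambda)
    b <- lambda / (1 + lambda)
    for (it in seq_len(max_iter)) {
      ynew <- a * as.numeric(Wa %*% (yc / da)) + b * ya
      res <- max(abs(ynew - yc))
      yc <- ynew
      iters <- it
      if (res < tol) break
    }
    if (res >= tol) warning("random walk did not converge in ", max_iter,
                            " iterations (residual ", signif(res, 3), ")")
    y[active] <- yc
  }
  attr(y, "iterations") <- iters
  attr(y, "residual") <- res
  attr(y, "converged") <- res < tol
  y
}

# Candidate-graph similarity matrix for reranking: weighted-term cosine plus
# the topical kernel under the deepest shared ancestor model of each pair.
candidate_graph <- function(candidates, cand_leaf, hierarchy, corpus,
                            lexicon = NULL) {
  config <- hierarchy$config
  betas <- config$betas
  boosted <- boosted_tokens(lexicon, config$boosted_groups)
  toks <- lapply(corpus$records[candidates], `[[`, "tokens")
  n <- length(candidates)
  W <- matrix(0, n, n)
  wsum <- 0
  if (betas$beta1 > 0) {
    W <- W + betas$beta1 * phi1_matrix(toks, boosted, config$boost)
    wsum <- wsum + betas$beta1
  }
  if (betas$beta3 > 0) {
    chains <- lapply(cand_leaf, function(l) node_chain(hierarchy, l))
    model_node <- vapply(cand_leaf, function(l) deepest_model_node(hierarchy, l),
                         character(1))
    if (length(unique(model_node)) == 1L && !is.na(model_node[1L])) {
      # common case: one shared model -> vectorized pairwise JS
      model <- hierarchy$nodes[[model_node[1L]]]$model
      theta <- model$doc_topic[candidates, , drop = FALSE]
      theta <- theta / rowSums(theta)
      S3 <- js_to_similarity(js_matrix(theta))
      diag(S3) <- 0
      W <- W + betas$beta3 * S3
      wsum <- wsum + betas$beta3
      if (wsum > 0) W <- W / wsum
      diag(W) <- 0
      dimnames(W) <- list(candidates, candidates)
      return(W)
    }
    S3 <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        common <- intersect(chains[[i]], chains[[j]])
        mn <- NA_character_
        for (id in rev(common)) {
          if (!is.null(hierarchy$nodes[[id]]$model)) { mn <- id; break }
        }
        if (is.na(mn)) next
        model <- hierarchy$nodes[[mn]]$model
        ti <- model$doc_topic[candidates[i], ]
        tj <- model$doc_topic[candidates[j], ]
        S3[i, j] <- S3[j, i] <-
          js_to_similarity(topic_kernel(ti / sum(ti), tj / sum(tj)))
      }
    }
    W <- W + betas$beta3 * S3
    wsum <- wsum + betas$beta3
  }
  if (wsum > 0) W <- W / wsum
  diag(W) <- 0
  dimnames(W) <- list(candidates, candidates)
  W
}

#' Hierarchy-routed search
#'
#' Routes the query to leaves, pools their member records (deduplicated),
#' scores them with the fused kernel, reranks by the graph random walk and
#' returns the top `n` (ties broken by record id).
#'
#' @param hierarchy A built (and typically labeled) `qa_hierarchy`.
#' @param corpus The contextualized `qa_corpus` it was built on.
#' @param query Query text or a contextualized `qa_record`.
#' @param n Number of results.
#' @param lexicon Optional `concept_lexicon`.
#' @return Data frame `id`, `score`, ranked; attribute `"leaves"` holds the
#'   reached leaf ids.
#' @export
search_hierarchy <- function(hierarchy, corpus, query, n = 10L,
                             lexicon = NULL) {
  if (is.character(query)) query <- qa_query(query)
  config <- hierarchy$config
  leaves <- route_query(hierarchy, query, lexicon = lexicon)
  pool <- unlist(lapply(leaves, function(l) {
    ids <- hierarchy$nodes[[l]]$members
    stats::setNames(rep(l, length(ids)), ids)
  }))
  if (!length(pool)) {
    warning("empty candidate pool")
    return(structure(data.frame(id = character(0), score = numeric(0)),
                     leaves = leaves))
  }
  keep <- !duplicated(names(pool))
  cand <- names(pool)[keep]
  cand_leaf <- unname(pool[keep])
  y_bar <- initial_scores(query, cand, cand_leaf, hierarchy, corpus, lexicon)
  W <- candidate_graph(cand, cand_leaf, hierarchy, corpus, lexicon)
  y <- random_walk_rank(W, y_bar, lambda = config$lambda,
                        tol = config$walk_tol,
                        max_iter = config$walk_max_iter)
  ord <- order(-y, cand)
  out <- data.frame(id = cand[ord], score = as.numeric(y)[ord],
                    stringsAsFactors = FALSE)[seq_len(min(n, length(cand))), ]
  rownames(out) <- NULL
  structure(out, leaves = leaves)
}

#' Flat term-matching baseline
#'
#' Ranks the whole corpus by weighted-term cosine to the query; the
#' comparison point for hierarchy-routed retrieval.
#'
#' @param corpus A contextualized `qa_corpus`.
#' @param query Query text or a contextualized `qa_record`.
#' @param n Number of results.
#' @param lexicon Optional `concept_lexicon`.
#' @param boost,boosted_groups Term-boost settings.
#' @return Data frame `id`, `score`, ranked.
#' @export
flat_search <- function(corpus, query, n = 10L, lexicon = NULL, boost = 2,
                        boosted_groups = run_config()$boosted_groups) {
  if (is.character(query)) query <- qa_query(query)
  boosted <- boosted_tokens(lexicon, boosted_groups)
  qbag <- weighted_bag(query$tokens, boosted, boost)
  ids <- corpus_ids(corpus)
  sc <- vapply(ids, function(id) {
    cosine_bags(qbag, weighted_bag(corpus$records[[id]]$tokens, boosted, boost))
  }, numeric(1))
  ord <- order(-sc, ids)
  out <- data.frame(id = ids[ord], score = sc[ord],
                    stringsAsFactors = FALSE)[seq_len(min(n, length(ids))), ]
  rownames(out) <- NULL
  out
}
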