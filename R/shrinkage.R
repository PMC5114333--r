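# Shrinkage termination test and multi-leaf record assignment:
# - trial bipartition of a node and its inter/intra relation statistics,
#   against the termination threshold delta;
# - the leading-gap heuristic picking how many child topics a record joins.

#' Trial bipartition of a node
#'
#' Fits a 2-topic model on the member documents and assigns each to its
#' argmax topic. If one side comes out empty the split falls back to a
#' balanced split by first-topic probability rank.
#'
#' @param docs Named list of member token vectors (names are record ids).
#' @param seed Integer seed.
#' @param alpha,eta,n_iter Passed to [fit_topic_model()].
#' @return List of class `bipartition`: `a`, `b` (id vectors, union = all
#'   members), `theta` (members x 2 mixture matrix), `model`.
#' @export
bipartition <- function(docs, seed = 1L, alpha = NULL, eta = 0.01,
                        n_iter = 150L) {
  if (length(docs) < 4L) stop_qa("bipartition needs at least 4 members")
  if (is.null(names(docs))) names(docs) <- as.character(seq_along(docs))
  model <- fit_topic_model(docs, 2L, alpha = alpha, eta = eta,
                           n_iter = n_iter, seed = seed)
  theta <- model$doc_topic
  side <- max.col(theta, ties.method = "first")
  if (length(unique(side)) < 2L) {
    ord <- order(theta[, 1L], decreasing = TRUE)
    side <- integer(length(docs))
    side[ord[seq_len(ceiling(length(docs) / 2))]] <- 1L
    side[side == 0L] <- 2L
  }
  structure(list(a = names(docs)[side == 1L], b = names(docs)[side == 2L],
                 theta = theta, model = model),
            class = "bipartition")
}

#' Average pairwise relation between two record sets
#'
#' `R(A, B) = (1 / (|A| |B|)) * sum_{i in A, j in B} S(x_i, x_j)` over the
#' full cross product. When the sets overlap, identity pairs enter the sum
#' with `S(x, x) = 1` per the literal formula.
#'
#' @param set_a,set_b Nonempty id vectors.
#' @param sim Either a similarity matrix with id dimnames, or a function
#'   `function(id_i, id_j) -> numeric`.
#' @return Nonnegative real.
#' @export
avg_relation <- function(set_a, set_b, sim) {
  if (!length(set_a) || !length(set_b)) stop_qa("avg_relation on an empty set")
  if (is.matrix(sim)) {
    S <- sim[set_a, set_b, drop = FALSE]
    same <- outer(set_a, set_b, "==")
    S[same] <- 1
    mean(S)
  } else {
    total <- 0
    for (i in set_a) for (j in set_b) {
      total <- total + if (identical(i, j)) 1 else sim(i, j)
    }
    total / (length(set_a) * length(set_b))
  }
}

#' Inter- and intra-node relations of a bipartition
#'
#' Normalized relations of a trial split of node `V = A U B`:
#' `inter = R(A,B)/R(A,V) + R(A,B)/R(B,V)` and
#' `intra = R(A,A)/R(A,V) + R(B,B)/R(B,V)`. A strong inter-node relation
#' means the two trial children are indivisible and the node should stay a
#' leaf.
#'
#' @param part A [bipartition()] (or list with `a`, `b`).
#' @param members Id vector of the parent node `V` (defaults to `A U B`).
#' @param sim Similarity matrix or function as in [avg_relation()].
#' @return List of class `relation_stats`: `r_ab`, `r_av`, `r_bv`, `r_aa`,
#'   `r_bb`, `inter`, `intra`, `degenerate`.
#' @export
inter_intra <- function(part, members = NULL, sim) {
  a <- part$a; b <- part$b
  if (is.null(members)) members <- union(a, b)
  r_ab <- avg_relation(a, b, sim)
  r_av <- avg_relation(a, members, sim)
  r_bv <- avg_relation(b, members, sim)
  r_aa <- avg_relation(a, a, sim)
  r_bb <- avg_relation(b, b, sim)
  degenerate <- (r_av <= 0 || r_bv <= 0)
  structure(list(
    r_ab = r_ab, r_av = r_av, r_bv = r_bv, r_aa = r_aa, r_bb = r_bb,
    inter = if (degenerate) NA_real_ else r_ab / r_av + r_ab / r_bv,
    intra = if (degenerate) NA_real_ else r_aa / r_av + r_bb / r_bv,
    degenerate = degenerate
  ), class = "relation_stats")
}

# Fused similarity matrix over a node's members from their tokens and the
# trial model's mixtures; ids as dimnames.
node_similarity <- function(docs, theta, config, lexicon = NULL,
                            trees = NULL) {
  sm <- similarity_matrix(docs, config$betas, theta = theta, trees = trees,
                          lexicon = lexicon, boost = config$boost,
                          boosted_groups = config$boosted_groups,
                          phi3_polarity = config$phi3_polarity)
  W <- sm$W
  dimnames(W) <- list(names(docs), names(docs))
  W
}

#' Shrinkage decision for a node
#'
#' Trial-bipartitions the node, estimates the inter-node relation on the
#' fused similarity and stops expansion when `inter > delta` (strictly), or
#' when the statistics are degenerate. For nodes larger than `sample_max`
#' members the statistics are estimated on a seeded uniform subsample (the
#' relation is an average, so a subsample estimates it unbiasedly).
#'
#' @param docs Named list of member token vectors.
#' @param delta Termination threshold.
#' @param config A [run_config()] (kernel settings).
#' @param seed Integer seed.
#' @param lexicon Optional `concept_lexicon` for term boosting.
#' @param sample_max Subsample cap; default from `config`.
#' @return List of class `shrink_decision`: `expand` (logical), `stats`
#'   (a `relation_stats`), `partition`.
#' @export
should_expand <- function(docs, delta = NULL, config = run_config(),
                          seed = 1L, lexicon = NULL, sample_max = NULL) {
  if (is.null(delta)) delta <- config$delta
  if (is.null(sample_max)) sample_max <- config$shrink_sample_max
  if (length(docs) < 4L) {
    return(structure(list(expand = FALSE, stats = NULL, partition = NULL),
                     class = "shrink_decision"))
  }
  use <- docs
  if (length(docs) > sample_max) {
    keep <- with_seed(derive_seed(seed, "shrink-sample"),
                      sort(sample.int(length(docs), sample_max)))
    use <- docs[keep]
  }
  part <- bipartition(use, seed = derive_seed(seed, "shrink-split"),
                      alpha = config$alpha, eta = config$eta,
                      n_iter = config$gibbs_iter)
  W <- node_similarity(use, part$theta, config, lexicon = lexicon)
  stats <- inter_intra(part, members = names(use), sim = W)
  expand <- !stats$degenerate && !(stats$inter > delta)
  structure(list(expand = expand, stats = stats, partition = part),
            class = "shrink_decision")
}

#' Leading child nodes of a topic posterior
#'
#' Sorts the child probabilities in decreasing order, computes the gaps
#' between adjacent values, and cuts after the position of the maximum gap
#' (earliest position on ties, so an all-equal posterior keeps only the top
#' child). Returns the original child indices before the cut.
#'
#' @param posterior Probability vector over child topics.
#' @return Integer vector of selected child indices (at least one).
#' @export
leading_nodes <- function(posterior) {
  check_distribution(posterior)
  k <- length(posterior)
  if (k == 1L) return(1L)
  ord <- order(posterior, decreasing = TRUE)
  p <- posterior[ord]
  gaps <- p[-k] - p[-1L]
  cut <- which.max(gaps)  # first maximal gap
  ord[seq_len(cut)]
}

#' Assign a node's records to its leading child topics
#'
#' Each record joins the leading child topics of its posterior mixture
#' (multiple memberships allowed); with `multi = FALSE` only the argmax child
#' is kept. Children left without members are dropped.
#'
#' @param model A `topic_model` fitted on the parent's members, with
#'   `doc_topic` rows named by record id (as [fit_topic_model()] does for a
#'   named doc list).
#' @param multi Allow multi-membership (default `TRUE`).
#' @return Named list: one id vector per child topic (names `"1" ... "k"`,
#'   empty children dropped). The union of the memberships equals the parent
#'   membership.
#' @export
assign_records <- function(model, multi = TRUE) {
  theta <- model$doc_topic
  if (is.null(rownames(theta))) {
    stop_qa("model must carry record ids as doc_topic rownames")
  }
  members <- vector("list", model$k)
  for (i in seq_len(nrow(theta))) {
    sel <- if (multi) leading_nodes(theta[i, ]) else which.max(theta[i, ])
    for (t in sel) members[[t]] <- c(members[[t]], rownames(theta)[i])
  }
  names(members) <- as.character(seq_len(model$k))
  members[lengths(members) > 0L]
}
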