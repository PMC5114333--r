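# Per-node topic models: collapsed-Gibbs LDA fitting, held-out perplexity,
# and perplexity-driven selection of the number of child topics.

#' Fit a topic model on a set of token lists
#'
#' Latent Dirichlet allocation with symmetric Dirichlet priors, fitted by a
#' collapsed Gibbs sampler. Fits are deterministic for a given seed (internal
#' RNG, independent of R's stream).
#'
#' @param docs List of token vectors (one per document).
#' @param k Number of topics, `>= 2` and `<= length(docs)`.
#' @param alpha Document-topic prior; default `1/k`.
#' @param eta Topic-word prior; default 0.01.
#' @param n_iter Gibbs sweeps; default 150.
#' @param seed Integer seed.
#' @return Object of class `topic_model`: `k`, `vocab`, `topic_word` (k x V,
#'   rows sum to 1), `doc_topic` (one row per document), `alpha`, `eta`,
#'   `seed`.
#' @export
fit_topic_model <- function(docs, k, alpha = NULL, eta = 0.01,
                            n_iter = 150L, seed = 1L) {
  if (!is_count(k) || k < 2) stop_qa("k must be an integer >= 2")
  if (length(docs) < k) {
    stop_qa("cannot fit %d topics on %d documents", k, length(docs))
  }
  if (is.null(alpha)) alpha <- 1 / k
  vocab <- sort(unique(unlist(docs)))
  if (!length(vocab)) stop_qa("empty vocabulary")
  ids <- lapply(docs, function(d) match(d, vocab) - 1L)
  doc_idx <- rep(seq_along(docs) - 1L, lengths(ids))
  word_idx <- unlist(ids)
  if (!length(word_idx)) stop_qa("no tokens to model")
  fit <- lda_gibbs(as.integer(doc_idx), as.integer(word_idx),
                   length(docs), length(vocab), as.integer(k),
                   alpha, eta, as.integer(n_iter), as.integer(seed))
  colnames(fit$topic_word) <- vocab
  model <- structure(list(k = as.integer(k), vocab = vocab,
                          topic_word = fit$topic_word,
                          doc_topic = fit$doc_topic,
                          alpha = alpha, eta = eta, seed = as.integer(seed)),
                     class = "topic_model")
  # refine the document mixtures by posterior inference under the fitted
  # topic-word rows: sampled topic counts over-smooth short documents,
  # whereas the inferred posterior is the representation the assignment and
  # retrieval stages consume
  model$doc_topic <- refine_doc_topic(model, doc_idx, word_idx, length(docs))
  if (!is.null(names(docs))) rownames(model$doc_topic) <- names(docs)
  model
}

# Vectorized fixed-point posterior inference of all document mixtures at
# once; doc_idx/word_idx are the 0-based flattened token streams.
refine_doc_topic <- function(model, doc_idx, word_idx, n_docs,
                             n_iter = 100L, tol = 1e-8) {
  k <- model$k
  d <- doc_idx + 1L
  phiT <- t(model$topic_word)[word_idx + 1L, , drop = FALSE]  # N x k
  theta <- matrix(1 / k, n_docs, k)
  for (it in seq_len(n_iter)) {
    r <- theta[d, , drop = FALSE] * phiT
    rs <- rowSums(r)
    rs[rs == 0] <- 1
    r <- r / rs
    theta_new <- rowsum(r, d) + model$alpha
    theta_new <- theta_new / rowSums(theta_new)
    full <- matrix(1 / k, n_docs, k)
    full[as.integer(rownames(theta_new)), ] <- theta_new
    delta <- max(abs(full - theta))
    theta <- full
    if (delta < tol) break
  }
  theta
}

#' Infer the topic mixture of a record or token vector
#'
#' Posterior mean of the document-topic mixture under a fitted model,
#' estimated by fixed-point iteration with the topic-word rows held fixed.
#' Out-of-vocabulary tokens are ignored; a document with no in-vocabulary
#' token gets the uniform prior mixture.
#'
#' @param model A `topic_model`.
#' @param x A contextualized `qa_record` or a character token vector.
#' @param n_iter Maximum fixed-point iterations.
#' @param tol Max-norm convergence tolerance.
#' @return Probability vector of length `model$k` summing to 1.
#' @export
infer_mixture <- function(model, x, n_iter = 100L, tol = 1e-10) {
  tokens <- if (inherits(x, "qa_record")) {
    if (is.null(x$tokens)) stop_qa("record %s not contextualized", x$id)
    x$tokens
  } else as.character(x)
  idx <- match(tokens, model$vocab)
  idx <- idx[!is.na(idx)]
  k <- model$k
  if (!length(idx)) return(rep(1 / k, k))
  phi_w <- model$topic_word[, idx, drop = FALSE]  # k x T
  theta <- rep(1 / k, k)
  for (i in seq_len(n_iter)) {
    r <- phi_w * theta                  # k x T responsibilities
    cs <- colSums(r)
    cs[cs == 0] <- 1
    r <- sweep(r, 2L, cs, "/")
    theta_new <- model$alpha + rowSums(r)
    theta_new <- theta_new / sum(theta_new)
    if (max(abs(theta_new - theta)) < tol) { theta <- theta_new; break }
    theta <- theta_new
  }
  theta
}

#' Held-out perplexity of a topic model
#'
#' `exp(-sum_i log p(d_i) / sum_i l_i)` over the hold-out documents, where
#' `p(d_i)` is the model's held-out likelihood of document `i` and `l_i` its
#' evaluated token count. Lower is better. The held-out likelihood is
#' estimated by document completion: the document's mixture is inferred from
#' the odd-position tokens and the likelihood evaluated on the even-position
#' tokens, so a model with superfluous topics cannot reward itself by
#' re-fitting the very tokens it is scored on. Both the likelihood and the
#' length normalizer run over in-vocabulary tokens; per-token probabilities
#' are floored at 1e-12.
#'
#' @param model A `topic_model`.
#' @param holdout List of token vectors.
#' @return Positive real.
#' @export
perplexity <- function(model, holdout) {
  if (!length(holdout)) stop_qa("empty hold-out set")
  loglik <- 0
  n_tok <- 0L
  for (doc in holdout) {
    idx <- match(doc, model$vocab)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    if (length(idx) >= 2L) {
      est <- idx[seq_along(idx) %% 2L == 1L]
      ev <- idx[seq_along(idx) %% 2L == 0L]
      theta <- infer_mixture(model, model$vocab[est])
    } else {
      ev <- idx
      theta <- rep(1 / model$k, model$k)
    }
    pw <- as.numeric(theta %*% model$topic_word[, ev, drop = FALSE])
    pw[pw < 1e-12] <- 1e-12
    loglik <- loglik + sum(log(pw))
    n_tok <- n_tok + length(ev)
  }
  if (n_tok == 0L) stop_qa("hold-out set shares no vocabulary with the model")
  exp(-loglik / n_tok)
}

#' Select the number of child topics by held-out perplexity
#'
#' Splits the documents into train/hold-out (seeded), fits one model per
#' candidate `k` on the train split, evaluates each on the hold-out split,
#' and returns the full perplexity table plus the argmin (ties broken to the
#' smaller `k`).
#'
#' @param docs List of token vectors, `length >= 4`.
#' @param k_range Integer vector of candidate child counts (or a `c(lo, hi)`
#'   pair, expanded to `lo:hi`), all within `[2, length(docs))`.
#' @param holdout_fraction Fraction of documents held out.
#' @param seed Integer seed controlling the split and every fit.
#' @param alpha,eta,n_iter Passed to [fit_topic_model()].
#' @return Object of class `perplexity_report`: `table` (data frame `k`,
#'   `perplexity`), `selected_k`, `models` (one fitted model per k, on the
#'   train split).
#' @export
select_child_count <- function(docs, k_range = c(2L, 12L),
                               holdout_fraction = 0.1, seed = 1L,
                               alpha = NULL, eta = 0.01, n_iter = 150L) {
  if (length(docs) < 4L) stop_qa("need at least 4 documents to select k")
  ks <- if (length(k_range) == 2L && k_range[2] > k_range[1] + 1L) {
    seq.int(k_range[1], k_range[2])
  } else unique(as.integer(k_range))
  if (!length(ks)) stop_qa("empty k range")
  ks <- sort(ks)
  n <- length(docs)
  m <- max(1L, min(ceiling(holdout_fraction * n), n - 2L))
  hold_idx <- with_seed(derive_seed(seed, "kselect-split"), sort(sample.int(n, m)))
  train <- docs[-hold_idx]
  hold <- docs[hold_idx]
  ks <- ks[ks <= length(train)]
  if (!length(ks)) stop_qa("k range exceeds the number of training documents")
  perp <- numeric(length(ks))
  models <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    models[[i]] <- fit_topic_model(train, ks[i], alpha = alpha, eta = eta,
                                   n_iter = n_iter,
                                   seed = derive_seed(seed, paste0("fit-k", ks[i])))
    perp[i] <- perplexity(models[[i]], hold)
  }
  sel <- ks[which.min(perp)]  # which.min takes the first (smallest k) on ties
  structure(list(table = data.frame(k = ks, perplexity = perp),
                 selected_k = sel,
                 models = stats::setNames(models, ks)),
            class = "perplexity_report")
}

#' @export
print.perplexity_report <- function(x, ...) {
  cat(sprintf("<perplexity_report> selected k = %d\n", x$selected_k))
  print(x$table, row.names = FALSE)
  invisible(x)
}
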