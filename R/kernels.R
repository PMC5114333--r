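# Per-pair similarity kernels and their linear fusion:
#   phi1 - weighted term kernel (cosine over concept-boosted bags of words)
#   phi2 - syntactic tree kernel (see parsetree.R)
#   phi3 - latent topic kernel (Jensen-Shannon divergence of topic mixtures)
# plus the pairwise similarity matrix used by shrinkage and retrieval.

#' Kernel fusion weights
#'
#' Nonnegative weights for the lexical, syntactic and topical kernels; they
#' must sum to 1.
#'
#' @param beta1,beta2,beta3 Nonnegative reals summing to 1.
#' @return An object of class `similarity_weights`.
#' @export
similarity_weights <- function(beta1, beta2, beta3) {
  b <- c(beta1, beta2, beta3)
  if (any(!is.finite(b)) || any(b < 0)) stop_qa("fusion weights must be nonnegative")
  if (abs(sum(b) - 1) > 1e-9) stop_qa("fusion weights must sum to 1 (got %.12f)", sum(b))
  structure(list(beta1 = b[1], beta2 = b[2], beta3 = b[3]),
            class = "similarity_weights")
}

#' The grid of fusion weights searched when tuning
#'
#' Enumerates the simplex lattice with the given step: `beta1` and `beta2`
#' range over `[0, 1]` in steps of `step` with `beta3 = 1 - beta1 - beta2`.
#'
#' @param step Grid step, default 0.05.
#' @return Data frame with columns `beta1`, `beta2`, `beta3`.
#' @export
beta_grid <- function(step = 0.05) {
  m <- round(1 / step)
  g <- expand.grid(i = 0:m, j = 0:m)
  g <- g[g$i + g$j <= m, ]
  out <- data.frame(beta1 = g$i * step, beta2 = g$j * step)
  out$beta3 <- 1 - out$beta1 - out$beta2
  out$beta3[abs(out$beta3) < 1e-12] <- 0
  out[order(out$beta1, out$beta2), , drop = FALSE]
}

# Weighted bag of words for one record: term counts, with tokens whose
# singularized form belongs to a boosted semantic group multiplied by `boost`.
weighted_bag <- function(tokens, boosted = character(0), boost = 2) {
  if (!length(tokens)) return(numeric(0))
  counts <- table(tokens)
  w <- as.numeric(counts)
  names(w) <- names(counts)
  if (length(boosted) && boost != 1) {
    hit <- singularize(names(w)) %in% boosted
    w[hit] <- w[hit] * boost
  }
  w
}

cosine_bags <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  common <- intersect(names(a), names(b))
  if (!length(common)) return(0)
  num <- sum(a[common] * b[common])
  num / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Weighted term kernel (phi1)
#'
#' Cosine similarity of the two records' weighted bags of words, where tokens
#' mapping to a boosted semantic group of the lexicon count `boost` times.
#'
#' @param a,b Contextualized `qa_record`s.
#' @param lexicon Optional `concept_lexicon` providing semantic groups.
#' @param boost Concept boost factor, `>= 1`.
#' @param boosted_groups Semantic groups receiving the boost.
#' @return Similarity in `[0, 1]`.
#' @export
weighted_term_kernel <- function(a, b, lexicon = NULL, boost = 2,
                                 boosted_groups = run_config()$boosted_groups) {
  if (is.null(a$tokens) || is.null(b$tokens)) {
    stop_qa("records must be contextualized before kernel evaluation")
  }
  if (boost < 1) stop_qa("boost must be >= 1")
  boosted <- boosted_tokens(lexicon, boosted_groups)
  cosine_bags(weighted_bag(a$tokens, boosted, boost),
              weighted_bag(b$tokens, boosted, boost))
}

#' Latent topic kernel (phi3): Jensen-Shannon divergence
#'
#' `0.5 KL(p || m) + 0.5 KL(q || m)` with `m = 0.5 p + 0.5 q`, natural
#' logarithm. Zero iff `p == q`; bounded above by `ln 2`.
#'
#' @param p,q Probability vectors of equal dimension.
#' @return Divergence in `[0, ln 2]`.
#' @export
topic_kernel <- function(p, q) {
  if (length(p) != length(q)) stop_qa("topic distributions differ in dimension")
  check_distribution(p); check_distribution(q)
  m <- 0.5 * (p + q)
  0.5 * kl_div(p, m) + 0.5 * kl_div(q, m)
}

check_distribution <- function(p) {
  if (any(p < -1e-12)) stop_qa("distribution has negative entries")
  if (abs(sum(p) - 1) > 1e-9) stop_qa("distribution does not sum to 1")
  invisible(p)
}

kl_div <- function(p, m) {
  i <- p > 0
  sum(p[i] * log(p[i] / m[i]))
}

# Convert a JS divergence to a similarity in [0, 1].
js_to_similarity <- function(js) 1 - js / log(2)

#' Linear fusion of the three kernels
#'
#' The topical kernel is a divergence while the other two are similarities;
#' under the default polarity it is converted via `1 - JS/ln 2` before fusion
#' so all three components increase with similarity.
#'
#' @param phi1 Lexical similarity in `[0, 1]`.
#' @param phi2 Syntactic similarity, min-max scaled to `[0, 1]`.
#' @param phi3_div Topical JS divergence in `[0, ln 2]`.
#' @param betas A [similarity_weights()] object.
#' @param phi3_polarity `"similarity"` (default conversion) or `"divergence"`
#'   (fuse the raw divergence).
#' @return Fused similarity.
#' @export
fuse <- function(phi1, phi2, phi3_div, betas,
                 phi3_polarity = c("similarity", "divergence")) {
  phi3_polarity <- match.arg(phi3_polarity)
  if (!inherits(betas, "similarity_weights")) {
    betas <- similarity_weights(betas[1], betas[2], betas[3])
  }
  vals <- cbind(phi1, phi2, phi3_div)
  if (any(!is.finite(vals))) stop_qa("kernel values must be finite")
  phi3 <- if (phi3_polarity == "similarity") js_to_similarity(vals[, 3]) else vals[, 3]
  out <- betas$beta1 * vals[, 1] + betas$beta2 * vals[, 2] + betas$beta3 * phi3
  as.numeric(out)
}

# Pairwise cosine matrix of weighted bags (rows = records). `token_lists` is a
# list of token vectors; returns a dense symmetric matrix with unit diagonal.
phi1_matrix <- function(token_lists, boosted = character(0), boost = 2) {
  vocab <- sort(unique(unlist(token_lists)))
  n <- length(token_lists)
  if (!length(vocab)) return(matrix(0, n, n))
  M <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    w <- weighted_bag(token_lists[[i]], boosted, boost)
    if (length(w)) M[i, names(w)] <- w
  }
  nrm <- sqrt(rowSums(M^2))
  nz <- nrm > 0
  M[nz, ] <- M[nz, , drop = FALSE] / nrm[nz]
  S <- tcrossprod(M)
  S[!nz, ] <- 0; S[, !nz] <- 0
  S
}

# Pairwise JS divergence matrix from rows of a topic-mixture matrix, via
# JS(p, q) = H((p+q)/2) - (H(p) + H(q)) / 2.
js_matrix <- function(theta) {
  n <- nrow(theta)
  ent <- apply(theta, 1, entropy_nat)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    M <- 0.5 * (theta[rest, , drop = FALSE] +
                  matrix(theta[i, ], length(rest), ncol(theta), byrow = TRUE))
    hm <- apply(M, 1, entropy_nat)
    d <- hm - 0.5 * (ent[rest] + ent[i])
    d[d < 0] <- 0
    D[i, rest] <- d
    D[rest, i] <- d
  }
  D
}

entropy_nat <- function(p) {
  i <- p > 0
  -sum(p[i] * log(p[i]))
}

#' Pairwise fused similarity matrix
#'
#' Builds the symmetric matrix `W` of fused pairwise similarities over a set
#' of records, with zero diagonal (the random walk has no self-loops), and the
#' row sums `d`. The syntactic kernel, if weighted, is min-max scaled over the
#' off-diagonal pairs of this record set before fusion.
#'
#' @param token_lists List of contextualized token vectors (one per record).
#' @param betas A [similarity_weights()].
#' @param theta Optional matrix of per-record topic mixtures (rows align with
#'   `token_lists`); required when `beta3 > 0`.
#' @param trees Optional list of per-record parse-tree lists (one list of
#'   sentence trees per record); required when `beta2 > 0`.
#' @param lexicon,boost,boosted_groups Concept boosting, as in
#'   [weighted_term_kernel()].
#' @param phi3_polarity See [fuse()].
#' @return List of class `similarity_matrix` with elements `W` (symmetric,
#'   zero diagonal), `d` (row sums) and `isolated` (indices with `d == 0`).
#' @export
similarity_matrix <- function(token_lists, betas, theta = NULL, trees = NULL,
                              lexicon = NULL, boost = 2,
                              boosted_groups = run_config()$boosted_groups,
                              phi3_polarity = c("similarity", "divergence")) {
  phi3_polarity <- match.arg(phi3_polarity)
  n <- length(token_lists)
  if (n < 2L) stop_qa("similarity matrix needs at least 2 records")
  if (!inherits(betas, "similarity_weights")) {
    betas <- similarity_weights(betas[1], betas[2], betas[3])
  }
  W <- matrix(0, n, n)
  if (betas$beta1 > 0) {
    boosted <- boosted_tokens(lexicon, boosted_groups)
    W <- W + betas$beta1 * phi1_matrix(token_lists, boosted, boost)
  }
  if (betas$beta2 > 0) {
    if (is.null(trees)) stop_qa("beta2 > 0 requires parse trees")
    P2 <- phi2_matrix(trees)
    W <- W + betas$beta2 * P2
  }
  if (betas$beta3 > 0) {
    if (is.null(theta)) stop_qa("beta3 > 0 requires topic mixtures")
    if (nrow(theta) != n) stop_qa("theta rows must align with records")
    D3 <- js_matrix(theta)
    S3 <- if (phi3_polarity == "similarity") js_to_similarity(D3) else D3
    W <- W + betas$beta3 * S3
  }
  diag(W) <- 0
  W[W < 0] <- 0
  W <- (W + t(W)) / 2
  d <- rowSums(W)
  if (all(d == 0)) {
    warning("all-zero similarity matrix: ranking degenerates to initial scores")
  }
  structure(list(W = W, d = d, isolated = which(d == 0)),
            class = "similarity_matrix")
}
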