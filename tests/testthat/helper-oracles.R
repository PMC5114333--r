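# Independent brute-force oracles used to check the package's closed-form /
# recursive implementations. These deliberately share no code with R/.

# Jensen-Shannon divergence by direct evaluation of the defining sums.
js_brute <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log(a[i] / b[i])
    s
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# --- subset-tree fragment enumeration ------------------------------------

# All fragments rooted at an internal node, as canonical strings: the node's
# full production, with each non-leaf child either stubbed (label only) or
# expanded recursively.
frags_at <- function(node) {
  if (is.null(node$children)) return(character(0))
  child_opts <- lapply(node$children, function(ch) {
    stub <- ch$label
    if (is.null(ch$children)) stub else c(stub, frags_at(ch))
  })
  combos <- Reduce(function(acc, opts) {
    unlist(lapply(acc, function(a) paste0(a, "|", opts)))
  }, child_opts, accumulate = FALSE, init = "")
  paste0(node$label, "(", sub("^\\|", "", combos), ")")
}

all_nodes_flat <- function(tree) {
  out <- list(tree)
  if (!is.null(tree$children)) {
    for (ch in tree$children) out <- c(out, all_nodes_flat(ch))
  }
  out
}

# STKN oracle: total common fragments = sum over fragment strings of
# (rooted occurrences in t1) * (rooted occurrences in t2).
stkn_oracle <- function(t1, t2) {
  occ <- function(tree) {
    fr <- unlist(lapply(all_nodes_flat(tree), frags_at))
    if (!length(fr)) return(table(character(0)))
    table(fr)
  }
  o1 <- occ(t1); o2 <- occ(t2)
  common <- intersect(names(o1), names(o2))
  sum(as.numeric(o1[common]) * as.numeric(o2[common]))
}

# Random small parse tree over a label alphabet (leaves are tokens).
random_tree <- function(max_nodes = 8L, labels = c("S", "NP", "VP", "N", "V"),
                        tokens = c("a", "b", "c")) {
  grow <- function(budget) {
    if (budget <= 1L) return(parse_tree(sample(tokens, 1L)))
    n_ch <- sample(1:min(3L, budget - 1L), 1L)
    kids <- list()
    left <- budget - 1L
    for (i in seq_len(n_ch)) {
      use <- if (i == n_ch) left else sample(1:max(1L, left - (n_ch - i)), 1L)
      kids[[i]] <- grow(use)
      left <- left - use
    }
    parse_tree(sample(labels, 1L), kids)
  }
  grow(sample(2:max_nodes, 1L))
}

# Leading-gap selection by explicit search over every cut position.
leading_brute <- function(p) {
  k <- length(p)
  ord <- order(p, decreasing = TRUE)
  if (k == 1L) return(1L)
  best_cut <- 1L
  best_gap <- -Inf
  for (cut in 1:(k - 1L)) {
    gap <- p[ord[cut]] - p[ord[cut + 1L]]
    if (gap > best_gap) { best_gap <- gap; best_cut <- cut }
  }
  sort(ord[seq_len(best_cut)])
}

# Average relation by explicit double loop with S(x, x) = 1.
avg_relation_brute <- function(a, b, W) {
  tot <- 0
  for (i in a) for (j in b) tot <- tot + if (i == j) 1 else W[i, j]
  tot / (length(a) * length(b))
}
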