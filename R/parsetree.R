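# Syntactic structures: parse trees, the subset-tree kernel (pure fragment
# counting, no decay), and the record-level syntactic kernel phi2.

#' Construct a parse-tree node
#'
#' Rooted ordered tree with nonterminal labels on internal nodes and tokens on
#' leaves.
#'
#' @param label Node label (nonterminal symbol, or token for a leaf).
#' @param children List of child `parse_tree` nodes; `NULL` for a leaf.
#' @return A `parse_tree`.
#' @export
parse_tree <- function(label, children = NULL) {
  if (!is.null(children)) {
    if (!length(children)) stop_qa("internal parse node must have >= 1 child")
    if (!all(vapply(children, inherits, logical(1), "parse_tree"))) {
      stop_qa("children must be parse_tree nodes")
    }
  }
  structure(list(label = as.character(label), children = children),
            class = "parse_tree")
}

is_leaf <- function(node) is.null(node$children)

# All nodes of a tree, preorder.
tree_nodes <- function(tree) {
  out <- list(tree)
  if (!is_leaf(tree)) {
    for (ch in tree$children) out <- c(out, tree_nodes(ch))
  }
  out
}

#' Number of nodes in a parse tree
#' @param tree A `parse_tree`.
#' @return Node count (internal + leaves).
#' @export
tree_size <- function(tree) length(tree_nodes(tree))

production_key <- function(node) {
  paste(node$label, "->",
        paste(vapply(node$children, function(c) c$label, character(1)),
              collapse = " "))
}

#' Subset-tree kernel (fragment counting)
#'
#' Counts the tree fragments common to two parse trees: the sum over all node
#' pairs of the number of matched sub-tree fragments rooted at those nodes,
#' computed by the standard subset-tree recursion with no decay factor. A
#' fragment takes a node's entire production and optionally expands any
#' non-leaf child recursively.
#'
#' @param t1,t2 Nonempty `parse_tree`s.
#' @return Nonnegative fragment count.
#' @export
stkn <- function(t1, t2) {
  if (!inherits(t1, "parse_tree") || !inherits(t2, "parse_tree")) {
    stop_qa("stkn expects parse_tree inputs")
  }
  n1 <- Filter(Negate(is_leaf), tree_nodes(t1))
  n2 <- Filter(Negate(is_leaf), tree_nodes(t2))
  if (!length(n1) && !length(n2) && (is.null(t1$label) || is.null(t2$label))) {
    stop_qa("empty tree")
  }
  total <- 0
  for (a in n1) {
    ka <- production_key(a)
    for (b in n2) {
      if (ka == production_key(b)) total <- total + stkn_c(a, b)
    }
  }
  total
}

# C(n1, n2) for nodes with identical productions.
stkn_c <- function(a, b) {
  prod <- 1
  for (j in seq_along(a$children)) {
    ca <- a$children[[j]]; cb <- b$children[[j]]
    if (!is_leaf(ca) && !is_leaf(cb) &&
        production_key(ca) == production_key(cb)) {
      prod <- prod * (1 + stkn_c(ca, cb))
    }
  }
  prod
}

#' Right-branching parser over POS tags
#'
#' Builds a trivial constituency tree for a token sequence: each token becomes
#' a preterminal labeled with its POS tag, and preterminals are chained
#' right-branching under `S` nodes. A stand-in so the syntactic kernel is
#' exercisable without a full parser; any `function(tokens) -> parse_tree`
#' plugs in instead.
#'
#' @param tagger A tagger, `function(tokens) -> character` of equal length.
#' @return A parser function `function(tokens) -> parse_tree`.
#' @export
right_branching_parser <- function(tagger = default_tagger()) {
  function(tokens) {
    if (!length(tokens)) stop_qa("cannot parse an empty sentence")
    tags <- tagger(tokens)
    pre <- Map(function(tag, tok) parse_tree(tag, list(parse_tree(tok))),
               tags, tokens)
    tree <- parse_tree("S", list(pre[[length(pre)]]))
    if (length(pre) > 1L) {
      for (i in rev(seq_len(length(pre) - 1L))) {
        tree <- parse_tree("S", list(pre[[i]], tree))
      }
    }
    tree
  }
}

# Sentences of a record: question plus answers, split on terminal punctuation,
# tokenized without stop-word removal (syntax needs function words).
record_sentences <- function(record) {
  texts <- c(record$question, record$answers)
  sents <- unlist(lapply(texts, function(t) strsplit(t, "[.?!;]+")[[1L]]))
  toks <- lapply(sents, tokenize, stopwords = character(0))
  toks[lengths(toks) > 0L]
}

# Parse every sentence of a record.
record_trees <- function(record, parser) {
  sents <- record_sentences(record)
  if (!length(sents)) stop_qa("record %s has no parseable sentence", record$id)
  lapply(sents, parser)
}

#' Syntactic kernel (phi2) between two records
#'
#' Averages the subset-tree kernel over all cross pairs of sentences:
#' `sum_ij STKN(T(s_i), T(s_j)) / (|d1| * |d2|)` where `|d|` is the sentence
#' count, moderating the effect of record length. The value is unbounded;
#' [similarity_matrix()] min-max scales it over the current record set before
#' fusion.
#'
#' @param a,b `qa_record`s with at least one sentence each.
#' @param parser Sentence parser, e.g. [right_branching_parser()].
#' @return Nonnegative real.
#' @export
syntactic_kernel <- function(a, b, parser = right_branching_parser()) {
  phi2_trees(record_trees(a, parser), record_trees(b, parser))
}

phi2_trees <- function(trees_a, trees_b) {
  total <- 0
  for (ta in trees_a) for (tb in trees_b) total <- total + stkn(ta, tb)
  total / (length(trees_a) * length(trees_b))
}

# Pairwise raw phi2 over record tree lists, min-max scaled to [0, 1] over the
# off-diagonal entries (constant nonzero -> 1, constant zero -> 0).
phi2_matrix <- function(trees) {
  n <- length(trees)
  P <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- phi2_trees(trees[[i]], trees[[j]])
      P[i, j] <- v; P[j, i] <- v
    }
  }
  off <- P[upper.tri(P)]
  lo <- min(off); hi <- max(off)
  if (hi > lo) {
    P <- (P - lo) / (hi - lo)
  } else {
    P[] <- if (hi > 0) 1 else 0
  }
  diag(P) <- 0
  P
}
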