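# Evaluation metrics: parent-child tuple accuracy and taxonomy cohesiveness
# against a reference terminology tree, S@K / P@K for node labels, and
# NDCG@n for retrieval.

#' Construct a reference taxonomy
#'
#' Rooted tree over terminology ids (a Medical Subject Headings stand-in)
#' used only for evaluation.
#'
#' @param parent,child Equal-length character vectors of directed edges.
#' @param names Optional named character vector `term_id -> name`.
#' @return Object of class `reference_taxonomy` with a `parent_of` map.
#' @export
reference_taxonomy <- function(parent, child, names = NULL) {
  if (length(parent) != length(child)) stop_qa("edge columns differ in length")
  if (anyDuplicated(child)) stop_qa("a taxonomy node may have only one parent")
  parent_of <- stats::setNames(as.character(parent), as.character(child))
  # acyclicity: walking up from any node must terminate
  for (t in names(parent_of)) {
    seen <- character(0); cur <- t
    while (cur %in% names(parent_of)) {
      if (cur %in% seen) stop_qa("taxonomy contains a cycle at %s", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  structure(list(parent_of = parent_of,
                 terms = union(parent, child),
                 names = names),
            class = "reference_taxonomy")
}

#' Read a reference taxonomy from an edge-list TSV
#'
#' Columns (no header): parent id, child id, optionally child name.
#'
#' @param path Path to a tab-separated edge list.
#' @return A `reference_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop_qa("taxonomy file not found: %s", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  nm <- if (ncol(tab) >= 3L) stats::setNames(tab[[3L]], tab[[2L]])
  reference_taxonomy(tab[[1L]], tab[[2L]], names = nm)
}

#' Write a reference taxonomy to TSV
#' @param taxonomy A `reference_taxonomy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  child <- names(taxonomy$parent_of)
  tab <- data.frame(parent = unname(taxonomy$parent_of), child = child)
  if (!is.null(taxonomy$names)) tab$name <- unname(taxonomy$names[child])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Length of the ancestor path t_parent -> ... -> t_child; NA when t_parent is
# not an ancestor of t_child.
ancestor_path_length <- function(taxonomy, t_parent, t_child) {
  if (identical(t_parent, t_child)) return(NA_integer_)
  cur <- t_child
  p <- 0L
  while (cur %in% names(taxonomy$parent_of)) {
    cur <- taxonomy$parent_of[[cur]]
    p <- p + 1L
    if (identical(cur, t_parent)) return(p)
  }
  NA_integer_
}

#' Ancestry weight of a terminology pair
#'
#' `1 / 2^p` when `t_parent` is a proper ancestor of `t_child` at path length
#' `p` in the reference taxonomy; 0 otherwise (including the reversed
#' direction and terms absent from the taxonomy).
#'
#' @param t_parent,t_child Terminology ids.
#' @param taxonomy A `reference_taxonomy`.
#' @return Real in `[0, 0.5]`.
#' @export
relation_weight <- function(t_parent, t_child, taxonomy) {
  if (!(t_parent %in% taxonomy$terms) || !(t_child %in% taxonomy$terms)) return(0)
  p <- ancestor_path_length(taxonomy, t_parent, t_child)
  if (is.na(p)) 0 else 1 / 2^p
}

# All labeled (parent node, child node) edges of a hierarchy with their label
# id lists; n_labels = how many top labels per node enter (NULL = all stored).
labeled_edges <- function(hierarchy, n_labels = NULL) {
  edges <- list()
  skipped <- 0L
  for (n in hierarchy$nodes) {
    if (!length(n$children)) next
    pl <- node_label_ids(n, n_labels)
    for (cid in n$children) {
      cl <- node_label_ids(hierarchy$nodes[[cid]], n_labels)
      if (!length(pl) || !length(cl)) { skipped <- skipped + 1L; next }
      edges[[length(edges) + 1L]] <- list(parent = pl, child = cl)
    }
  }
  list(edges = edges, skipped = skipped)
}

node_label_ids <- function(node, n_labels = NULL) {
  if (is.null(node$labels) || !nrow(node$labels)) return(character(0))
  ids <- node$labels$term_id
  if (!is.null(n_labels)) ids <- utils::head(ids, n_labels)
  ids
}

#' Local tuple accuracy of a labeled hierarchy
#'
#' Forms one (parent label, child label) tuple per hierarchy edge from the
#' top labels of the adjacent nodes and reports the proportion that are
#' direct parent-child edges in the reference taxonomy.
#'
#' @param hierarchy A labeled `qa_hierarchy`.
#' @param taxonomy A `reference_taxonomy`.
#' @param n_labels Labels per node entering the tuples (default 1, the top
#'   label).
#' @return List `total`, `correct`, `accuracy` (`NA` when no tuples),
#'   `skipped` (edges with an unlabeled endpoint).
#' @export
tuple_accuracy <- function(hierarchy, taxonomy, n_labels = 1L) {
  le <- labeled_edges(hierarchy, n_labels)
  total <- 0L; correct <- 0L
  for (e in le$edges) {
    for (tp in e$parent) for (tc in e$child) {
      total <- total + 1L
      if (!is.na(p <- ancestor_path_length(taxonomy, tp, tc)) && p == 1L) {
        correct <- correct + 1L
      }
    }
  }
  list(total = total, correct = correct,
       accuracy = if (total) correct / total else NA_real_,
       skipped = le$skipped)
}

#' Global cohesiveness of a labeled hierarchy
#'
#' Averages the ancestry weight `1/2^p` over all (parent-node terminology,
#' child-node terminology) label pairs of adjacent hierarchy nodes, pooled
#' globally over all edges. Ranges in `[0, 0.5]`; 0.5 means every labeled
#' edge mirrors a direct reference edge.
#'
#' @param hierarchy A labeled `qa_hierarchy`.
#' @param taxonomy A `reference_taxonomy`.
#' @param n_labels Labels per node entering the average (default all stored).
#' @param per_edge If `TRUE`, average the per-edge means instead of pooling.
#' @return Real in `[0, 0.5]`, or `NA` with no labeled edges.
#' @export
cohesiveness <- function(hierarchy, taxonomy, n_labels = NULL,
                         per_edge = FALSE) {
  le <- labeled_edges(hierarchy, n_labels)
  if (!length(le$edges)) return(NA_real_)
  edge_vals <- vapply(le$edges, function(e) {
    w <- outer(e$parent, e$child,
               Vectorize(function(tp, tc) relation_weight(tp, tc, taxonomy)))
    if (per_edge) mean(w) else sum(w)
  }, numeric(1))
  if (per_edge) return(mean(edge_vals))
  n_pairs <- sum(vapply(le$edges, function(e) {
    length(e$parent) * length(e$child)
  }, numeric(1)))
  sum(edge_vals) / n_pairs
}

#' Success at K for a ranked label list
#'
#' 1 when at least one relevant terminology appears in the top `K` of the
#' ranking, else 0.
#'
#' @param ranked Character vector of ranked terminology ids.
#' @param relevant Character vector of relevant terminology ids.
#' @param K Cutoff, `>= 1`.
#' @return 0 or 1.
#' @export
s_at_k <- function(ranked, relevant, K) {
  if (!is_count(K) || K < 1) stop_qa("K must be a positive integer")
  if (!length(ranked) || !length(relevant)) return(0)
  as.numeric(any(utils::head(ranked, K) %in% relevant))
}

#' Precision at K for a ranked label list
#'
#' `|C intersect R| / |C|` where `C` is the set of top-`K` ranked
#' terminologies and `R` the relevant set.
#'
#' @inheritParams s_at_k
#' @return Real in `[0, 1]`.
#' @export
p_at_k <- function(ranked, relevant, K) {
  if (!is_count(K) || K < 1) stop_qa("K must be a positive integer")
  C <- utils::head(ranked, K)
  if (!length(C) || !length(relevant)) return(0)
  sum(C %in% relevant) / length(C)
}

#' NDCG at n with graded gains
#'
#' Discounted cumulative gain with gain `2^rel - 1` and discount
#' `log2(rank + 1)`, normalized by the ideal ordering's DCG. Gains are the
#' graded relevances 0 / 1 / 2. An all-zero gain vector scores 0.
#'
#' @param gains Numeric vector of graded relevances in ranked order.
#' @param n Cutoff, `>= 1`.
#' @param ideal_gains Gain pool defining the ideal ranking; defaults to
#'   `gains` itself. Pass the gains of all judged records so a system that
#'   misses relevant records is penalized.
#' @return Real in `[0, 1]`.
#' @export
ndcg_at_n <- function(gains, n = length(gains), ideal_gains = gains) {
  if (!is_count(n) || n < 1) stop_qa("n must be a positive integer")
  if (!length(gains) && !length(ideal_gains)) return(0)
  dcg <- function(g) sum((2^g - 1) / log2(seq_along(g) + 1))
  top <- utils::head(gains, n)
  ideal <- utils::head(sort(ideal_gains, decreasing = TRUE), n)
  idcg <- dcg(ideal)
  if (idcg == 0) 0 else dcg(top) / idcg
}
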