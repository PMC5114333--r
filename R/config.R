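# Run configuration: every tunable of the pipeline with validated defaults.

#' Pipeline configuration
#'
#' Collects every tunable of the hierarchy builder, kernels, retrieval engine
#' and profiler, with validated defaults. A snapshot of the configuration is
#' stored inside every built hierarchy so results can be traced back to their
#' settings.
#'
#' @param delta Shrinkage termination threshold on the inter-node relation;
#'   expansion stops when `inter > delta`. The statistic ranges from 0 for
#'   perfectly separated trial children to 2 for indistinguishable ones; the
#'   default 1.6 was calibrated on synthetic corpora, where homogeneous nodes
#'   score near 2 and nodes with separable but vocabulary-sharing subtopics
#'   score at or below about 1.4 (see the methods vignette).
#' @param lambda Random-walk fitting weight: larger values tie the final
#'   relevance scores to the initial kernel scores, smaller values tie them to
#'   graph smoothness. Default 1 weights the two objective terms equally.
#' @param betas Numeric vector of 3 nonnegative fusion weights (lexical,
#'   syntactic, topical) summing to 1. Default `c(0.5, 0, 0.5)`.
#' @param boost Multiplicative weight applied to terms of boosted semantic
#'   groups in the weighted term kernel. Default 2.
#' @param boosted_groups Semantic groups whose concepts receive `boost`.
#' @param k_range Inclusive integer range of child counts searched per node.
#' @param min_node_size Nodes smaller than this are leaves. Default 20.
#' @param depth_cap Safety bound on hierarchy depth (root = depth 0).
#' @param holdout_fraction Fraction of a node's records held out for the
#'   perplexity-based child-count selection. Default 0.1.
#' @param profile_k Number of top frequent noun phrases voting per node.
#' @param profile_top_n Number of terminology labels kept per node.
#' @param alpha Dirichlet document-topic prior; `NULL` means `1/k`.
#' @param eta Dirichlet topic-word prior. Default 0.01.
#' @param gibbs_iter Collapsed-Gibbs sweeps per model fit. Default 150.
#' @param walk_tol Convergence tolerance (max-norm) of the random walk.
#' @param walk_max_iter Iteration cap of the random walk. Default 500.
#' @param shrink_sample_max Maximum node members used (seeded subsample) when
#'   estimating the shrinkage statistics. Default 300.
#' @param multi_membership Allow records to join several first-layer
#'   categories / child nodes. Default `TRUE`.
#' @param phi3_polarity `"similarity"` converts the topical divergence to
#'   `1 - JS/ln 2` before fusion; `"divergence"` fuses the raw divergence.
#' @param initial_score_kernel `"fused"` or `"phi1"`; which kernel initializes
#'   retrieval scores.
#' @param seed Global seed, expanded deterministically into per-stage seeds.
#' @return A validated list of class `qa_config`.
#' @export
run_config <- function(delta = 1.6,
                       lambda = 1,
                       betas = c(0.5, 0, 0.5),
                       boost = 2,
                       boosted_groups = c("disease or syndrome",
                                          "body part, organ or organ component",
                                          "sign or symptom",
                                          "neoplasm"),
                       k_range = c(2L, 12L),
                       min_node_size = 20L,
                       depth_cap = 6L,
                       holdout_fraction = 0.1,
                       profile_k = 20L,
                       profile_top_n = 5L,
                       alpha = NULL,
                       eta = 0.01,
                       gibbs_iter = 150L,
                       walk_tol = 1e-8,
                       walk_max_iter = 500L,
                       shrink_sample_max = 300L,
                       multi_membership = TRUE,
                       phi3_polarity = c("similarity", "divergence"),
                       initial_score_kernel = c("fused", "phi1"),
                       seed = 42L) {
  phi3_polarity <- match.arg(phi3_polarity)
  initial_score_kernel <- match.arg(initial_score_kernel)
  if (!(is.numeric(delta) && length(delta) == 1L && delta >= 0)) {
    stop_qa("config field 'delta' must be a nonnegative scalar")
  }
  if (!(is.numeric(lambda) && length(lambda) == 1L && lambda > 0)) {
    stop_qa("config field 'lambda' must be positive")
  }
  betas <- similarity_weights(betas[1], betas[2], betas[3])
  if (!(is.numeric(boost) && length(boost) == 1L && boost >= 1)) {
    stop_qa("config field 'boost' must be >= 1")
  }
  if (!(length(k_range) == 2L && is_count(k_range[1]) && is_count(k_range[2]) &&
        k_range[1] >= 2 && k_range[2] >= k_range[1])) {
    stop_qa("config field 'k_range' must be an integer pair with 2 <= lo <= hi")
  }
  if (!(is.numeric(holdout_fraction) && holdout_fraction > 0 &&
        holdout_fraction < 1)) {
    stop_qa("config field 'holdout_fraction' must lie in (0, 1)")
  }
  for (fld in c("min_node_size", "depth_cap", "profile_k", "profile_top_n",
                "gibbs_iter", "walk_max_iter", "shrink_sample_max", "seed")) {
    v <- get(fld)
    if (!is_count(v) || v < 1) stop_qa("config field '%s' must be a positive integer", fld)
  }
  if (!is.null(alpha) && !(is.numeric(alpha) && alpha > 0)) {
    stop_qa("config field 'alpha' must be positive or NULL")
  }
  if (!(is.numeric(eta) && eta > 0)) stop_qa("config field 'eta' must be positive")
  structure(list(
    delta = delta, lambda = lambda, betas = betas, boost = boost,
    boosted_groups = boosted_groups,
    k_range = as.integer(k_range), min_node_size = as.integer(min_node_size),
    depth_cap = as.integer(depth_cap),
    holdout_fraction = holdout_fraction,
    profile_k = as.integer(profile_k),
    profile_top_n = as.integer(profile_top_n),
    alpha = alpha, eta = eta, gibbs_iter = as.integer(gibbs_iter),
    walk_tol = walk_tol, walk_max_iter = as.integer(walk_max_iter),
    shrink_sample_max = as.integer(shrink_sample_max),
    multi_membership = isTRUE(multi_membership),
    phi3_polarity = phi3_polarity,
    initial_score_kernel = initial_score_kernel,
    seed = as.integer(seed)
  ), class = "qa_config")
}

#' Read a configuration from a JSON file
#'
#' Fields absent from the file fall back to the [run_config()] defaults.
#'
#' @param path Path to a JSON object of config fields.
#' @return A `qa_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_qa("config file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop_qa("unknown config field(s): %s", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

# Round-trippable plain-list snapshot stored inside hierarchies.
config_snapshot <- function(config) {
  out <- unclass(config)
  out$betas <- as.numeric(unlist(out$betas))
  out
}

config_from_snapshot <- function(snap) {
  snap <- snap[names(snap) %in% names(formals(run_config))]
  snap <- lapply(snap, function(x) if (is.list(x)) unlist(x) else x)
  do.call(run_config, snap)
}
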