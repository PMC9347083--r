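#' @title Graph-theory features from regional volume similarity
#' @name graph_features
#' @description
#' Each subject's regional volumes define a morphometric similarity graph:
#' the edge weight between two regions is the symmetric ratio
#' \eqn{2 / (v_i/v_j + v_j/v_i)}, which lies in (0, 1] and equals 1 only for
#' equal volumes. The weighted matrix is binarized at a set of thresholds
#' (0.3, 0.5, 0.7, 0.9 by default) and four node-wise metrics are computed
#' per binary graph: degree, clustering coefficient, betweenness centrality
#' (normalized to [0, 1]) and eigenvector centrality (unit Euclidean norm).
NULL

#' Pairwise volume-ratio similarity matrix
#'
#' @param volumes Named numeric vector of strictly positive regional volumes
#'   for one subject.
#' @return Symmetric matrix with entries `2 / (v_i/v_j + v_j/v_i)` in
#'   (0, 1]; unit diagonal by convention (the diagonal takes no part in edge
#'   logic).
#' @export
ratio_matrix <- function(volumes) {
  v <- as.numeric(volumes)
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad)) {
    nm <- if (!is.null(names(volumes))) names(volumes)[bad] else as.character(bad)
    stop("non-positive volume for feature(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  r <- outer(v, v, function(a, b) 2 / (a / b + b / a))
  # enforce exact symmetry and unit diagonal against rounding
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(names(volumes), names(volumes))
  r
}

#' Binarize a similarity matrix at a threshold
#'
#' Edges are placed where the ratio similarity meets the threshold
#' (inclusive: `ratio >= threshold`), excluding self-loops.
#'
#' @param r Ratio matrix from [ratio_matrix()].
#' @param threshold Real in (0, 1].
#' @return Symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
binarize_graph <- function(r, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold <= 1)
  adj <- (r >= threshold) * 1
  diag(adj) <- 0
  adj
}

#' Node-wise metrics of a binary graph
#'
#' Computes, for every node: degree (neighbor count); clustering coefficient
#' (fraction of pairs of neighbors that are themselves connected, 0 for
#' degree < 2); betweenness centrality (fraction of shortest source-target
#' paths through the node, counted with multiplicity and normalized by
#' (n-1)(n-2)/2 unordered pairs); and eigenvector centrality (the
#' non-negative principal eigenvector of the adjacency matrix at unit
#' Euclidean norm, computed by power iteration; an edgeless graph yields
#' all-zero centrality with a warning).
#'
#' @param adj Symmetric 0/1 adjacency matrix with zero diagonal.
#' @return List with numeric vectors `degree`, `clustering`, `betweenness`,
#'   `eigenvector`, each of length `nrow(adj)`.
#' @export
node_metrics <- function(adj) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  stopifnot(n == ncol(adj), all(adj %in% c(0, 1)),
            all(diag(adj) == 0), isTRUE(all.equal(adj, t(adj))))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  degree <- as.numeric(igraph::degree(g))
  clustering <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  # igraph returns NaN for degree-1 nodes with isolates="zero" only for
  # degree-0; define degree < 2 as 0 explicitly
  clustering[!is.finite(clustering)] <- 0
  if (n > 2) {
    betweenness <- as.numeric(igraph::betweenness(g, normalized = TRUE))
  } else {
    betweenness <- rep(0, n)
  }
  eigenvector <- power_iteration_centrality(adj)
  list(degree = degree, clustering = clustering,
       betweenness = betweenness, eigenvector = eigenvector)
}

#' Principal-eigenvector centrality by power iteration
#'
#' Deterministic shifted power iteration (on A + I, which shares A's
#' eigenvectors but has a strictly dominant positive eigenvalue even on
#' bipartite graphs) from the uniform positive start vector; converges to
#' the non-negative dominant eigenvector of the adjacency matrix. Returned
#' at unit Euclidean norm. For an edgeless graph the centrality is
#' identically zero (with a warning): there is no dominant direction.
#'
#' @param adj Symmetric non-negative matrix.
#' @param tol Residual tolerance `max|A x - lambda x|` (default 1e-12).
#' @param max_iter Iteration cap (default 20000).
#' @return Non-negative numeric vector with unit Euclidean norm (or zeros).
#' @keywords internal
power_iteration_centrality <- function(adj, tol = 1e-12, max_iter = 20000L) {
  n <- nrow(adj)
  if (sum(adj) == 0) {
    warning("edgeless graph: eigenvector centrality set to zero")
    return(rep(0, n))
  }
  m <- adj + diag(n)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(m %*% x)
    y <- y / sqrt(sum(y^2))
    ax <- as.numeric(adj %*% y)
    lambda <- sum(y * ax)
    if (max(abs(ax - lambda * y)) < tol) { x <- y; break }
    x <- y
  }
  x[x < 0] <- 0 # numerically tiny negatives only
  x / sqrt(sum(x^2))
}

#' Append graph-theory feature columns to a feature table
#'
#' For each subject and each binarization threshold, the four node metrics
#' are computed on the graph over the table's `is_graph_node` (volume)
#' columns and appended as columns named `<metric>@<threshold>:<node>`.
#' Appended columns carry the node's anatomical group and measure type
#' `"graph"` in the feature metadata; original columns are untouched.
#'
#' @param table A [feature_table()] with at least 2 graph-node columns.
#' @param thresholds Numeric vector of binarization thresholds
#'   (default `c(0.3, 0.5, 0.7, 0.9)`).
#' @return A `feature_table` with `4 * n_nodes * length(thresholds)`
#'   appended columns.
#' @export
gt_features <- function(table, thresholds = c(0.3, 0.5, 0.7, 0.9)) {
  node_idx <- which(table$meta$is_graph_node)
  if (length(node_idx) < 2)
    stop("gt_features requires at least 2 graph-node columns", call. = FALSE)
  nodes <- table$meta$name[node_idx]
  metrics <- c("degree", "clustering", "betweenness", "eigenvector")
  thr_lab <- format(thresholds, trim = TRUE)
  new_names <- as.character(t(outer(
    paste0(rep(metrics, each = length(thresholds)), "@",
           rep(thr_lab, times = length(metrics))),
    nodes, paste, sep = ":")))
  # layout: for metric m, threshold t: block of n_nodes columns
  ns <- n_subjects(table)
  out <- matrix(NA_real_, nrow = ns, ncol = length(new_names),
                dimnames = list(rownames(table$features), new_names))
  for (s in seq_len(ns)) {
    r <- ratio_matrix(stats::setNames(table$features[s, node_idx], nodes))
    per_thr <- lapply(thresholds, function(th) {
      node_metrics(binarize_graph(r, th))
    })
    row_vals <- unlist(lapply(metrics, function(m)
      unlist(lapply(per_thr, `[[`, m), use.names = FALSE)), use.names = FALSE)
    out[s, ] <- row_vals
  }
  node_groups <- table$meta$anatomical_group[node_idx]
  add_meta <- data.frame(
    name = new_names,
    anatomical_group = rep(rep(node_groups,
                               times = length(thresholds)), times = length(metrics)),
    measure_type = "graph",
    is_graph_node = FALSE,
    stringsAsFactors = FALSE)
  feature_table(table$metadata,
                cbind(table$features, out),
                rbind(table$meta, add_meta))
}
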