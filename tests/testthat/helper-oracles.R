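# Independent brute-force references for the graph metrics, used as oracles
# against the package implementation. These deliberately take the slow,
# enumerate-everything route.

# all simple paths from s to t by depth-first search
enumerate_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(adj[v, ] == 1))
      if (!w %in% path) walk(c(path, w))
  }
  walk(s)
  paths
}

# betweenness by shortest-path enumeration, normalized by (n-1)(n-2)/2
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  if (n < 3) return(bc)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- enumerate_paths(adj, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    for (v in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + through / sigma
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# clustering by triangle counting among each node's neighbors
brute_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / choose(k, 2)
  }, numeric(1))
}

# principal eigenvector by dense eigendecomposition; also reports the gap
# between the two largest eigenvalues so callers can skip degenerate cases
brute_eigenvector <- function(adj) {
  e <- eigen(adj, symmetric = TRUE)
  v <- abs(e$vectors[, 1])
  list(vector = v / sqrt(sum(v^2)),
       gap = if (nrow(adj) > 1) e$values[1] - e$values[2] else Inf,
       lambda = e$values[1])
}

random_adjacency <- function(n, p = 0.5) {
  adj <- matrix(0, n, n)
  upper <- which(upper.tri(adj))
  adj[upper] <- as.numeric(stats::runif(length(upper)) < p)
  adj + t(adj)
}

# small three-subject fixture table used across io tests
tiny_table <- function() {
  metadata <- data.frame(
    subject_id = c("s1", "s2", "s3"),
    age_at_scan = c(70, 75, 80),
    sex = c("M", "F", "M"),
    dataset = "SIM-A",
    protocol = "MPRAGE",
    baseline_dx = c("HC", "MCI", "AD"),
    final_dx = c("HC", "MCI", "AD"),
    followup_months = c(24, 30, 18),
    stringsAsFactors = FALSE)
  features <- matrix(c(3000, 2900, 2500,
                       4000, 4100, 3600,
                       2.5, 2.4, 2.2,
                       0.12, 0.13, 0.14,
                       1800, 1750, 1600),
                     nrow = 3,
                     dimnames = list(NULL, c("hip_vol", "tem_vol", "thick",
                                             "curv", "area")))
  meta <- data.frame(
    name = colnames(features),
    anatomical_group = c("hippocampus", "temporal", "frontal", "parietal",
                         "temporal"),
    measure_type = c("volume", "volume", "mean thickness", "mean curvature",
                     "surface area"),
    is_graph_node = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  feature_table(metadata, features, meta)
}

# separable two-class toy matrix for learner tests; positive class shifted
separable_xy <- function(n = 30, p = 6, shift = 3, seed = 42) {
  set.seed(seed)
  y <- factor(rep(c("neg", "pos"), each = n), levels = c("neg", "pos"))
  x <- matrix(stats::rnorm(2 * n * p), 2 * n, p)
  x[y == "pos", 1:2] <- x[y == "pos", 1:2] + shift
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}
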