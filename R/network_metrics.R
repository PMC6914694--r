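# One-to-one back-mapping from embedded points to full networks, display
# thresholding, and weighted graph summaries (global efficiency, local
# efficiency, degree assortativity).

#' Retrieve the full network behind an embedded point
#'
#' Every row of the edge-vector stack corresponds to exactly one embedded
#' point and one dynamic network, so any point can be mapped back to its full
#' correlation matrix. Select either by stack row or by
#' (subject, condition, window).
#'
#' @param stack an `edge_stack`.
#' @param row stack row index, or
#' @param subject,condition,window series coordinates of the network.
#' @return n x n correlation matrix with attributes `subject_id`,
#'   `condition`, `window_index`.
#' @export
lookup_network <- function(stack, row = NULL, subject = NULL,
                           condition = NULL, window = NULL) {
  stopifnot(inherits(stack, "edge_stack"))
  meta <- stack$row_meta
  if (is.null(row)) {
    if (is.null(subject) || is.null(condition) || is.null(window)) {
      stopf("supply either `row` or all of subject, condition, window")
    }
    row <- which(meta$subject_id == subject & meta$condition == condition &
                   meta$window_index == window)
    if (length(row) == 0L) {
      stopf("no network for subject %s, condition %s, window %s",
            subject, condition, window)
    }
    if (length(row) > 1L) stopf("index resolves to %d rows", length(row))
  }
  if (!is_count(row) || row > nrow(stack$values)) {
    stopf("row index %s out of range (1..%d)", row, nrow(stack$values))
  }
  m <- devectorize(stack$values[row, ], stack$n_rois)
  attr(m, "subject_id") <- meta$subject_id[row]
  attr(m, "condition") <- meta$condition[row]
  attr(m, "window_index") <- meta$window_index[row]
  m
}

#' Keep only the strongest edges of a network
#'
#' Retains the `ceiling(fraction * m)` edges with the largest correlation
#' values (`mode = "signed"`, the default, keeps the largest signed values —
#' the convention used for hub display; `mode = "absolute"` ranks by
#' magnitude). All other edges are set to zero; the node set and the retained
#' weights are unchanged, and the diagonal is zeroed.
#'
#' @param m symmetric n x n matrix of edge weights.
#' @param fraction fraction of the n(n-1)/2 edges to keep, in (0, 1); the
#'   display convention is 0.015 (the strongest 1.5%).
#' @param mode `"signed"` or `"absolute"` ranking.
#' @return n x n symmetric matrix with zero diagonal (the thresholded graph).
#' @export
threshold_top_edges <- function(m, fraction = 0.015,
                                mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (!is_number(fraction) || fraction <= 0 || fraction >= 1) {
    stopf("fraction must lie in (0, 1)")
  }
  v <- vectorize_upper(m)
  n_keep <- ceiling(fraction * length(v))
  key <- if (mode == "signed") v else abs(v)
  keep <- order(key, decreasing = TRUE)[seq_len(n_keep)]  # stable order
  w <- numeric(length(v))
  w[keep] <- v[keep]
  g <- devectorize(w, nrow(m))
  diag(g) <- 0
  g
}

#' Node degrees or strengths of a thresholded network
#'
#' @param g thresholded adjacency matrix (zeros = absent edges).
#' @param weighted `FALSE` (default) counts edges per node; `TRUE` sums edge
#'   weights (strength).
#' @return numeric vector of length n.
#' @export
degree_sequence <- function(g, weighted = FALSE) {
  g <- as.matrix(g)
  diag(g) <- 0
  if (weighted) rowSums(g) else rowSums(g != 0)
}

# weighted shortest-path distance matrix; edge length = 1 / weight
shortest_path_lengths <- function(g) {
  if (any(g < 0)) {
    stopf("negative edge weights; threshold the network first (e.g. threshold_top_edges)")
  }
  ig <- igraph::graph_from_adjacency_matrix(g, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  w <- igraph::E(ig)$weight
  igraph::distances(ig, weights = if (length(w)) 1 / w else NULL)
}

#' Global efficiency of a weighted network
#'
#' Mean inverse weighted shortest-path length over all ordered node pairs,
#' with edge length taken as 1/weight (stronger correlation = shorter path)
#' and disconnected pairs contributing 0. For a fully connected unit-weight
#' graph the value is 1.
#'
#' @param g adjacency matrix with nonnegative weights (threshold first).
#' @return scalar in [0, 1] for weights in [0, 1].
#' @export
global_efficiency <- function(g) {
  g <- as.matrix(g)
  if (nrow(g) < 2L) stopf("need at least 2 nodes")
  d <- shortest_path_lengths(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (nrow(g) * (nrow(g) - 1L))
}

#' Local efficiency of a weighted network
#'
#' Mean over nodes of the global efficiency of each node's open neighbourhood
#' subgraph (the subgraph induced by its neighbours, excluding the node
#' itself). Nodes with fewer than 2 neighbours contribute 0.
#'
#' @inheritParams global_efficiency
#' @return scalar in [0, 1] for weights in [0, 1].
#' @export
local_efficiency <- function(g) {
  g <- as.matrix(g)
  if (any(g < 0)) {
    stopf("negative edge weights; threshold the network first")
  }
  n <- nrow(g)
  diag(g) <- 0
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(g[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(g[nb, nb, drop = FALSE])
  }, 0)
  mean(vals)
}

#' Degree assortativity of a thresholded network
#'
#' Pearson correlation between the binary degrees of the two endpoints of
#' every edge (each edge counted in both orientations). Positive values mean
#' hubs connect to hubs. Undefined (returned as `NA` with a message
#' attribute) when endpoint degrees have zero variance, e.g. on a regular
#' graph.
#'
#' @param g thresholded adjacency matrix with >= 2 edges.
#' @return scalar in [-1, 1], or `NA` when undefined.
#' @export
assortativity_degree <- function(g) {
  g <- as.matrix(g)
  diag(g) <- 0
  deg <- rowSums(g != 0)
  e <- which(upper.tri(g) & g != 0, arr.ind = TRUE)
  if (nrow(e) < 2L) stopf("need at least 2 edges")
  x <- c(deg[e[, 1L]], deg[e[, 2L]])
  y <- c(deg[e[, 2L]], deg[e[, 1L]])
  if (sd(x) == 0 || sd(y) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "undefined: endpoint degrees have zero variance"
    return(out)
  }
  cor(x, y)
}

#' Graph summaries of one thresholded network
#'
#' @param m full correlation matrix.
#' @param fraction display threshold passed to [threshold_top_edges()].
#' @param mode thresholding mode.
#' @return named vector: global_efficiency, local_efficiency, assortativity.
#' @export
graph_metrics <- function(m, fraction = 0.015, mode = "signed") {
  g <- threshold_top_edges(m, fraction, mode)
  c(global_efficiency = global_efficiency(g),
    local_efficiency = local_efficiency(g),
    assortativity = as.numeric(assortativity_degree(g)))
}

#' Average graph summaries over a dynamic network series
#'
#' Computes [graph_metrics()] per window on the thresholded graph and
#' averages over windows. Windows whose assortativity is undefined are
#' dropped from the assortativity average only.
#'
#' @param series a `dynamic_networks` object.
#' @inheritParams graph_metrics
#' @return named vector of the three series-average metrics.
#' @export
series_average_metrics <- function(series, fraction = 0.015,
                                   mode = "signed") {
  stopifnot(inherits(series, "dynamic_networks"))
  per <- vapply(series$matrices, graph_metrics, numeric(3),
                fraction = fraction, mode = mode)
  c(global_efficiency = mean(per["global_efficiency", ]),
    local_efficiency = mean(per["local_efficiency", ]),
    assortativity = mean(per["assortativity", ], na.rm = TRUE))
}

#' Export a network for BrainNet-style viewers
#'
#' Writes the plain-text `.node` file (columns: x y z colour size label, one
#' row per node; colour = binary degree, size = strength normalised by its
#' maximum magnitude) and the `.edge` file (the full thresholded n x n
#' matrix, tab-separated).
#'
#' @param m full correlation matrix.
#' @param node_coordinates n x 3 matrix of node positions (e.g. MNI mm).
#' @param prefix output path prefix; writes `<prefix>.node`, `<prefix>.edge`.
#' @param fraction display threshold.
#' @param mode thresholding mode.
#' @param labels optional node labels (defaults to `n1..nN`).
#' @return named character vector of the two file paths, invisibly.
#' @export
export_brainnet <- function(m, node_coordinates, prefix, fraction = 0.015,
                            mode = "signed", labels = NULL) {
  node_coordinates <- as.matrix(node_coordinates)
  n <- nrow(m)
  if (nrow(node_coordinates) != n || ncol(node_coordinates) != 3L) {
    stopf("node_coordinates must be %d x 3 (got %d x %d)", n,
          nrow(node_coordinates), ncol(node_coordinates))
  }
  if (is.null(labels)) labels <- sprintf("n%d", seq_len(n))
  g <- threshold_top_edges(m, fraction, mode)
  strength <- degree_sequence(g, weighted = TRUE)
  size <- if (max(abs(strength)) > 0) strength / max(abs(strength))
          else strength
  node <- data.frame(node_coordinates[, 1L], node_coordinates[, 2L],
                     node_coordinates[, 3L],
                     colour = degree_sequence(g), size = size,
                     label = labels)
  node_path <- paste0(prefix, ".node")
  edge_path <- paste0(prefix, ".edge")
  write.table(node, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(g, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(node = node_path, edge = edge_path))
}
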