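# Markov clustering of weighted protein-interaction graphs, with the
# STRING-style minimum-confidence edge filter.

#' Build an interaction graph from an edge list
#'
#' Edges with score below `min_score` are dropped (the "minimum required
#' interaction score"; an edge scoring exactly `min_score` is kept). Nodes
#' with no surviving edge are retained as isolated nodes.
#'
#' @param edges Edge-list data.frame (`node_a`, `node_b`, `score`), scores
#'   in [0,1].
#' @param nodes Character vector of node identifiers; every edge endpoint
#'   must appear here.
#' @param min_score Minimum confidence score (default 0.40, "medium").
#' @return An `interaction_graph`: list with `nodes` and the symmetric
#'   `weights` matrix (zero diagonal).
#' @export
build_graph <- function(edges, nodes, min_score = 0.40) {
  nodes <- as.character(nodes)
  stopifnot(!anyDuplicated(nodes))
  validate_edge_list(edges)
  bad <- setdiff(c(edges$node_a, edges$node_b), nodes)
  if (length(bad))
    stop("edge endpoint(s) not in node list: ", paste(bad, collapse = ", "))
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  keep <- edges$score >= min_score
  for (k in which(keep)) {
    w[edges$node_a[k], edges$node_b[k]] <- edges$score[k]
    w[edges$node_b[k], edges$node_a[k]] <- edges$score[k]
  }
  structure(list(nodes = nodes, weights = w), class = "interaction_graph")
}

#' Markov clustering (MCL)
#'
#' Standard MCL on the weighted adjacency matrix: self-loops of weight
#' `self_loop` are added, columns are normalized to a stochastic matrix,
#' then expansion (matrix power `expansion`) alternates with inflation
#' (elementwise power `inflation` followed by column renormalization) and
#' pruning of entries below `prune_epsilon`, until the matrix changes by
#' less than `conv_tol` or `max_iter` is reached. Clusters are the
#' connected components of the nonzero structure of the converged matrix;
#' isolated nodes form singleton clusters. Inflation controls granularity
#' (higher = finer).
#'
#' @param graph An `interaction_graph` from [build_graph()].
#' @param inflation Inflation exponent (> 1; default 1.7).
#' @param expansion Expansion power (default 2).
#' @param self_loop Self-loop weight added before normalization (default 1).
#' @param prune_epsilon Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap.
#' @param conv_tol Convergence tolerance on the max absolute change.
#' @return A `cluster_assignment`: list with `membership` (named integer
#'   vector, dense cluster ids from 1 in order of first node appearance),
#'   `n_iter`, and `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 1.7, expansion = 2,
                        self_loop = 1, prune_epsilon = 1e-5,
                        max_iter = 100, conv_tol = 1e-6) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (inflation <= 1) stop("inflation must be > 1")
  M <- graph$weights
  stopifnot(isTRUE(all.equal(M, t(M))), all(M >= 0), all(M <= 1))
  diag(M) <- self_loop
  M <- normalize_columns(M)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M_prev <- M
    for (e in seq_len(expansion - 1L)) M <- M %*% M_prev
    M <- normalize_columns(M^inflation)
    M[M < prune_epsilon] <- 0
    M <- normalize_columns(M)
    if (max(abs(M - M_prev)) < conv_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations")
  structure(list(membership = components_from_structure(M, graph$nodes),
                 n_iter = it, converged = converged),
            class = "cluster_assignment")
}

normalize_columns <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1  # all-zero column (fully pruned isolated node)
  sweep(M, 2L, cs, `/`)
}

components_from_structure <- function(M, nodes) {
  adj <- (M > 0) | (t(M) > 0)
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # dense ids in order of first appearance
  ids <- match(comp, unique(comp))
  names(ids) <- nodes
  ids
}

#' Write a cluster assignment as TSV
#'
#' @param assignment A `cluster_assignment`.
#' @param path File path.
#' @export
write_clusters <- function(assignment, path) {
  d <- data.frame(node = names(assignment$membership),
                  cluster = as.integer(assignment$membership),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
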