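# Independent reference MCL used as the oracle for mcl_cluster(). Written
# deliberately differently from the package routine: explicit per-column
# loops, no pruning, transitive-closure component extraction with no
# igraph dependency.
reference_mcl <- function(weights, inflation, self_loop = 1,
                          max_iter = 200, tol = 1e-9) {
  n <- nrow(weights)
  m <- weights
  for (i in seq_len(n)) m[i, i] <- self_loop
  colnorm <- function(mm) {
    for (j in seq_len(n)) {
      s <- sum(mm[, j])
      if (s > 0) mm[, j] <- mm[, j] / s
    }
    mm
  }
  m <- colnorm(m)
  for (it in seq_len(max_iter)) {
    prev <- m
    m <- m %*% m
    m <- colnorm(m^inflation)
    if (max(abs(m - prev)) < tol) break
  }
  reach <- (m > 1e-8) | t(m > 1e-8)
  diag(reach) <- TRUE
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  names(comp) <- rownames(weights)
  comp
}

# Fixed-seed two-community random graph (12 nodes, intra 0.9 / inter 0.05).
two_community_graph <- function(seed = 11, n_per = 6, p_intra = 0.9,
                                p_inter = 0.05) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(2 * n_per))
  block <- rep(1:2, each = n_per)
  ea <- character(0); eb <- character(0); sc <- numeric(0)
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      p <- if (block[i] == block[j]) p_intra else p_inter
      if (stats::runif(1) < p) {
        ea <- c(ea, nodes[i]); eb <- c(eb, nodes[j])
        sc <- c(sc, round(stats::runif(1, 0.5, 1), 3))
      }
    }
  }
  list(nodes = nodes,
       edges = data.frame(node_a = ea, node_b = eb, score = sc,
                          stringsAsFactors = FALSE))
}
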