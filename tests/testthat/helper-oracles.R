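# Independent oracles used across the suite. They deliberately avoid the
# package's BFS/accumulation code paths: distances come from Floyd-Warshall,
# shortest paths are enumerated explicitly, subtree membership is decided by
# walking parent chains, and hypergeometric tails are enumerated over all
# draws.

# adjacency matrix of an interaction_graph
adj_matrix <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) A[i, graph$adj[[i]]] <- 1L
  A
}

floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- ifelse(A == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# all shortest paths s -> t as a list of index vectors
enumerate_shortest_paths <- function(A, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  if (s == t) return(list(s))
  out <- list()
  for (w in which(A[s, ] == 1L)) {
    if (D[w, t] == D[s, t] - 1) {
      for (p in enumerate_shortest_paths(A, D, w, t))
        out[[length(out) + 1L]] <- c(s, p)
    }
  }
  out
}

# Brute-force scores for all seven measures by explicit path enumeration.
oracle_centralities <- function(graph) {
  n <- length(graph$nodes)
  A <- adj_matrix(graph)
  D <- floyd_warshall(A)
  btw <- numeric(n); str <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(D[s, t])) next
    paths <- enumerate_shortest_paths(A, D, s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      str[v] <- str[v] + through
      btw[v] <- btw[v] + through / length(paths)
    }
  }
  clo <- vapply(seq_len(n), function(v)
    sum(1 / D[v, -v][is.finite(D[v, -v])]), numeric(1))
  # components from reachability
  comp <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0) next
    cid <- cid + 1L
    comp[is.finite(D[v, ])] <- cid
  }
  rad <- vapply(seq_len(n), function(v) {
    members <- which(comp == comp[v])
    if (length(members) == 1) return(0)
    diam <- max(D[members, members])
    sum(diam + 1 - D[v, setdiff(members, v)]) / (length(members) - 1)
  }, numeric(1))
  mnc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1L)
    if (length(nb) == 0) return(0)
    sub <- A[nb, nb, drop = FALSE]
    Dsub <- floyd_warshall(sub)
    max(vapply(seq_along(nb), function(i) sum(is.finite(Dsub[i, ])),
               numeric(1)))
  }, numeric(1))
  bn <- oracle_bottleneck(A, D)
  data.frame(node = graph$nodes, degree = rowSums(A), betweenness = btw,
             closeness = clo, stress = str, radiality = rad, mnc = mnc,
             bottleneck = bn)
}

# Bottleneck oracle: same deterministic tree rule (lexicographically
# smallest parent), but subtree membership decided by walking parent chains.
oracle_bottleneck <- function(A, D) {
  n <- nrow(A)
  score <- integer(n)
  for (s in seq_len(n)) {
    reach <- which(is.finite(D[s, ]))
    nc <- length(reach)
    if (nc == 1) next
    parent <- rep(NA_integer_, n)
    for (v in reach) {
      if (v == s) next
      parent[v] <- min(which(A[v, ] == 1L & D[s, ] == D[s, v] - 1))
    }
    in_subtree <- function(u, v) {   # is v on u's chain to the root?
      while (!is.na(u)) {
        if (u == v) return(TRUE)
        u <- parent[u]
      }
      FALSE
    }
    for (v in reach) {
      if (v == s) next
      size <- sum(vapply(reach, function(u) in_subtree(u, v), logical(1)))
      if (size > nc / 4) score[v] <- score[v] + 1L
    }
  }
  score
}

# Uniform Erdos-Renyi interaction_graph over letter-named nodes.
random_test_graph <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  edges <- if (n >= 2) {
    pairs <- t(combn(nodes, 2))
    pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  } else matrix(character(0), ncol = 2)
  interaction_graph(edges, nodes = nodes)
}

# Exhaustive hypergeometric upper tail: over all C(N, n) draws, the
# fraction with overlap >= k.
oracle_hyper_tail <- function(k, M, n, N) {
  draws <- combn(N, n)
  mean(apply(draws <= M, 2, sum) >= k)
}

# small helper: expression_study from case/control value matrices
make_study <- function(case, control, study_id = "s") {
  m <- cbind(case, control)
  colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  expression_study(m, c(rep("case", ncol(case)),
                        rep("control", ncol(control))),
                   study_id = study_id)
}

# simulated hierarchical-model study used by several tests
simulate_hier_study <- function(n_genes, n1 = 12, n2 = 12, d0 = 4,
                                s0_sq = 0.05, effect = NULL,
                                study_id = "sim") {
  sigma <- sqrt(d0 * s0_sq / rchisq(n_genes, d0))
  base <- rnorm(n_genes, 7, 1.5)
  eff <- effect %||% numeric(n_genes)
  logm <- outer(base, rep(1, n1 + n2)) +
    outer(eff, c(rep(1, n1), rep(0, n2))) +
    matrix(rnorm(n_genes * (n1 + n2), 0, rep(sigma, n1 + n2)),
           nrow = n_genes)
  m <- 2^logm
  rownames(m) <- sprintf("G%05d", seq_len(n_genes))
  expression_study(m, c(rep("case", n1), rep("control", n2)),
                   study_id = study_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
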