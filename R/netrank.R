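#' Undirected simple interaction graph
#'
#' Node-labelled undirected graph backed by sorted adjacency lists. Self
#' loops are dropped with a warning and duplicate edges are collapsed, so
#' the invariants (simple, symmetric neighbor sets) hold by construction.
#' Nodes are stored in lexicographic order; that order is the tie-break
#' order used throughout the centrality code.
#'
#' @param edges two-column matrix or data frame of node labels (may have
#'   zero rows).
#' @param nodes optional character vector of node labels; isolated nodes not
#'   appearing in `edges` are kept.
#' @return object of class `interaction_graph`: list with `nodes`
#'   (character) and `adj` (list of integer neighbor indices).
#' @export
interaction_graph <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2 && !(length(edges) == 0))
    stop_data("edge input must have two columns")
  storage.mode(edges) <- "character"
  if (nrow(edges) > 0) {
    loops <- edges[, 1] == edges[, 2]
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped")
      edges <- edges[!loops, , drop = FALSE]
    }
  }
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  adj <- rep(list(integer(0)), length(nodes))
  if (nrow(edges) > 0) {
    i <- match(edges[, 1], nodes)
    j <- match(edges[, 2], nodes)
    key <- paste(pmin(i, j), pmax(i, j))
    dup <- duplicated(key)
    i <- i[!dup]; j <- j[!dup]
    for (e in seq_along(i)) {
      adj[[i[e]]] <- c(adj[[i[e]]], j[e])
      adj[[j[e]]] <- c(adj[[j[e]]], i[e])
    }
    adj <- lapply(adj, sort)
  }
  structure(list(nodes = nodes, adj = adj), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph: %d nodes, %d edges>\n", length(x$nodes),
              sum(vapply(x$adj, length, integer(1))) / 2))
  invisible(x)
}

#' Edge list of a graph
#'
#' @param graph an [interaction_graph()].
#' @return two-column character matrix, one row per edge, i < j order.
#' @export
graph_edges <- function(graph) {
  out <- do.call(rbind, lapply(seq_along(graph$adj), function(i) {
    j <- graph$adj[[i]][graph$adj[[i]] > i]
    if (length(j)) cbind(graph$nodes[i], graph$nodes[j])
  }))
  if (is.null(out)) out <- matrix(character(0), ncol = 2)
  colnames(out) <- c("node1", "node2")
  out
}

#' Dice similarity of two nodes' neighborhoods
#'
#' D(i, j) = 2 |N_i intersect N_j| / (|N_i| + |N_j|): 1 for identical
#' nonempty neighbor sets, 0 for disjoint ones. `1 - neighborhood_similarity`
#' is the corresponding distance.
#'
#' @param graph an [interaction_graph()].
#' @param i,j node labels.
#' @return similarity in \[0, 1\].
#' @export
neighborhood_similarity <- function(graph, i, j) {
  ii <- match(i, graph$nodes); jj <- match(j, graph$nodes)
  if (is.na(ii) || is.na(jj)) stop_data("unknown node: ",
                                        if (is.na(ii)) i else j)
  ni <- graph$adj[[ii]]; nj <- graph$adj[[jj]]
  if (length(ni) + length(nj) == 0)
    stop_data("similarity undefined: nodes '", i, "' and '", j,
              "' are both isolated")
  2 * length(intersect(ni, nj)) / (length(ni) + length(nj))
}

# BFS from one source: distances (Inf if unreachable) and shortest-path
# counts sigma.
bfs_sp <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n); sigma <- numeric(n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# All-pairs distance and path-count matrices.
all_pairs_sp <- function(graph) {
  n <- length(graph$nodes)
  D <- matrix(Inf, n, n); S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    b <- bfs_sp(graph$adj, s)
    D[s, ] <- b$dist
    S[s, ] <- b$sigma
  }
  list(D = D, S = S)
}

# Connected-component id per node.
graph_components <- function(graph) {
  n <- length(graph$nodes)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    frontier <- s; comp[s] <- cid
    while (length(frontier) > 0) {
      nxt <- unlist(graph$adj[frontier])
      nxt <- nxt[is.na(comp[nxt])]
      comp[nxt] <- cid
      frontier <- unique(nxt)
    }
  }
  comp
}

#' Topological centrality scores
#'
#' Computes one of the node-ranking measures used for PPI hub selection:
#' \describe{
#'   \item{degree}{neighbor count.}
#'   \item{betweenness}{sum over unordered pairs s, t (both != v) of the
#'     fraction of shortest s-t paths passing through v (unnormalized).}
#'   \item{closeness}{harmonic closeness, sum of 1/d(v, w); unreachable
#'     nodes contribute 0 (well defined on disconnected graphs).}
#'   \item{stress}{number of shortest s-t paths (unordered pairs, both != v)
#'     passing through v.}
#'   \item{radiality}{within v's connected component,
#'     sum_w (diameter + 1 - d(v, w)) / (n_C - 1); isolated nodes score 0.}
#'   \item{mnc}{maximal neighborhood component: size of the largest
#'     connected component of the subgraph induced by v's neighbors.}
#'   \item{bottleneck}{see [bottleneck_scores()].}
#' }
#'
#' @param graph an [interaction_graph()].
#' @param measure one of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"stress"`, `"radiality"`, `"mnc"`, `"bottleneck"`.
#' @return named numeric vector of node scores.
#' @export
compute_centrality <- function(graph,
                               measure = c("degree", "betweenness",
                                           "closeness", "stress",
                                           "radiality", "mnc",
                                           "bottleneck")) {
  measure <- match.arg(measure)
  n <- length(graph$nodes)
  if (n == 0) stop_data("empty graph")
  out <- switch(measure,
    degree = vapply(graph$adj, length, integer(1)),
    mnc = vapply(seq_len(n), function(v) mnc_one(graph, v), numeric(1)),
    bottleneck = bottleneck_scores_raw(graph),
    {
      sp <- all_pairs_sp(graph)
      switch(measure,
        closeness = {
          inv <- 1 / sp$D
          diag(inv) <- 0
          rowSums(inv)
        },
        radiality = radiality_from_sp(graph, sp$D),
        betweenness = btw_stress_from_sp(sp)$betweenness,
        stress = btw_stress_from_sp(sp)$stress)
    })
  names(out) <- graph$nodes
  out
}

mnc_one <- function(graph, v) {
  nb <- graph$adj[[v]]
  if (length(nb) == 0) return(0)
  sub_adj <- lapply(nb, function(u) match(intersect(graph$adj[[u]], nb), nb))
  comp <- rep(NA_integer_, length(nb)); cid <- 0L
  for (s in seq_along(nb)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    frontier <- s; comp[s] <- cid
    while (length(frontier) > 0) {
      nxt <- unlist(sub_adj[frontier])
      nxt <- nxt[is.na(comp[nxt])]
      comp[nxt] <- cid
      frontier <- unique(nxt)
    }
  }
  max(tabulate(comp))
}

radiality_from_sp <- function(graph, D) {
  comp <- graph_components(graph)
  n <- length(graph$nodes)
  out <- numeric(n)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    nc <- length(members)
    if (nc == 1) next
    Dc <- D[members, members, drop = FALSE]
    diam <- max(Dc)
    out[members] <- (rowSums(diam + 1 - Dc) - (diam + 1)) / (nc - 1)
  }
  out
}

btw_stress_from_sp <- function(sp) {
  D <- sp$D; S <- sp$S
  n <- nrow(D)
  btw <- numeric(n); str <- numeric(n)
  ut <- upper.tri(D)
  frac <- matrix(0, n, n)
  ok0 <- ut & is.finite(D)
  for (v in seq_len(n)) {
    through <- outer(D[, v], D[v, ], `+`)
    on_path <- ok0 & is.finite(through) & through == D
    on_path[v, ] <- FALSE; on_path[, v] <- FALSE
    if (!any(on_path)) next
    paths_v <- outer(S[, v], S[v, ])
    str[v] <- sum(paths_v[on_path])
    btw[v] <- sum(paths_v[on_path] / S[on_path])
  }
  list(betweenness = btw, stress = str)
}

#' BottleNeck scores
#'
#' For every root s, a deterministic shortest-path tree is grown by BFS,
#' each non-root node taking its lexicographically smallest parent among
#' neighbors one step closer to the root. A node v != s earns one point for
#' that tree iff the subtree rooted at v (v included) holds more than a
#' quarter of the nodes of s's component. The score sums points over all
#' roots in v's component. The tree is not unique in general; the
#' lexicographic parent rule makes the score reproducible.
#'
#' @param graph an [interaction_graph()].
#' @return named integer vector of scores.
#' @export
bottleneck_scores <- function(graph) {
  out <- bottleneck_scores_raw(graph)
  names(out) <- graph$nodes
  out
}

bottleneck_scores_raw <- function(graph) {
  n <- length(graph$nodes)
  score <- integer(n)
  for (s in seq_len(n)) {
    dist <- bfs_sp(graph$adj, s)$dist
    reach <- which(is.finite(dist))
    nc <- length(reach)
    if (nc == 1) next
    parent <- rep(NA_integer_, n)
    for (v in reach) {
      if (v == s) next
      cand <- graph$adj[[v]][dist[graph$adj[[v]]] == dist[v] - 1]
      parent[v] <- min(cand)  # adjacency is in index (= lex) order
    }
    size <- rep(1L, n)
    for (v in reach[order(dist[reach], decreasing = TRUE)]) {
      if (v == s) next
      size[parent[v]] <- size[parent[v]] + size[v]
    }
    pts <- reach[reach != s & size[reach] > nc / 4]
    score[pts] <- score[pts] + 1L
  }
  score
}

#' All seven centrality measures at once
#'
#' @param graph an [interaction_graph()].
#' @return data frame (class `centrality_table`) with one row per node and
#'   columns `node`, `degree`, `betweenness`, `closeness`, `stress`,
#'   `radiality`, `mnc`, `bottleneck`.
#' @export
centrality_table <- function(graph) {
  n <- length(graph$nodes)
  if (n == 0) stop_data("empty graph")
  sp <- all_pairs_sp(graph)
  bs <- btw_stress_from_sp(sp)
  inv <- 1 / sp$D; diag(inv) <- 0
  out <- data.frame(
    node = graph$nodes,
    degree = vapply(graph$adj, length, integer(1)),
    betweenness = bs$betweenness,
    closeness = rowSums(inv),
    stress = bs$stress,
    radiality = radiality_from_sp(graph, sp$D),
    mnc = vapply(seq_len(n), function(v) mnc_one(graph, v), numeric(1)),
    bottleneck = bottleneck_scores_raw(graph),
    stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}

hub_measures <- c("degree", "betweenness", "closeness", "stress",
                  "radiality", "mnc", "bottleneck")

#' Select hub genes from a PPI network
#'
#' Ranks every node under the seven centrality measures and aggregates:
#' `"mean_rank"` (default) averages the descending score ranks (ties share
#' the average rank) and keeps the `k` smallest aggregates; `"topk_count"`
#' counts appearances in each measure's top-`k` list and keeps the `k` most
#' frequent. Ties are broken by higher degree, then lexicographic node id,
#' so the ordering is total and reproducible.
#'
#' @param graph an [interaction_graph()] with at least `k` nodes.
#' @param k number of hubs (default 10).
#' @param method `"mean_rank"` or `"topk_count"`.
#' @return object of class `hub_selection`: data frame with `node`, the
#'   per-measure ranks, `aggregate` (mean rank or top-k count) and `rank`;
#'   the first `k` rows are the selected hubs (attribute `k`).
#' @export
select_hubs <- function(graph, k = 10, method = c("mean_rank", "topk_count")) {
  method <- match.arg(method)
  if (k <= 0) stop_config("k must be positive")
  ct <- centrality_table(graph)
  k <- min(k, nrow(ct))
  ranks <- vapply(hub_measures, function(m) rank(-ct[[m]]),
                  numeric(nrow(ct)))
  if (method == "mean_rank") {
    aggregate <- rowMeans(ranks)
    ord <- order(aggregate, -ct$degree, ct$node)
  } else {
    in_top <- vapply(hub_measures, function(m) {
      o <- order(-ct[[m]], -ct$degree, ct$node)
      seq_len(nrow(ct)) %in% o[seq_len(k)]
    }, logical(nrow(ct)))
    aggregate <- rowSums(in_top)
    ord <- order(-aggregate, -ct$degree, ct$node)
  }
  out <- data.frame(node = ct$node, ranks, aggregate = aggregate,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("hub_selection", "data.frame"),
            k = k, method = method)
}

#' @export
print.hub_selection <- function(x, ...) {
  k <- attr(x, "k")
  cat(sprintf("<hub_selection: top %d of %d nodes by %s>\n", k, nrow(x),
              attr(x, "method")))
  print.data.frame(utils::head(as.data.frame(x)[, c("node", "aggregate",
                                                    "rank")], k))
  invisible(x)
}

#' Hub gene list
#'
#' @param selection a [select_hubs()] result.
#' @return character vector of the selected hub node ids, best first.
#' @export
hub_genes <- function(selection) {
  selection$node[seq_len(attr(selection, "k"))]
}

#' Rank regulators of a target gene set
#'
#' Orders the regulators of a bipartite regulator-to-gene network by the
#' number of distinct target genes they hit (descending, ties broken
#' lexicographically), independently within each regulator kind (e.g. TF
#' vs miRNA). Regulators hitting no target are excluded.
#'
#' @param network data frame with columns `regulator`, `kind`, `gene`
#'   (directed regulator -> gene edges; duplicates collapsed).
#' @param target_genes non-empty character vector of target gene ids.
#' @param top_n regulators to keep per kind (default all).
#' @return data frame with columns `regulator`, `kind`, `n_targets`,
#'   ordered within kind.
#' @export
rank_regulators <- function(network, target_genes, top_n = Inf) {
  if (length(target_genes) == 0) stop_config("empty target gene set")
  network <- as.data.frame(network)
  if (!all(c("regulator", "kind", "gene") %in% names(network)))
    stop_data("network needs columns regulator, kind, gene")
  network <- unique(network[, c("regulator", "kind", "gene")])
  hit <- network[network$gene %in% target_genes, , drop = FALSE]
  if (nrow(hit) == 0)
    return(data.frame(regulator = character(0), kind = character(0),
                      n_targets = integer(0)))
  counts <- aggregate(gene ~ regulator + kind, data = hit,
                      FUN = function(g) length(unique(g)))
  names(counts)[3] <- "n_targets"
  out <- do.call(rbind, lapply(split(counts, counts$kind), function(d) {
    d <- d[order(-d$n_targets, d$regulator), , drop = FALSE]
    utils::head(d, top_n)
  }))
  rownames(out) <- NULL
  out
}
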