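#' Gene-set collection
#'
#' Named gene sets over a universe of annotated genes. The universe defaults
#' to the union of the sets; a user-supplied background is accepted and must
#' cover every set.
#'
#' @param sets named list of character vectors (duplicates within a set are
#'   collapsed).
#' @param universe optional character vector of annotated genes.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  sets <- lapply(sets, unique)
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  bad <- vapply(sets, function(s) !all(s %in% universe), logical(1))
  if (any(bad))
    stop_data("set(s) not contained in the universe: ",
              paste(names(sets)[bad], collapse = ", "))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection: %d sets over %d genes>\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Build the 2x2 enrichment contingency table
#'
#' Cells: k (query genes in the set), M - k (set genes not in the query),
#' n - k (query genes outside the set), N - M - n + k (the rest); they sum
#' to the universe size N. Query genes outside the universe are dropped
#' with a warning.
#'
#' @param query_genes character vector of query gene ids.
#' @param set_genes character vector, must be contained in `universe`.
#' @param universe character vector of annotated genes (non-empty).
#' @return list with `k`, `M`, `n`, `N`, `cells` (2x2 matrix) and `overlap`
#'   (the k overlapping ids).
#' @export
build_contingency <- function(query_genes, set_genes, universe) {
  if (length(universe) == 0) stop_config("empty universe")
  universe <- unique(universe)
  set_genes <- unique(set_genes)
  query_genes <- unique(query_genes)
  if (!all(set_genes %in% universe))
    stop_data("set genes outside the universe")
  outside <- setdiff(query_genes, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query_genes <- intersect(query_genes, universe)
  }
  N <- length(universe); M <- length(set_genes); n <- length(query_genes)
  overlap <- intersect(query_genes, set_genes)
  k <- length(overlap)
  cells <- matrix(c(k, M - k, n - k, N - M - n + k), nrow = 2, byrow = TRUE,
                  dimnames = list(c("in_set", "not_in_set"),
                                  c("query", "not_query")))
  if (any(cells < 0)) stop_data("impossible contingency configuration")
  list(k = k, M = M, n = n, N = N, cells = cells, overlap = overlap)
}

#' One-sided over-representation p-value
#'
#' Upper-tail hypergeometric probability P(X >= k) with X ~
#' Hypergeometric(N, M, n) — the Fisher exact test for over-representation.
#'
#' @param table a [build_contingency()] result.
#' @return p-value in (0, 1\].
#' @export
enrichment_test <- function(table) {
  with(table, {
    if (any(c(k, M, n, N) < 0) || M > N || n > N || k > min(M, n))
      stop_data("impossible contingency configuration")
    phyper(k - 1, M, N - M, n, lower.tail = FALSE)
  })
}

#' Test a query gene set against every set of a collection
#'
#' One hypergeometric test per set, Benjamini-Hochberg adjustment across the
#' collection, results sorted by raw p-value.
#'
#' @param query_genes non-empty character vector.
#' @param collection a [gene_set_collection()].
#' @param p_cut adjusted-p significance threshold (default 0.05).
#' @return data frame (class `enrichment_result`) with columns `set`, `k`,
#'   `M`, `n`, `N`, `p`, `adj_p`, `significant`, `overlap`
#'   (comma-separated ids).
#' @export
enrich_collection <- function(query_genes, collection, p_cut = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(query_genes) == 0 || length(collection$sets) == 0)
    stop_data("need a non-empty query and collection")
  rows <- lapply(names(collection$sets), function(nm) {
    ct <- suppressWarnings(
      build_contingency(query_genes, collection$sets[[nm]],
                        collection$universe))
    data.frame(set = nm, k = ct$k, M = ct$M, n = ct$n, N = ct$N,
               p = enrichment_test(ct),
               overlap = paste(sort(ct$overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- adjust_pvalues(out$p, "bh")
  out$significant <- out$adj_p < p_cut
  out <- out[order(out$p, out$set),
             c("set", "k", "M", "n", "N", "p", "adj_p", "significant",
               "overlap")]
  rownames(out) <- NULL
  dropped <- length(setdiff(unique(query_genes), collection$universe))
  if (dropped > 0)
    stage_message("enrich", dropped, " query gene(s) outside the universe ",
                  "were dropped")
  structure(out, class = c("enrichment_result", "data.frame"),
            p_cut = p_cut, n_query_dropped = dropped)
}

#' Methylation beta-value
#'
#' beta = M / (M + U + 100), where M and U are the methylated and
#' unmethylated probe intensities. The +100 stabilizer keeps the value in
#' \[0, 1) even at extreme intensities. Vectorized.
#'
#' @param M_intensity,U_intensity non-negative intensities.
#' @return beta values in \[0, 1).
#' @export
beta_value <- function(M_intensity, U_intensity) {
  if (any(M_intensity < 0) || any(U_intensity < 0))
    stop_data("intensities must be non-negative")
  M_intensity / (M_intensity + U_intensity + 100)
}

#' Compare group mean beta-values
#'
#' Calls a probe hypo- or hypermethylated in group 1 relative to group 2
#' when the group mean beta differs by more than `margin`; no fixed
#' biological cutoff is imposed.
#'
#' @param beta1,beta2 beta-value vectors for the two groups.
#' @param margin minimum absolute difference of means (default 0.1).
#' @return one of `"hypomethylated"`, `"hypermethylated"`, `"unchanged"`,
#'   plus the mean difference as attribute `delta`.
#' @export
methylation_call <- function(beta1, beta2, margin = 0.1) {
  delta <- mean(beta1) - mean(beta2)
  call <- if (delta < -margin) "hypomethylated"
          else if (delta > margin) "hypermethylated" else "unchanged"
  structure(call, delta = delta)
}
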