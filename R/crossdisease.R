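#' Intersect DEG calls across the cohorts of one disease
#'
#' A gene is a common DEG (cDEG) for a disease when its per-cohort calls
#' agree. Genes absent from some cohorts (platform differences) are
#' tolerated: under `"strict"` (default) a gene is kept iff it is called a
#' DEG with the same direction in every cohort where it is measured; under
#' `"majority"` it must be a same-direction DEG in more than half of all
#' cohorts.
#'
#' @param deg_tables list of [classify_degs()] results (one per cohort).
#' @param mode `"strict"` or `"majority"`.
#' @return named character vector mapping kept gene ids to `"up"`/`"down"`.
#' @export
intersect_common_degs <- function(deg_tables, mode = c("strict", "majority")) {
  mode <- match.arg(mode)
  if (length(deg_tables) < 1) stop_data("need at least one DEG table")
  for (tab in deg_tables) {
    if (!all(c("gene_id", "direction") %in% names(tab)))
      stop_data("each table needs gene_id and direction columns")
    if (anyDuplicated(tab$gene_id))
      stop_data("duplicate gene ids within one DEG table")
  }
  genes <- unique(unlist(lapply(deg_tables, `[[`, "gene_id")))
  calls <- vapply(deg_tables, function(tab) {
    d <- tab$direction[match(genes, tab$gene_id)]
    ifelse(is.na(d), "absent", d)
  }, character(length(genes)))
  if (length(genes) == 1) calls <- matrix(calls, nrow = 1)
  n_up <- rowSums(calls == "up")
  n_down <- rowSums(calls == "down")
  n_present <- rowSums(calls != "absent")
  keep_dir <- rep(NA_character_, length(genes))
  if (mode == "strict") {
    keep_dir[n_present > 0 & n_up == n_present] <- "up"
    keep_dir[n_present > 0 & n_down == n_present] <- "down"
  } else {
    half <- length(deg_tables) / 2
    keep_dir[n_up > half] <- "up"
    keep_dir[n_down > half] <- "down"
  }
  out <- keep_dir[!is.na(keep_dir)]
  names(out) <- genes[!is.na(keep_dir)]
  out
}

#' Aggregate per-cohort fold changes into a per-disease profile
#'
#' Unweighted mean of the per-cohort aLog2FC values over the cohorts where
#' each gene was measured, with contributing-cohort counts. Genes absent
#' from every cohort are returned in the `rejects` attribute rather than
#' silently dropped.
#'
#' @param deg_tables list of per-cohort tables carrying `gene_id` and
#'   `alog2fc`.
#' @param genes character vector of genes to aggregate.
#' @param disease_id label stored with the profile.
#' @return object of class `fold_change_profile`: data frame with columns
#'   `gene_id`, `alog2fc`, `n_datasets`.
#' @export
aggregate_disease_fold_changes <- function(deg_tables, genes,
                                           disease_id = "disease") {
  fc <- vapply(deg_tables, function(tab)
    tab$alog2fc[match(genes, tab$gene_id)], numeric(length(genes)))
  if (length(genes) == 1) fc <- matrix(fc, nrow = 1)
  n_ds <- rowSums(!is.na(fc))
  rejects <- genes[n_ds == 0]
  keep <- n_ds > 0
  prof <- data.frame(gene_id = genes[keep],
                     alog2fc = rowMeans(fc, na.rm = TRUE)[keep],
                     n_datasets = n_ds[keep],
                     stringsAsFactors = FALSE)
  structure(prof, class = c("fold_change_profile", "data.frame"),
            disease_id = disease_id, rejects = rejects)
}

#' Intersect two diseases' common DEGs into the shared DEG set
#'
#' @param cdegs1,cdegs2 named direction vectors from
#'   [intersect_common_degs()].
#' @param require_concordant if `TRUE` (default) a gene must have the same
#'   direction in both diseases; otherwise discordant genes are kept with
#'   direction `"discordant"`.
#' @return object of class `shared_deg_set`: data frame with columns
#'   `gene_id`, `dir_disease1`, `dir_disease2`, `direction`; attributes
#'   `n_up` and `n_down` count the concordant directions.
#' @export
intersect_shared_degs <- function(cdegs1, cdegs2, require_concordant = TRUE) {
  common <- intersect(names(cdegs1), names(cdegs2))
  d1 <- unname(cdegs1[common]); d2 <- unname(cdegs2[common])
  concord <- d1 == d2
  direction <- ifelse(concord, d1, "discordant")
  if (require_concordant) {
    common <- common[concord]
    d1 <- d1[concord]; d2 <- d2[concord]; direction <- direction[concord]
  }
  out <- data.frame(gene_id = common, dir_disease1 = d1, dir_disease2 = d2,
                    direction = direction, stringsAsFactors = FALSE)
  structure(out, class = c("shared_deg_set", "data.frame"),
            n_up = sum(direction == "up"), n_down = sum(direction == "down"))
}

#' @export
print.shared_deg_set <- function(x, ...) {
  cat(sprintf("<shared_deg_set: %d genes (%d up, %d down)>\n",
              nrow(x), attr(x, "n_up"), attr(x, "n_down")))
  NextMethod()
}

#' Local genetic association between two diseases
#'
#' Pearson correlation between the two diseases' aggregated aLog2FC values
#' over a common gene set (typically the shared DEGs). Genes missing from
#' either profile are excluded and reported.
#'
#' @param profile_x,profile_y [aggregate_disease_fold_changes()] results.
#' @param genes genes to correlate; defaults to the profiles' common genes.
#' @return object of class `association_result`: list with `r`, `n_genes`,
#'   `excluded`, and (after [association_permutation_p()]) `p_perm`,
#'   `n_perm`, `seed`.
#' @export
local_association <- function(profile_x, profile_y, genes = NULL) {
  if (is.null(genes))
    genes <- intersect(profile_x$gene_id, profile_y$gene_id)
  x <- profile_x$alog2fc[match(genes, profile_x$gene_id)]
  y <- profile_y$alog2fc[match(genes, profile_y$gene_id)]
  excluded <- genes[is.na(x) | is.na(y)]
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop_data("need >= 3 genes present in both profiles (have ",
              length(x), ")")
  if (sd(x) == 0 || sd(y) == 0)
    stop_data("undefined correlation: zero variance in a fold-change profile")
  structure(list(r = cor(x, y), n_genes = length(x), excluded = excluded,
                 genes = genes[keep], x = x, y = y,
                 p_perm = NULL, n_perm = NULL, seed = NULL),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result: r = %.4f over %d genes%s>\n", x$r,
              x$n_genes,
              if (!is.null(x$p_perm))
                sprintf(", permutation p = %.4g (%d perms)", x$p_perm,
                        x$n_perm) else ""))
  invisible(x)
}

#' Permutation p-value for the local association
#'
#' Two-sided add-one estimator: p = (1 + #\{|r_perm| >= |r_obs|\}) /
#' (n_perm + 1), permuting the second profile's values over genes.
#'
#' @inheritParams local_association
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return an `association_result` with `p_perm` filled in.
#' @export
association_permutation_p <- function(profile_x, profile_y, genes = NULL,
                                      n_perm = 999L, seed = 1L) {
  if (n_perm < 100) stop_config("n_perm must be >= 100")
  obs <- local_association(profile_x, profile_y, genes)
  set.seed(seed)
  r_perm <- replicate(n_perm, cor(obs$x, sample(obs$y)))
  obs$p_perm <- (1 + sum(abs(r_perm) >= abs(obs$r))) / (n_perm + 1)
  obs$n_perm <- as.integer(n_perm)
  obs$seed <- as.integer(seed)
  obs
}
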