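#' Simulation configuration for a two-disease expression study design
#'
#' Describes the synthetic study: two diseases, several independent
#' case/control cohorts each, a hierarchical per-gene variance model
#' (sigma_g^2 ~ scaled-inverse-chi^2(d0, s0^2)), and planted gene classes
#' (shared up, shared down, disease-specific, null) whose cross-disease
#' effect sizes are drawn from a bivariate normal with correlation `rho`.
#'
#' Defaults mirror an eight-cohort microarray design (4 cohorts per disease,
#' 6-27 samples per group) with 2000 genes, 120 shared up-regulated genes of
#' mean effect 1.5 log2 units (spread 0.2), cross-disease effect correlation
#' 0.8 and variance prior d0 = 4, s0^2 = 0.05. The shared genes default to a
#' single direction class because the planted correlation is only
#' identifiable within a direction class (mixing up and down classes makes
#' any between-class separation dominate a Pearson correlation).
#'
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @param n_genes total number of genes.
#' @param n_datasets_per_disease cohorts per disease.
#' @param samples_per_group list of two lists (one per disease), each holding
#'   `n_datasets_per_disease` integer pairs `c(cases, controls)`. `NULL`
#'   uses the default design (6/7, 12/12, 12/12, 12/12; 14/14, 27/27,
#'   12/12, 13/13).
#' @param n_shared_up,n_shared_down genes up-/down-regulated in both
#'   diseases.
#' @param n_specific_per_disease genes perturbed in exactly one disease
#'   (this many in each).
#' @param effect_mean,effect_sd mean and between-gene spread of the absolute
#'   planted effect, log2 units.
#' @param cross_disease_effect_correlation correlation `rho` in \[-1, 1\] of
#'   the two diseases' effects for shared genes.
#' @param variance_prior_df,variance_prior_scale d0 > 0 and s0^2 > 0 of the
#'   scaled-inverse-chi^2 variance prior.
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline abundance
#'   distribution on the log2 scale.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 2000L,
                              n_datasets_per_disease = 4L,
                              samples_per_group = NULL,
                              n_shared_up = 120L,
                              n_shared_down = 0L,
                              n_specific_per_disease = 40L,
                              effect_mean = 1.5,
                              effect_sd = 0.2,
                              cross_disease_effect_correlation = 0.8,
                              variance_prior_df = 4,
                              variance_prior_scale = 0.05,
                              baseline_log2_mean = 7,
                              baseline_log2_sd = 1.5) {
  if (is.null(samples_per_group)) {
    samples_per_group <- list(
      disease1 = list(c(6L, 7L), c(12L, 12L), c(12L, 12L), c(12L, 12L)),
      disease2 = list(c(14L, 14L), c(27L, 27L), c(12L, 12L), c(13L, 13L)))
    samples_per_group <- lapply(samples_per_group, function(d)
      d[seq_len(min(n_datasets_per_disease, length(d)))])
    if (length(samples_per_group$disease1) < n_datasets_per_disease)
      samples_per_group <- lapply(samples_per_group, function(d)
        c(d, rep(list(c(12L, 12L)),
                 n_datasets_per_disease - length(d))))
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_datasets_per_disease = as.integer(n_datasets_per_disease),
              samples_per_group = samples_per_group,
              n_shared_up = as.integer(n_shared_up),
              n_shared_down = as.integer(n_shared_down),
              n_specific_per_disease = as.integer(n_specific_per_disease),
              effect_mean = effect_mean, effect_sd = effect_sd,
              cross_disease_effect_correlation = cross_disease_effect_correlation,
              variance_prior_df = variance_prior_df,
              variance_prior_scale = variance_prior_scale,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd)
  counts <- c(cfg$n_genes, cfg$n_shared_up, cfg$n_shared_down,
              cfg$n_specific_per_disease, cfg$n_datasets_per_disease)
  if (any(counts < 0)) stop_config("all counts must be >= 0")
  if (cfg$n_shared_up + cfg$n_shared_down + 2L * cfg$n_specific_per_disease >
      cfg$n_genes)
    stop_config("planted gene classes exceed n_genes")
  if (abs(cfg$cross_disease_effect_correlation) > 1)
    stop_config("cross_disease_effect_correlation must lie in [-1, 1]")
  if (cfg$variance_prior_df <= 0 || cfg$variance_prior_scale <= 0)
    stop_config("variance prior hyperparameters must be positive")
  for (d in cfg$samples_per_group)
    for (p in d) if (length(p) != 2 || any(p < 2))
      stop_config("each cohort needs c(cases, controls), both >= 2")
  structure(cfg, class = "simulation_config")
}

#' Generate two diseases' worth of synthetic expression cohorts
#'
#' Gene classes are assigned in a fixed order (shared up, shared down,
#' disease-1-specific, disease-2-specific, null). Each gene gets one true
#' variance sigma_g^2 = d0 s0^2 / chi^2_d0 shared by every cohort of both
#' diseases. Shared genes draw their per-disease effect pair from a
#' bivariate normal with means +/- `effect_mean`, sd `effect_sd` and
#' correlation `rho`; disease-specific genes draw a single effect of random
#' sign from the same marginal; null genes have zero effect in both
#' diseases. Log2 expression for a sample is baseline + effect (cases only)
#' + N(0, sigma_g), and intensities are 2^(log2 value), hence strictly
#' positive.
#'
#' @param config a [simulation_config()].
#' @return list with `studies` (list of two lists of [expression_study()]
#'   objects, named `disease1` and `disease2`) and `truth` (data frame:
#'   gene_id, class, effect_disease1, effect_disease2, sigma_sq).
#' @export
generate_two_disease_studies <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n))
  class <- rep("null", n)
  idx <- 0L
  take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }
  i_up <- take(config$n_shared_up)
  i_dn <- take(config$n_shared_down)
  i_s1 <- take(config$n_specific_per_disease)
  i_s2 <- take(config$n_specific_per_disease)
  class[i_up] <- "shared_up"; class[i_dn] <- "shared_down"
  class[i_s1] <- "specific_disease1"; class[i_s2] <- "specific_disease2"

  sigma_sq <- config$variance_prior_df * config$variance_prior_scale /
    rchisq(n, df = config$variance_prior_df)
  baseline <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

  e1 <- numeric(n); e2 <- numeric(n)
  rho <- config$cross_disease_effect_correlation
  draw_pair <- function(k, sign) {
    z1 <- rnorm(k); z2 <- rnorm(k)
    cbind(sign * config$effect_mean + config$effect_sd * z1,
          sign * config$effect_mean +
            config$effect_sd * (rho * z1 + sqrt(1 - rho^2) * z2))
  }
  if (length(i_up)) { p <- draw_pair(length(i_up), +1); e1[i_up] <- p[, 1]; e2[i_up] <- p[, 2] }
  if (length(i_dn)) { p <- draw_pair(length(i_dn), -1); e1[i_dn] <- p[, 1]; e2[i_dn] <- p[, 2] }
  if (length(i_s1))
    e1[i_s1] <- sample(c(-1, 1), length(i_s1), replace = TRUE) *
      rnorm(length(i_s1), config$effect_mean, config$effect_sd)
  if (length(i_s2))
    e2[i_s2] <- sample(c(-1, 1), length(i_s2), replace = TRUE) *
      rnorm(length(i_s2), config$effect_mean, config$effect_sd)

  make_disease <- function(effects, disease_name, designs) {
    lapply(seq_along(designs), function(d) {
      set.seed(derive_seed())
      nc <- designs[[d]][1]; nk <- designs[[d]][2]
      grp <- c(rep("case", nc), rep("control", nk))
      mu <- outer(baseline, rep(1, nc + nk)) +
        outer(effects, as.numeric(grp == "case"))
      noise <- matrix(rnorm(n * (nc + nk), 0, rep(sqrt(sigma_sq), nc + nk)),
                      nrow = n)
      m <- 2^(mu + noise)
      dimnames(m) <- list(gene_ids,
                          sprintf("%s_D%d_S%02d", disease_name, d,
                                  seq_len(nc + nk)))
      expression_study(m, grp, study_id = sprintf("%s_cohort%d",
                                                  disease_name, d))
    })
  }
  studies <- list(
    disease1 = make_disease(e1, "disease1", config$samples_per_group[[1]]),
    disease2 = make_disease(e2, "disease2", config$samples_per_group[[2]]))
  truth <- data.frame(gene_id = gene_ids, class = class,
                      effect_disease1 = e1, effect_disease2 = e2,
                      sigma_sq = sigma_sq, stringsAsFactors = FALSE)
  list(studies = studies, truth = truth)
}

#' Generate a PPI-like graph with planted hubs
#'
#' Background nodes are wired as an Erdos-Renyi graph with the given edge
#' density; each planted hub is then attached to `hub_degree` distinct
#' background nodes. The construction is validated, not rewired: with a
#' density high enough that some background node reaches `hub_degree`, a
#' configuration error is raised.
#'
#' @param n_background_nodes,n_planted_hubs node counts
#'   (`n_planted_hubs < n_background_nodes`).
#' @param hub_degree neighbors per planted hub (must be `<` total node
#'   count).
#' @param density background edge probability in \[0, 1\].
#' @param seed integer seed.
#' @return an `interaction_graph` whose planted hubs are named `HUB1`,
#'   `HUB2`, ... (attribute `planted_hubs`).
#' @export
generate_ppi_graph <- function(n_background_nodes, n_planted_hubs,
                               hub_degree, density = 0.02, seed = 1L) {
  if (n_planted_hubs >= n_background_nodes)
    stop_config("need n_planted_hubs < n_background_nodes")
  n_total <- n_background_nodes + n_planted_hubs
  if (n_planted_hubs > 0 && hub_degree >= n_total)
    stop_config("hub_degree must be smaller than the node count")
  if (density < 0 || density > 1) stop_config("density must lie in [0, 1]")
  set.seed(seed)
  bg <- sprintf("B%04d", seq_len(n_background_nodes))
  hubs <- if (n_planted_hubs > 0) sprintf("HUB%d", seq_len(n_planted_hubs))
          else character(0)
  edges <- matrix(character(0), ncol = 2)
  if (n_background_nodes >= 2 && density > 0) {
    pairs <- t(combn(bg, 2))
    keep <- runif(nrow(pairs)) < density
    edges <- pairs[keep, , drop = FALSE]
  }
  for (h in hubs) {
    nb <- sample(bg, hub_degree)
    edges <- rbind(edges, cbind(h, nb))
  }
  g <- interaction_graph(edges, nodes = c(bg, hubs))
  if (n_planted_hubs > 0) {
    deg <- vapply(g$adj, length, integer(1))
    names(deg) <- g$nodes
    if (min(deg[hubs]) <= max(deg[setdiff(g$nodes, hubs)]))
      stop_config("planted hubs do not dominate background degrees; ",
                  "lower density or raise hub_degree")
  }
  attr(g, "planted_hubs") <- hubs
  g
}

#' Generate a gene-set collection with one planted enriched set
#'
#' The first (designated) set contains every planted gene, padded with
#' random universe genes up to a size drawn from `set_size_range`; the
#' remaining sets are uniform draws from the universe.
#'
#' @param n_sets total number of sets (>= 1 unless `planted_set` is empty).
#' @param set_size_range integer pair, inclusive range of set sizes.
#' @param universe character vector of annotated gene ids.
#' @param planted_set subset of `universe` guaranteed to sit in the first
#'   set.
#' @param seed integer seed.
#' @return a [gene_set_collection()]; the designated set is named
#'   `"PLANTED"`.
#' @export
generate_gene_set_collection <- function(n_sets, set_size_range, universe,
                                         planted_set = character(0),
                                         seed = 1L) {
  if (!all(planted_set %in% universe))
    stop_config("planted_set must be a subset of the universe")
  if (max(set_size_range) > length(universe))
    stop_config("set sizes exceed the universe")
  if (n_sets == 0) {
    if (length(planted_set) > 0)
      stop_config("cannot plant a set in an empty collection")
    return(gene_set_collection(list(), universe = universe))
  }
  set.seed(seed)
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                  replace = TRUE)
  sets <- vector("list", n_sets)
  sizes[1] <- max(sizes[1], length(planted_set))
  pad <- sample(setdiff(universe, planted_set),
                sizes[1] - length(planted_set))
  sets[[1]] <- c(planted_set, pad)
  if (n_sets > 1)
    for (i in 2:n_sets) sets[[i]] <- sample(universe, sizes[i])
  names(sets) <- c("PLANTED", if (n_sets > 1) sprintf("SET%03d", 2:n_sets))
  gene_set_collection(sets, universe = universe)
}

#' Generate a binding-affinity-score matrix with planted strong ligands
#'
#' Entries are kcal/mol docking scores (more negative = stronger). The first
#' `n_strong_ligands` columns are centred at `strong_mean`, the rest at
#' `weak_mean`, with independent Gaussian noise. Defaults mirror a screen of
#' 30 candidate molecules against 15 receptor proteins with 3 planted strong
#' binders.
#'
#' @param n_receptors,n_ligands matrix dimensions (>= 1).
#' @param n_strong_ligands planted strong columns (`<= n_ligands`).
#' @param strong_mean,weak_mean column centres, kcal/mol
#'   (`strong_mean < weak_mean`).
#' @param noise_sd entry-level noise sd, kcal/mol.
#' @param seed integer seed.
#' @return a [bas_matrix()]; planted strong ligand ids are in attribute
#'   `strong_ligands`.
#' @export
generate_bas_matrix <- function(n_receptors = 15L, n_ligands = 30L,
                                n_strong_ligands = 3L, strong_mean = -8.5,
                                weak_mean = -6.0, noise_sd = 0.5,
                                seed = 1L) {
  if (n_receptors < 1 || n_ligands < 1)
    stop_config("matrix dimensions must be >= 1")
  if (n_strong_ligands > n_ligands)
    stop_config("n_strong_ligands must be <= n_ligands")
  if (strong_mean >= weak_mean)
    stop_config("strong_mean must be more negative than weak_mean")
  set.seed(seed)
  centre <- c(rep(strong_mean, n_strong_ligands),
              rep(weak_mean, n_ligands - n_strong_ligands))
  m <- matrix(rep(centre, each = n_receptors), nrow = n_receptors) +
    matrix(rnorm(n_receptors * n_ligands, 0, noise_sd), nrow = n_receptors)
  dimnames(m) <- list(sprintf("REC%02d", seq_len(n_receptors)),
                      sprintf("LIG%02d", seq_len(n_ligands)))
  b <- bas_matrix(m)
  attr(b, "strong_ligands") <- colnames(m)[seq_len(n_strong_ligands)]
  b
}
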