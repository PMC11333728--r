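#' Assemble a pipeline configuration
#'
#' Either a YAML file or an R list. Top-level keys:
#' \describe{
#'   \item{simulate}{list of [simulation_config()] arguments — the pipeline
#'     then generates its own two-disease cohorts; alternatively
#'     `expression` gives real input paths.}
#'   \item{expression}{list with `disease1` and `disease2`, each a list of
#'     `list(expr = , samples = )` path pairs.}
#'   \item{deg}{`p_cut` (0.05), `fc_cut` (1), `adjust` ("bh").}
#'   \item{intersection}{`mode` ("strict"), `require_concordant` (TRUE).}
#'   \item{association}{`n_perm` (999).}
#'   \item{network}{path to an edge list / SIF, or a list of
#'     [generate_ppi_graph()] arguments, or NULL to skip hub selection.}
#'   \item{hubs}{`k` (10), `method` ("mean_rank").}
#'   \item{gene_sets}{GMT path, or a list of
#'     [generate_gene_set_collection()] arguments (planted set defaults to
#'     the selected hubs), or NULL to skip enrichment.}
#'   \item{enrich}{`p_cut` (0.05).}
#'   \item{bas}{CSV path or a list of [generate_bas_matrix()] arguments or
#'     NULL; `avg_cut` (-7.7) and `per_receptor_cut` (-7.0) live under
#'     `drug`.}
#'   \item{seed}{master seed; every stage's randomness derives from it.}
#' }
#'
#' @param config list or path to a YAML file.
#' @return validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_config("config must be a list or YAML path")
  if (is.null(config$simulate) && is.null(config$expression))
    stop_config("config needs either a 'simulate' block or 'expression' paths")
  config$seed <- as.integer(config$seed %||% 1L)
  config$deg <- utils::modifyList(
    list(p_cut = 0.05, fc_cut = 1.0, adjust = "bh"), config$deg %||% list())
  config$intersection <- utils::modifyList(
    list(mode = "strict", require_concordant = TRUE),
    config$intersection %||% list())
  config$association <- utils::modifyList(
    list(n_perm = 999L), config$association %||% list())
  config$hubs <- utils::modifyList(
    list(k = 10L, method = "mean_rank"), config$hubs %||% list())
  config$enrich <- utils::modifyList(
    list(p_cut = 0.05), config$enrich %||% list())
  config$drug <- utils::modifyList(
    list(avg_cut = -7.7, per_receptor_cut = -7.0, min_coverage = 0.8),
    config$drug %||% list())
  structure(config, class = "pipeline_config")
}

#' Run the whole cross-disease pipeline
#'
#' Stages: per-cohort differential expression; within-disease common-DEG
#' intersection; cross-disease shared-DEG intersection; fold-change
#' aggregation and local association (with permutation p); PPI hub
#' selection (when a network is configured); gene-set enrichment of the
#' hubs (when gene sets are configured); BAS drug ranking and selection
#' (when a score matrix is configured). All stage tables are written under
#' `outdir` together with a single `report.json`; the run is fully
#' deterministic given the seed. A stage failure aborts with a stage-tagged
#' error; a MANIFEST file marks which stages completed.
#'
#' @param config a [pipeline_config()] (or list / YAML path coerced to one).
#' @param outdir output directory, created if needed.
#' @return the report (class `pipeline_report`), invisibly also written as
#'   JSON.
#' @export
run_pipeline <- function(config, outdir = tempfile("crossdx_")) {
  config <- pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(outdir, "MANIFEST")
  done <- character(0)
  mark <- function(stage) {
    done <<- c(done, stage)
    writeLines(done, manifest)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(sprintf("[%s] %s", stage, conditionMessage(e)),
                          class = c("crossdx_stage_error", "error")))
    })
  }
  set.seed(config$seed)
  seeds <- list(sim = derive_seed(), assoc = derive_seed(),
                net = derive_seed(), sets = derive_seed(),
                bas = derive_seed())
  truth <- NULL

  # --- input stage -----------------------------------------------------
  studies <- run_stage("input", {
    if (!is.null(config$simulate)) {
      sim_args <- utils::modifyList(config$simulate,
                                    list(seed = config$simulate$seed %||%
                                           seeds$sim))
      sim <- generate_two_disease_studies(do.call(simulation_config,
                                                  sim_args))
      truth <- sim$truth
      utils::write.table(truth, file.path(outdir, "truth_labels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sim$studies
    } else {
      lapply(config$expression, function(cohorts)
        lapply(cohorts, function(co)
          read_expression_study(co$expr, co$samples)))
    }
  })
  stage_message("input", sprintf("%d + %d cohorts", length(studies[[1]]),
                                 length(studies[[2]])))
  mark("input")

  # --- differential expression -----------------------------------------
  degs <- run_stage("deg", lapply(studies, function(cohorts)
    lapply(cohorts, function(st) {
      d <- run_deg(st, p_cut = config$deg$p_cut, fc_cut = config$deg$fc_cut,
                   adjust = config$deg$adjust)
      write_deg_table(d, file.path(outdir, paste0("deg_", attr(d, "study_id"),
                                                  ".tsv")))
      d
    })))
  deg_counts <- lapply(degs, function(tabs) lapply(tabs, function(d)
    list(study_id = attr(d, "study_id"), n_up = attr(d, "n_up"),
         n_down = attr(d, "n_down"))))
  mark("deg")

  # --- intersections ----------------------------------------------------
  shared <- run_stage("shared", {
    cdegs <- lapply(degs, intersect_common_degs,
                    mode = config$intersection$mode)
    sh <- intersect_shared_degs(
      cdegs[[1]], cdegs[[2]],
      require_concordant = config$intersection$require_concordant)
    prof1 <- aggregate_disease_fold_changes(degs[[1]], sh$gene_id,
                                            disease_id = "disease1")
    prof2 <- aggregate_disease_fold_changes(degs[[2]], sh$gene_id,
                                            disease_id = "disease2")
    out <- as.data.frame(sh)
    out$alog2fc_disease1 <- prof1$alog2fc[match(out$gene_id, prof1$gene_id)]
    out$alog2fc_disease2 <- prof2$alog2fc[match(out$gene_id, prof2$gene_id)]
    utils::write.table(out, file.path(outdir, "shared_degs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(set = sh, cdegs = cdegs, prof1 = prof1, prof2 = prof2)
  })
  stage_message("shared", sprintf("%d shared DEGs (%d up, %d down)",
                                  nrow(shared$set), attr(shared$set, "n_up"),
                                  attr(shared$set, "n_down")))
  mark("shared")

  # --- association ------------------------------------------------------
  assoc <- run_stage("associate", {
    a <- association_permutation_p(shared$prof1, shared$prof2,
                                   genes = shared$set$gene_id,
                                   n_perm = config$association$n_perm,
                                   seed = seeds$assoc)
    jsonlite::write_json(
      list(r = a$r, n_genes = a$n_genes, p_perm = a$p_perm,
           n_perm = a$n_perm, seed = a$seed),
      file.path(outdir, "association.json"), auto_unbox = TRUE, digits = NA)
    a
  })
  stage_message("associate", sprintf("r = %.3f (p_perm = %.3g)", assoc$r,
                                     assoc$p_perm))
  mark("associate")

  # --- network hubs -----------------------------------------------------
  hubs <- NULL
  if (!is.null(config$network)) {
    hubs <- run_stage("hubs", {
      graph <- if (is.character(config$network)) read_network(config$network)
        else do.call(generate_ppi_graph,
                     utils::modifyList(config$network,
                                       list(seed = config$network$seed %||%
                                              seeds$net)))
      ct <- centrality_table(graph)
      utils::write.table(ct, file.path(outdir, "centrality.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sel <- select_hubs(graph, k = config$hubs$k,
                         method = config$hubs$method)
      utils::write.table(as.data.frame(sel), file.path(outdir, "hubs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sel
    })
    mark("hubs")
  }

  # --- enrichment -------------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    enrichment <- run_stage("enrich", {
      query <- if (!is.null(hubs)) hub_genes(hubs) else shared$set$gene_id
      coll <- if (is.character(config$gene_sets))
        read_gmt(config$gene_sets)
      else {
        # default universe: the query plus simulated background genes
        universe <- config$gene_sets$universe %||%
          c(query, sprintf("BG%04d",
                           seq_len(max(100L, 10L * length(query)))))
        do.call(generate_gene_set_collection, utils::modifyList(
          config$gene_sets,
          list(seed = config$gene_sets$seed %||% seeds$sets,
               universe = universe,
               planted_set = config$gene_sets$planted_set %||%
                 intersect(query, universe))))
      }
      res <- enrich_collection(query, coll, p_cut = config$enrich$p_cut)
      utils::write.table(as.data.frame(res),
                         file.path(outdir, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      res
    })
    mark("enrich")
  }

  # --- drug ranking -----------------------------------------------------
  drugs <- NULL
  if (!is.null(config$bas)) {
    drugs <- run_stage("dockrank", {
      bas <- if (is.character(config$bas)) read_bas_csv(config$bas)
        else do.call(generate_bas_matrix,
                     utils::modifyList(config$bas,
                                       list(seed = config$bas$seed %||%
                                              seeds$bas)))
      ranking <- rank_bas_matrix(bas,
                                 min_coverage = config$drug$min_coverage)
      utils::write.table(ranking$ligands,
                         file.path(outdir, "drug_ranking.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      sel <- select_candidate_drugs(
        ranking, avg_cut = config$drug$avg_cut,
        per_receptor_cut = config$drug$per_receptor_cut)
      jsonlite::write_json(as.data.frame(sel),
                           file.path(outdir, "drug_selection.json"),
                           auto_unbox = TRUE, digits = NA)
      list(ranking = ranking, selection = sel)
    })
    mark("dockrank")
  }

  report <- structure(list(
    package_version = as.character(utils::packageVersion("crossdx")),
    seed = config$seed,
    deg = deg_counts,
    cdeg_counts = lapply(shared$cdegs, function(cd)
      list(n_up = sum(cd == "up"), n_down = sum(cd == "down"))),
    shared = list(n = nrow(shared$set), n_up = attr(shared$set, "n_up"),
                  n_down = attr(shared$set, "n_down")),
    association = list(r = assoc$r, n_genes = assoc$n_genes,
                       p_perm = assoc$p_perm),
    hubs = if (!is.null(hubs)) hub_genes(hubs),
    enrichment = if (!is.null(enrichment))
      list(top_set = enrichment$set[1],
           top_p = enrichment$p[1],
           n_significant = sum(enrichment$significant)),
    drugs = if (!is.null(drugs))
      list(selected = drugs$selection$ligand,
           mean_bas = drugs$selection$mean_bas),
    stages = c(done, "report")), class = "pipeline_report")
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  mark("report")
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  shared DEGs: %d (%d up, %d down)\n", x$shared$n,
              x$shared$n_up, x$shared$n_down))
  cat(sprintf("  association: r = %.3f over %d genes (p_perm = %.3g)\n",
              x$association$r, x$association$n_genes, x$association$p_perm))
  if (!is.null(x$hubs))
    cat("  hubs:", paste(utils::head(x$hubs, 10), collapse = ", "), "\n")
  if (!is.null(x$enrichment))
    cat(sprintf("  top enriched set: %s (p = %.3g)\n", x$enrichment$top_set,
                x$enrichment$top_p))
  if (!is.null(x$drugs))
    cat("  selected drugs:", paste(x$drugs$selected, collapse = ", "), "\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}
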