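# Readers and writers for the plain-text interchange formats the pipeline
# consumes: expression TSV + sample sheet, edge-list TSV / SIF, GMT gene
# sets, bipartite regulator TSV, BAS CSV, descriptor / ADMET TSV.

#' Write an expression study as TSV plus a sample sheet
#'
#' @param study an [expression_study()].
#' @param expr_path genes x samples TSV (first column `gene_id`).
#' @param samples_path sample sheet TSV with columns `sample_id`, `group`.
#' @export
write_expression_study <- function(study, expr_path, samples_path) {
  df <- data.frame(gene_id = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(study$matrix), group = study$group),
    samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(study)
}

#' Read an expression study from TSV plus a sample sheet
#'
#' @param expr_path,samples_path paths written by
#'   [write_expression_study()].
#' @param study_id cohort label.
#' @inheritParams expression_study
#' @return an [expression_study()].
#' @export
read_expression_study <- function(expr_path, samples_path,
                                  study_id = basename(expr_path),
                                  pseudocount = 0) {
  expr <- utils::read.table(expr_path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  samples <- utils::read.table(samples_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop_data("sample sheet needs columns sample_id and group")
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr[[1]]
  missing <- setdiff(colnames(m), samples$sample_id)
  if (length(missing) > 0)
    stop_data("samples missing from sheet: ",
              paste(missing, collapse = ", "))
  grp <- samples$group[match(colnames(m), samples$sample_id)]
  expression_study(m, grp, study_id = study_id, pseudocount = pseudocount)
}

#' Write/read a DEG table as TSV
#'
#' Columns: gene_id, alog2fc, t, p, adj_p, direction.
#' @param deg a `deg_table`.
#' @param path TSV path.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(as.data.frame(deg), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(deg)
}

#' @rdname write_deg_table
#' @param study_id cohort label for the re-read table.
#' @export
read_deg_table <- function(path, study_id = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "alog2fc", "adj_p", "direction") %in% names(tab)))
    stop_data("not a DEG table: ", path)
  structure(tab, class = c("deg_table", "data.frame"), study_id = study_id,
            n_up = sum(tab$direction == "up"),
            n_down = sum(tab$direction == "down"))
}

#' Read a network edge list (two-column TSV or SIF)
#'
#' SIF lines are `node1 <relation> node2 [node3 ...]`; every trailing node
#' yields one edge. Two-column TSV lines are plain `node1 <tab> node2`; a
#' header row named node1/node2 (or source/target) is detected and skipped.
#'
#' @param path input file.
#' @param format `"tsv"` or `"sif"`; default guessed from the extension.
#' @return an [interaction_graph()].
#' @export
read_network <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "sif") {
    edges <- do.call(rbind, lapply(strsplit(lines, "[\t ]+"), function(f) {
      if (length(f) < 3) return(NULL)
      cbind(f[1], f[-(1:2)])
    }))
    if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  } else {
    fields <- strsplit(lines, "\t")
    if (length(fields) > 0 &&
        tolower(fields[[1]][1]) %in% c("node1", "source", "from"))
      fields <- fields[-1]
    edges <- do.call(rbind, lapply(fields, function(f) f[1:2]))
    if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  }
  interaction_graph(edges)
}

#' Write a graph as a two-column TSV edge list or SIF
#'
#' @param graph an [interaction_graph()].
#' @param path output file.
#' @param format `"tsv"` or `"sif"`.
#' @param relation SIF relation label (default `"pp"`).
#' @export
write_network <- function(graph, path, format = c("tsv", "sif"),
                          relation = "pp") {
  format <- match.arg(format)
  e <- graph_edges(graph)
  if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    writeLines(paste(e[, 1], relation, e[, 2], sep = "\t"), path)
  }
  invisible(graph)
}

#' Read a gene-set collection from a GMT file
#'
#' Parsing is delegated to [fgsea::gmtPathways()] (tab-separated lines:
#' name, description, members).
#'
#' @param path GMT file.
#' @param universe optional background; defaults to the union of the sets.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  gene_set_collection(fgsea::gmtPathways(path), universe = universe)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @param descriptions optional character vector (recycled) for the second
#'   GMT column.
#' @export
write_gmt <- function(collection, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(collection$sets))
  lines <- vapply(seq_along(collection$sets), function(i)
    paste(c(names(collection$sets)[i], descriptions[i],
            collection$sets[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' Read a bipartite regulator network TSV
#'
#' Three columns: regulator, kind (e.g. TF or miRNA), gene.
#'
#' @param path TSV with a header row.
#' @return data frame with columns `regulator`, `kind`, `gene`.
#' @export
read_bipartite_network <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("regulator", "kind", "gene") %in% names(tab)))
    stop_data("bipartite network needs columns regulator, kind, gene")
  tab
}

#' Read/write a BAS matrix CSV
#'
#' First column receptor ids, header row ligand ids, empty cells = missing.
#'
#' @param path CSV file.
#' @return a [bas_matrix()].
#' @export
read_bas_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  bas_matrix(m)
}

#' @rdname read_bas_csv
#' @param matrix a [bas_matrix()].
#' @export
write_bas_csv <- function(matrix, path) {
  df <- data.frame(receptor = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(matrix)
}

#' Read a molecule descriptor or ADMET TSV
#'
#' Header names are lower-cased and mapped onto the canonical fields
#' (`compound`, `mw`, `logp`, `hba`, `hbd`, `psa`, `rotatable_bonds`;
#' `caco2`, `hia`, `pgp_inhibitor`, `logbb`, `logps`, `cyp3a4_inhibitor`,
#' `total_clearance`, `ames`, `lc50`, `ld50`).
#'
#' @param path TSV with a header row.
#' @return data frame.
#' @export
read_molecule_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  tab
}
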