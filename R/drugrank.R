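#' Binding-affinity-score matrix
#'
#' Receptors in rows, ligands in columns, entries in kcal/mol (more negative
#' = stronger predicted binding). Missing entries (failed docking runs) are
#' allowed as NA and handled by the coverage rule in [rank_bas_matrix()].
#'
#' @param matrix numeric matrix with unique row (receptor) and column
#'   (ligand) names.
#' @return object of class `bas_matrix`.
#' @export
bas_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop_data("BAS input must be a numeric matrix")
  if (nrow(matrix) < 1 || ncol(matrix) < 1) stop_config("empty BAS matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop_data("BAS matrix needs receptor row names and ligand column names")
  if (anyDuplicated(rownames(matrix)) || anyDuplicated(colnames(matrix)))
    stop_data("receptor/ligand labels must be unique")
  if (any(is.infinite(matrix)))
    stop_data("non-missing BAS entries must be finite")
  structure(matrix, class = c("bas_matrix", "matrix"))
}

#' Rank ligands and receptors by average binding affinity
#'
#' Column (ligand) and row (receptor) means are taken over non-missing
#' entries and ordered strongest binding first (most negative mean first;
#' ties broken by id). Ligands whose docking coverage across receptors falls
#' below `min_coverage` are excluded from the ranking and reported.
#'
#' @param matrix a [bas_matrix()].
#' @param min_coverage minimum fraction of receptors with a non-missing
#'   score for a ligand to be ranked (default 0.8).
#' @return object of class `drug_ranking`: list with `ligands` and
#'   `receptors` data frames (id, mean_bas, coverage, rank), `excluded`
#'   (ligand ids below coverage) and the input `matrix`.
#' @export
rank_bas_matrix <- function(matrix, min_coverage = 0.8) {
  matrix <- bas_matrix(unclass(matrix))
  cover <- colMeans(!is.na(matrix))
  excluded <- colnames(matrix)[cover < min_coverage]
  if (length(excluded) > 0)
    warning("ligand(s) below docking coverage excluded: ",
            paste(excluded, collapse = ", "))
  keep <- setdiff(colnames(matrix), excluded)
  if (length(keep) == 0) stop_data("no ligand meets the coverage floor")
  lmean <- colMeans(matrix[, keep, drop = FALSE], na.rm = TRUE)
  lig <- data.frame(ligand = keep, mean_bas = lmean,
                    coverage = cover[keep], stringsAsFactors = FALSE,
                    row.names = NULL)
  lig <- lig[order(lig$mean_bas, lig$ligand), , drop = FALSE]
  lig$rank <- seq_len(nrow(lig))
  rmean <- rowMeans(matrix, na.rm = TRUE)
  rec <- data.frame(receptor = rownames(matrix), mean_bas = rmean,
                    coverage = rowMeans(!is.na(matrix)),
                    stringsAsFactors = FALSE, row.names = NULL)
  rec <- rec[order(rec$mean_bas, rec$receptor), , drop = FALSE]
  rec$rank <- seq_len(nrow(rec))
  rownames(lig) <- rownames(rec) <- NULL
  structure(list(ligands = lig, receptors = rec, excluded = excluded,
                 matrix = matrix),
            class = "drug_ranking")
}

#' @export
print.drug_ranking <- function(x, ...) {
  cat(sprintf("<drug_ranking: %d ligands x %d receptors%s>\n",
              nrow(x$ligands), nrow(x$receptors),
              if (length(x$excluded))
                sprintf(" (%d ligands excluded)", length(x$excluded)) else ""))
  print(utils::head(x$ligands))
  invisible(x)
}

#' Select candidate drugs from a ranking
#'
#' Keeps ligands whose average score beats `avg_cut` (mean BAS strictly
#' below the cut, kcal/mol) and reports, for each selected ligand, the
#' receptors it does not bind strongly (entries at or above
#' `per_receptor_cut`), so exceptions like a single weakly-bound receptor
#' are visible.
#'
#' @param ranking a [rank_bas_matrix()] result.
#' @param avg_cut ligand-mean threshold, kcal/mol (default -7.7).
#' @param per_receptor_cut strong-binding threshold per entry, kcal/mol
#'   (default -7.0).
#' @return data frame (class `drug_selection`) with columns `ligand`,
#'   `mean_bas`, `rank`, `n_weak`, `weak_receptors` (comma-separated,
#'   missing entries flagged `?`).
#' @export
select_candidate_drugs <- function(ranking, avg_cut = -7.7,
                                   per_receptor_cut = -7.0) {
  stopifnot(inherits(ranking, "drug_ranking"))
  sel <- ranking$ligands[ranking$ligands$mean_bas < avg_cut, , drop = FALSE]
  weak <- vapply(sel$ligand, function(l) {
    col <- ranking$matrix[, l]
    w <- names(col)[!is.na(col) & col >= per_receptor_cut]
    miss <- names(col)[is.na(col)]
    paste(c(w, if (length(miss)) paste0(miss, "?")), collapse = ",")
  }, character(1))
  out <- data.frame(ligand = sel$ligand, mean_bas = sel$mean_bas,
                    rank = sel$rank,
                    n_weak = vapply(strsplit(weak, ","), function(x)
                      sum(nzchar(x)), integer(1)),
                    weak_receptors = weak,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("drug_selection", "data.frame"),
            avg_cut = avg_cut, per_receptor_cut = per_receptor_cut)
}

lipinski_rules <- list(
  MW  = function(d) d$mw > 500,     # molecular weight <= 500 Da
  LogP = function(d) d$logp > 5,    # octanol/water partition <= 5
  HBD = function(d) d$hbd > 5,      # H-bond donors <= 5
  HBA = function(d) d$hba > 10)     # H-bond acceptors <= 10

#' Lipinski rule-of-five violations
#'
#' Counts violations of the canonical bounds: molecular weight <= 500 Da,
#' LogP <= 5, H-bond donors <= 5, H-bond acceptors <= 10.
#'
#' @param descriptors list or one-row data frame with fields `mw`, `logp`,
#'   `hba`, `hbd` (extra fields ignored).
#' @return list with `count` (0-4) and `violated` (rule names).
#' @export
lipinski_violations <- function(descriptors) {
  d <- as.list(descriptors)
  for (f in c("mw", "logp", "hba", "hbd"))
    if (is.null(d[[f]]) || is.na(d[[f]]))
      stop_data("missing descriptor field: ", f)
  hit <- vapply(lipinski_rules, function(rule) isTRUE(rule(d)), logical(1))
  list(count = sum(hit), violated = names(hit)[hit])
}

#' Screen a descriptor table against the rule of five
#'
#' @param descriptors data frame with columns `compound`, `mw`, `logp`,
#'   `hba`, `hbd`.
#' @return data frame with `compound`, `violations`, `violated_rules`,
#'   `rule_of_five_pass` (no violations).
#' @export
lipinski_screen <- function(descriptors) {
  rows <- lapply(seq_len(nrow(descriptors)), function(i)
    lipinski_violations(descriptors[i, , drop = FALSE]))
  data.frame(compound = descriptors$compound,
             violations = vapply(rows, `[[`, integer(1), "count"),
             violated_rules = vapply(rows, function(r)
               paste(r$violated, collapse = ","), character(1)),
             rule_of_five_pass = vapply(rows, function(r) r$count == 0,
                                        logical(1)),
             stringsAsFactors = FALSE)
}

#' ADMET threshold rules
#'
#' Applies the printed decision rules to externally predicted ADMET values:
#' intestinal absorption is "high" iff HIA >= `hia_cut` (% scale, default
#' 30); blood-brain-barrier permeation is "permeant" for LogBB >= 0.3,
#' "poor" for LogBB < -1 and "intermediate" between; the inhibitor/toxicity
#' flags (P-gp, CYP3A4, AMES) are echoed into the verdict. No predictive
#' model is run — predictions are inputs.
#'
#' @param profile list or one-row data frame with at least `hia` and
#'   `logbb`; optional `pgp_inhibitor`, `cyp3a4_inhibitor`, `ames` flags.
#' @param hia_cut HIA threshold in percent (default 30; some literature
#'   uses 50).
#' @return list with `hia_verdict` (`"high"`/`"low"`), `bbb_verdict`
#'   (`"permeant"`/`"intermediate"`/`"poor"`) and the echoed flags.
#' @export
classify_admet <- function(profile, hia_cut = 30) {
  p <- as.list(profile)
  if (is.null(p$hia) || is.na(p$hia)) stop_data("missing field: hia")
  if (p$hia < 0 || p$hia > 100) stop_data("HIA must lie in [0, 100]")
  if (is.null(p$logbb) || is.na(p$logbb)) stop_data("missing field: logbb")
  list(hia_verdict = if (p$hia >= hia_cut) "high" else "low",
       bbb_verdict = if (p$logbb >= 0.3) "permeant"
                     else if (p$logbb < -1) "poor" else "intermediate",
       pgp_inhibitor = p$pgp_inhibitor %||% NA,
       cyp3a4_inhibitor = p$cyp3a4_inhibitor %||% NA,
       ames = p$ames %||% NA)
}

#' Screen an ADMET table with the threshold rules
#'
#' @param profiles data frame with columns `compound`, `hia`, `logbb` and
#'   optional flag columns.
#' @inheritParams classify_admet
#' @return data frame with one verdict row per compound.
#' @export
admet_screen <- function(profiles, hia_cut = 30) {
  rows <- lapply(seq_len(nrow(profiles)), function(i)
    classify_admet(profiles[i, , drop = FALSE], hia_cut = hia_cut))
  data.frame(compound = profiles$compound,
             hia_verdict = vapply(rows, `[[`, character(1), "hia_verdict"),
             bbb_verdict = vapply(rows, `[[`, character(1), "bbb_verdict"),
             pgp_inhibitor = vapply(rows, function(r)
               as.character(r$pgp_inhibitor), character(1)),
             cyp3a4_inhibitor = vapply(rows, function(r)
               as.character(r$cyp3a4_inhibitor), character(1)),
             ames = vapply(rows, function(r) as.character(r$ames),
                           character(1)),
             stringsAsFactors = FALSE)
}
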