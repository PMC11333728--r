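#' Expression study container
#'
#' Bundles one cohort's genes-by-samples intensity matrix with its
#' case/control labels. Intensities must be strictly positive: all modelling
#' is done on the log2 scale and a non-positive value has no log. No silent
#' pseudocount is added; use `pseudocount` explicitly if your platform
#' exports zeros.
#'
#' @param matrix numeric matrix, genes x samples, strictly positive
#'   intensities. Row names are taken as gene identifiers unless `gene_ids`
#'   is given.
#' @param group character/factor of length `ncol(matrix)` with values
#'   `"case"` or `"control"`.
#' @param study_id single string naming the cohort.
#' @param gene_ids optional character vector of unique gene identifiers.
#' @param pseudocount non-negative value added to every intensity before any
#'   log is taken. Default 0 (strict positivity enforced).
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(matrix, group, study_id = "study",
                             gene_ids = NULL, pseudocount = 0) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop_data("expression matrix must be a numeric matrix")
  if (!is.null(gene_ids)) rownames(matrix) <- gene_ids
  if (is.null(rownames(matrix)))
    rownames(matrix) <- sprintf("G%05d", seq_len(nrow(matrix)))
  if (anyDuplicated(rownames(matrix)))
    stop_data("gene identifiers must be unique in study '", study_id, "'")
  group <- as.character(group)
  if (length(group) != ncol(matrix))
    stop_data("group labels (", length(group), ") do not match sample count (",
              ncol(matrix), ") in study '", study_id, "'")
  if (!all(group %in% c("case", "control")))
    stop_data("group labels must be 'case' or 'control'")
  if (pseudocount < 0) stop_config("pseudocount must be non-negative")
  matrix <- matrix + pseudocount
  bad <- which(matrix <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_data("non-positive expression for gene '", rownames(matrix)[bad[1, 1]],
              "', sample '", colnames(matrix)[bad[1, 2]] %||% bad[1, 2],
              "' in study '", study_id, "'")
  }
  structure(
    list(matrix = matrix, group = group, study_id = study_id,
         n1 = sum(group == "case"), n2 = sum(group == "control")),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study '%s': %d genes, %d case / %d control>\n",
              x$study_id, nrow(x$matrix), x$n1, x$n2))
  invisible(x)
}

#' Average log2 fold change (case over control)
#'
#' For unequal group sizes this is the difference between the mean log2 case
#' expression and the mean log2 control expression. For equal group sizes the
#' index-paired mean log-ratio is used; the two forms are algebraically
#' identical when n1 = n2.
#'
#' @param study an [expression_study()].
#' @return named numeric vector of per-gene aLog2FC values (log2 units).
#' @export
alog2fc <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  lm2 <- log2(study$matrix)
  case <- lm2[, study$group == "case", drop = FALSE]
  ctrl <- lm2[, study$group == "control", drop = FALSE]
  if (ncol(case) == ncol(ctrl)) {
    # paired branch: mean_i log2(z^D_i / z^C_i)
    rowMeans(case - ctrl)
  } else {
    rowMeans(case) - rowMeans(ctrl)
  }
}

#' Newton inversion of the trigamma function
#'
#' Solves trigamma(x) = y for x > 0. Used by the moment estimator of the
#' variance-prior degrees of freedom. Tolerance 1e-8, at most 50 iterations;
#' non-convergence returns NA (caller falls back to an infinite prior).
#'
#' @param y positive target value.
#' @return x with trigamma(x) = y, or Inf for y <= 0, or NA on
#'   non-convergence.
#' @export
trigamma_inverse <- function(y) {
  if (!is.finite(y)) return(if (y > 0) 0 else NA_real_)
  if (y <= 0) return(Inf)
  # trigamma(x) ~ 1/x + 1/(2x^2); start from the 1/x asymptote
  x <- 0.5 + 1 / y
  for (i in seq_len(50)) {
    f <- trigamma(x) - y
    step <- f / psigamma(x, deriv = 2L)
    xn <- x - step
    if (xn <= 0) xn <- x / 2
    if (abs(xn - x) < 1e-8 * max(1, x)) return(xn)
    x <- xn
  }
  NA_real_
}

#' Empirical-Bayes moderated t-statistics for a two-group study
#'
#' Fits the hierarchical variance model under which per-gene residual
#' variances s_g^2 (pooled, d_g = n1 + n2 - 2 df) are scaled-inverse-chi^2
#' draws around a prior (d0, s0^2). The prior is estimated by matching the
#' first two moments of log s_g^2: with e_g = log s_g^2 - digamma(d_g/2) +
#' log(d_g/2), E[e] = log s0^2 + digamma(d0/2) - log(d0/2) and Var[e] =
#' trigamma(d_g/2) + trigamma(d0/2); the trigamma equation is inverted by
#' Newton iteration. Posterior variances s~_g^2 = (d0 s0^2 + d_g s_g^2) /
#' (d0 + d_g) shrink each gene toward the prior, and the moderated statistic
#' t_g = aLog2FC_g / (s~_g sqrt(1/n1 + 1/n2)) is referred to a t
#' distribution on d0 + d_g degrees of freedom (normal when d0 is infinite).
#'
#' @param study an [expression_study()] with at least 2 samples per group.
#' @param prior_df optional fixed prior df d0. `0` gives the classical pooled
#'   t-test, `Inf` full shrinkage to s0^2; `NULL` (default) estimates d0 by
#'   the moment method.
#' @return object of class `moderated_fit`: a list with `table` (data frame:
#'   gene_id, alog2fc, t, p) and `prior` (d0, s0_sq, residual df, per-gene
#'   s_sq and posterior s_sq).
#' @export
fit_moderated_t <- function(study, prior_df = NULL) {
  stopifnot(inherits(study, "expression_study"))
  if (study$n1 < 2 || study$n2 < 2)
    stop_data("need >= 2 case and >= 2 control samples in study '",
              study$study_id, "'")
  lm2 <- log2(study$matrix)
  case <- lm2[, study$group == "case", drop = FALSE]
  ctrl <- lm2[, study$group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  dg <- n1 + n2 - 2
  ss_case <- rowSums((case - rowMeans(case))^2)
  ss_ctrl <- rowSums((ctrl - rowMeans(ctrl))^2)
  s2 <- (ss_case + ss_ctrl) / dg
  fc <- alog2fc(study)

  pos <- s2 > 0
  if (!any(pos))
    stop_data("all genes have zero residual variance; cannot estimate the ",
              "variance prior")
  if (is.null(prior_df)) {
    if (sum(pos) < 2) {
      warning("fewer than 2 genes with positive variance; falling back to ",
              "prior_df = 0 (classical t)")
      d0 <- 0
      s0_sq <- mean(s2[pos])
    } else {
      e <- log(s2[pos]) - digamma(dg / 2) + log(dg / 2)
      emean <- mean(e)
      evar <- var(e)
      excess <- evar - trigamma(dg / 2)
      if (excess <= 0) {
        d0 <- Inf
        s0_sq <- exp(emean)
      } else {
        half_d0 <- trigamma_inverse(excess)
        if (is.na(half_d0)) {
          warning("trigamma inversion did not converge; using prior_df = Inf")
          d0 <- Inf
          s0_sq <- exp(emean)
        } else {
          d0 <- 2 * half_d0
          s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
        }
      }
    }
  } else {
    if (prior_df < 0) stop_config("prior_df must be >= 0 (or Inf)")
    d0 <- prior_df
    e <- log(s2[pos]) - digamma(dg / 2) + log(dg / 2)
    s0_sq <- if (is.infinite(d0)) exp(mean(e)) else
      exp(mean(e) + if (d0 > 0) digamma(d0 / 2) - log(d0 / 2) else 0)
    if (d0 == 0) s0_sq <- NA_real_  # unused when there is no shrinkage
  }

  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  tstat <- fc / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- d0 + dg
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(tstat)) else
    2 * pt(-abs(tstat), df = df_total)

  structure(
    list(table = data.frame(gene_id = rownames(study$matrix),
                            alog2fc = fc, t = tstat, p = p,
                            row.names = NULL,
                            stringsAsFactors = FALSE),
         prior = list(d0 = d0, s0_sq = s0_sq, residual_df = dg,
                      s_sq = s2, s_sq_post = s2_post),
         study_id = study$study_id, n1 = n1, n2 = n2),
    class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit '%s': %d genes, %d vs %d samples>\n",
              x$study_id, nrow(x$table), x$n1, x$n2))
  cat(sprintf("  variance prior: d0 = %.4g, s0^2 = %.4g (residual df %d)\n",
              x$prior$d0, x$prior$s0_sq, x$prior$residual_df))
  invisible(x)
}

#' Multiple-testing adjustment
#'
#' Thin wrapper around [stats::p.adjust()] restricted to the methods the
#' pipeline exposes. Input order is preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"bh"` (Benjamini-Hochberg step-up, default),
#'   `"bonferroni"`, or `"none"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_data("p-values must lie in [0, 1]")
  switch(method,
         bh = p.adjust(p, method = "BH"),
         bonferroni = p.adjust(p, method = "bonferroni"),
         none = p)
}

#' Call differentially expressed genes
#'
#' A gene is up-regulated iff its adjusted p-value is below `p_cut` and its
#' aLog2FC exceeds `+fc_cut`; down-regulated iff the adjusted p is below
#' `p_cut` and the aLog2FC is below `-fc_cut`; otherwise uncalled.
#'
#' @param fit a `moderated_fit`, or a data frame with columns `gene_id`,
#'   `alog2fc` and `p` (or `adj_p`).
#' @param p_cut adjusted p-value threshold (default 0.05).
#' @param fc_cut absolute aLog2FC threshold in log2 units (default 1).
#' @param adjust adjustment method passed to [adjust_pvalues()]; ignored if
#'   the input already carries an `adj_p` column.
#' @param study_id cohort label recorded in the result (defaults to the
#'   fit's).
#' @return object of class `deg_table`: data frame with columns `gene_id`,
#'   `alog2fc`, `t` (if available), `p`, `adj_p`, `direction` in
#'   `c("up", "down", "none")`, with the thresholds and up/down counts as
#'   attributes.
#' @export
classify_degs <- function(fit, p_cut = 0.05, fc_cut = 1.0,
                          adjust = c("bh", "bonferroni", "none"),
                          study_id = NULL) {
  adjust <- match.arg(adjust)
  if (inherits(fit, "moderated_fit")) {
    tab <- fit$table
    study_id <- study_id %||% fit$study_id
  } else {
    tab <- as.data.frame(fit)
    study_id <- study_id %||% "study"
  }
  if (!all(c("gene_id", "alog2fc") %in% names(tab)))
    stop_data("need columns gene_id and alog2fc")
  if (anyDuplicated(tab$gene_id))
    stop_data("duplicate gene ids in results for study '", study_id, "'")
  if (!"adj_p" %in% names(tab)) {
    if (!"p" %in% names(tab)) stop_data("need a p or adj_p column")
    tab$adj_p <- adjust_pvalues(tab$p, adjust)
  }
  dir <- rep("none", nrow(tab))
  dir[tab$adj_p < p_cut & tab$alog2fc > fc_cut] <- "up"
  dir[tab$adj_p < p_cut & tab$alog2fc < -fc_cut] <- "down"
  tab$direction <- dir
  structure(tab,
            class = c("deg_table", "data.frame"),
            study_id = study_id,
            p_cut = p_cut, fc_cut = fc_cut, adjust = adjust,
            n_up = sum(dir == "up"), n_down = sum(dir == "down"))
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("<deg_table '%s': %d genes, %d up / %d down (adj p < %g, |aLog2FC| > %g)>\n",
              attr(x, "study_id"), nrow(x), attr(x, "n_up"), attr(x, "n_down"),
              attr(x, "p_cut"), attr(x, "fc_cut")))
  NextMethod()
}

#' One-call differential expression for a study
#'
#' Convenience wrapper: moderated fit then DEG classification.
#'
#' @inheritParams fit_moderated_t
#' @inheritParams classify_degs
#' @return a `deg_table`.
#' @export
run_deg <- function(study, p_cut = 0.05, fc_cut = 1.0,
                    adjust = c("bh", "bonferroni", "none"), prior_df = NULL) {
  classify_degs(fit_moderated_t(study, prior_df = prior_df),
                p_cut = p_cut, fc_cut = fc_cut, adjust = match.arg(adjust))
}
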