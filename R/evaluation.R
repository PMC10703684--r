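# Cross-gene / cross-individual rank-correlation metrics, cross-model
# agreement, and stratification of per-gene performance by eQTL covariates.

#' Spearman rank correlation with explicit undefined handling
#'
#' Pearson correlation of average (midrank) ranks. When either vector is
#' constant the correlation is undefined and `NA` is returned — never a
#' silent zero, since zero-variance predictions are diagnostic.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  # identical or exactly reversed rankings are +-1 by definition; returning
  # them exactly keeps perfect monotone relations at literal 1.0 instead of
  # 1 - epsilon from the product-moment arithmetic
  if (identical(rx, ry)) return(1)
  if (isTRUE(all(rx + ry == length(rx) + 1))) return(-1)
  stats::cor(rx, ry)
}

#' Per-gene cross-individual correlation
#'
#' For each gene, the Spearman correlation between its predicted and
#' observed expression across individuals — the metric that asks whether a
#' model explains expression variation between people.
#'
#' @param pred,obs Genes x individuals matrices with identical dimnames.
#' @return Named per-gene vector of correlations (`NA` where undefined).
#' @export
cross_individual <- function(pred, obs) {
  check_matched(pred, obs)
  vapply(rownames(pred), function(g) spearman_rho(pred[g, ], obs[g, ]),
         numeric(1))
}

#' Per-individual cross-gene correlation
#'
#' For each individual, the Spearman correlation between predicted and
#' observed expression across genes — the metric dominated by reference
#' sequence differences between genes.
#'
#' @inheritParams cross_individual
#' @return Named per-individual vector of correlations.
#' @export
cross_gene <- function(pred, obs) {
  check_matched(pred, obs)
  vapply(colnames(pred), function(i) spearman_rho(pred[, i], obs[, i]),
         numeric(1))
}

#' Reference-sequence correlation across genes
#'
#' Spearman correlation between per-gene reference-sequence predictions and
#' the per-gene median observed expression.
#'
#' @param ref_pred Named per-gene vector of reference predictions.
#' @param obs Genes x individuals observed expression matrix.
#' @return Single correlation.
#' @export
reference_correlation <- function(ref_pred, obs) {
  if (!setequal(names(ref_pred), rownames(obs)))
    stop("gene sets differ between reference predictions and expression")
  med <- apply(obs, 1, stats::median)
  spearman_rho(ref_pred[rownames(obs)], med)
}

check_matched <- function(pred, obs) {
  if (!identical(dimnames(pred), dimnames(obs)))
    stop("prediction and observation matrices have mismatched indices")
}

#' Summarize an evaluation run
#'
#' Computes the three performance views (reference, cross-gene,
#' cross-individual) plus means and sample (n-1) standard deviations over
#' the defined entries of each distribution. Undefined correlations are
#' counted and excluded, never imputed.
#'
#' @param pred Genes x individuals prediction matrix.
#' @param obs Matched observed expression matrix.
#' @param ref_pred Optional named per-gene reference predictions.
#' @return An object of class `EvalResult`: list with `cross_individual`,
#'   `cross_gene`, `reference_corr`, and `summary` (a data.frame of n,
#'   n_undefined, mean, sd per metric).
#' @export
evaluate_predictions <- function(pred, obs, ref_pred = NULL) {
  ci <- cross_individual(pred, obs)
  cg <- cross_gene(pred, obs)
  rc <- if (!is.null(ref_pred)) reference_correlation(ref_pred, obs) else NA_real_
  summ <- function(v) {
    d <- v[!is.na(v)]
    data.frame(n = length(d), n_undefined = sum(is.na(v)),
               mean = if (length(d)) mean(d) else NA_real_,
               sd = if (length(d) > 1) stats::sd(d) else NA_real_)
  }
  summary <- rbind(cross_individual = summ(ci), cross_gene = summ(cg))
  structure(list(cross_individual = ci, cross_gene = cg,
                 reference_corr = rc, summary = summary),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat("Evaluation result\n")
  if (!is.na(x$reference_corr))
    cat(sprintf("  reference correlation (across genes): %.3f\n",
                x$reference_corr))
  s <- x$summary
  for (m in rownames(s))
    cat(sprintf("  %s: mean rho %.3f (sd %.3f, n=%d, undefined=%d)\n",
                m, s[m, "mean"], s[m, "sd"], s[m, "n"], s[m, "n_undefined"]))
  invisible(x)
}

#' Cross-model agreement in direction and magnitude
#'
#' Pearson correlation of two models' per-gene cross-individual
#' correlations (signed agreement) and of their absolute values (magnitude
#' agreement). Undefined entries are dropped pairwise. Models that identify
#' the same regulatory variation but disagree on its direction show high
#' magnitude agreement with low signed agreement.
#'
#' @param rho_a,rho_b Named per-gene correlation vectors on the same genes.
#' @return List with `signed_r`, `magnitude_r`, and `n_used`.
#' @export
model_agreement <- function(rho_a, rho_b) {
  if (!setequal(names(rho_a), names(rho_b)))
    stop("gene sets differ")
  rho_b <- rho_b[names(rho_a)]
  ok <- !is.na(rho_a) & !is.na(rho_b)
  if (sum(ok) < 3) stop("fewer than 3 shared defined genes")
  list(signed_r = stats::cor(rho_a[ok], rho_b[ok]),
       magnitude_r = stats::cor(abs(rho_a[ok]), abs(rho_b[ok])),
       n_used = sum(ok))
}

#' Stratify per-gene performance by eQTL and expression covariates
#'
#' Assembles, per gene: the cross-individual correlation, `-log10` of the
#' top eQTL p-value, the absolute eQTL distance to the TSS, the median
#' observed expression, and the coefficient of variation (sd/mean) of the
#' predicted expression across individuals. For each covariate, a Pearson
#' correlation and an ordinary-least-squares fit (slope, intercept) against
#' the cross-individual correlation are computed on all genes and on the
#' positive- and negative-correlation subsets.
#'
#' @param rho Named per-gene cross-individual correlations.
#' @param eqtl data.frame with one record per gene: columns `gene_id`,
#'   `pvalue`, `distance_to_tss` (signed bp). Typically the most significant
#'   eQTL within a distance cutoff of the TSS, ties broken by smaller
#'   `|distance_to_tss|` then lexicographic variant id.
#' @param obs,pred Matched genes x individuals matrices.
#' @return An object of class `StratificationTable`: list with `per_gene`
#'   (covariate data.frame) and `fits` (one row per covariate x subset with
#'   `pearson_r`, `slope`, `intercept`, `n`).
#' @export
stratify <- function(rho, eqtl, obs, pred) {
  check_matched(pred, obs)
  genes <- intersect(names(rho), eqtl$gene_id)
  n_excluded <- length(rho) - length(genes)
  if (n_excluded > 0)
    message(n_excluded, " gene(s) without an eQTL record excluded")
  e <- eqtl[match(genes, eqtl$gene_id), ]
  mu <- rowMeans(pred[genes, , drop = FALSE])
  sdv <- apply(pred[genes, , drop = FALSE], 1, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, sdv / mu)
  if (any(mu == 0))
    message(sum(mu == 0), " gene(s) with zero-mean predictions flagged (CV undefined)")
  per_gene <- data.frame(
    gene_id = genes,
    rho = rho[genes],
    neglog10_p = -log10(e$pvalue),
    abs_tss_distance = abs(e$distance_to_tss),
    median_expression = apply(obs[genes, , drop = FALSE], 1, stats::median),
    prediction_cv = cv,
    stringsAsFactors = FALSE)
  covs <- c("neglog10_p", "abs_tss_distance", "median_expression",
            "prediction_cv")
  subsets <- list(all = rep(TRUE, length(genes)),
                  positive = per_gene$rho > 0,
                  negative = per_gene$rho < 0)
  fits <- do.call(rbind, lapply(covs, function(cc) {
    do.call(rbind, lapply(names(subsets), function(ss) {
      keep <- subsets[[ss]] & !is.na(per_gene$rho) & !is.na(per_gene[[cc]])
      if (sum(keep) < 3)
        return(data.frame(covariate = cc, subset = ss, pearson_r = NA_real_,
                          slope = NA_real_, intercept = NA_real_,
                          n = sum(keep)))
      x <- per_gene[[cc]][keep]; y <- per_gene$rho[keep]
      ft <- stats::lm.fit(cbind(1, x), y)
      data.frame(covariate = cc, subset = ss,
                 pearson_r = if (stats::sd(x) == 0 || stats::sd(y) == 0)
                   NA_real_ else stats::cor(x, y),
                 slope = ft$coefficients[2], intercept = ft$coefficients[1],
                 n = sum(keep))
    }))
  }))
  rownames(fits) <- NULL
  structure(list(per_gene = per_gene, fits = fits, n_excluded = n_excluded),
            class = "StratificationTable")
}

#' @export
print.StratificationTable <- function(x, ...) {
  cat(sprintf("StratificationTable: %d gene(s), %d excluded\n",
              nrow(x$per_gene), x$n_excluded))
  print(x$fits)
  invisible(x)
}
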