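# Per-gene elastic-net baseline predicting expression from cis
# common-variant dosages, with nested cross-validation so every individual
# receives an out-of-fold prediction from a model that never saw them.
# This is not a competing sequence model: it bounds from below the genetic
# signal a predictor could extract for each gene.

#' Nested cross-validation scheme for the elastic-net baseline
#'
#' @param n_outer_folds Outer folds producing held-out predictions.
#' @param n_inner_folds Inner folds selecting the penalty within each outer
#'   training set.
#' @param mixing Elastic-net mixing parameter alpha; 0.5 mixes the L1 and
#'   L2 penalties equally (penalty `lambda * (0.5*||b||_1 + 0.25*||b||_2^2)`
#'   under the usual alpha-parameterization).
#' @param n_lambda Number of penalty grid points.
#' @param lambda_min_ratio Smallest grid penalty as a fraction of
#'   `lambda_max` (the smallest penalty zeroing all coefficients, computed
#'   per outer training set).
#' @param lambda Optional explicit penalty grid overriding the computed one.
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `CvScheme`.
#' @export
cv_scheme <- function(n_outer_folds = 10, n_inner_folds = 10, mixing = 0.5,
                      n_lambda = 50, lambda_min_ratio = 1e-4,
                      lambda = NULL, seed = 1) {
  stopifnot(n_outer_folds >= 2, n_inner_folds >= 2,
            mixing >= 0, mixing <= 1, n_lambda >= 2)
  structure(list(n_outer_folds = as.integer(n_outer_folds),
                 n_inner_folds = as.integer(n_inner_folds),
                 mixing = mixing, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio, lambda = lambda,
                 seed = as.integer(seed)),
            class = "CvScheme")
}

#' Build a cis dosage matrix for one gene
#'
#' Retains cohort variants on the gene's chromosome with
#' `|pos0 - tss0| <= window_bp` and cohort minor allele frequency
#' `>= maf_min` (computed from the analysis cohort's allele counts), with
#' alt-allele dosages summed over the two haplotypes.
#'
#' @param cohort A `PhasedCohort`.
#' @param gene Single-row gene annotation.
#' @param window_bp Distance cutoff from the TSS in bp (98300 matches the
#'   widest receptive field among the models evaluated).
#' @param maf_min Minor-allele-frequency cutoff (common variants only).
#' @return An object of class `DosageMatrix`: list with `dosages`
#'   (individuals x variants) and `variants` (metadata: id, pos, maf,
#'   signed distance to TSS). Zero qualifying variants yields an
#'   empty-matrix marker (0 columns).
#' @export
build_dosage_matrix <- function(cohort, gene, window_bp = 98300,
                                maf_min = 0.05) {
  stopifnot(inherits(cohort, "PhasedCohort"))
  tss0 <- gene$tss - 1L
  v <- cohort$variants
  pos0 <- v$pos - 1L
  d <- cohort$hap0 + cohort$hap1
  af <- rowMeans(d) / 2
  maf <- pmin(af, 1 - af)
  keep <- v$chrom == gene$chrom & abs(pos0 - tss0) <= window_bp &
    maf >= maf_min
  dm <- t(d[keep, , drop = FALSE])
  dimnames(dm) <- list(cohort$individuals, v$variant_id[keep])
  structure(list(
    dosages = dm,
    variants = data.frame(variant_id = v$variant_id[keep],
                          pos = v$pos[keep], maf = maf[keep],
                          distance_to_tss = pos0[keep] - tss0,
                          stringsAsFactors = FALSE)),
    class = "DosageMatrix")
}

# Penalty grid: n_lambda values log-spaced down from lambda_max, the
# smallest penalty at which every coefficient is zero for this training set.
lambda_grid <- function(X, y, scheme) {
  n <- nrow(X)
  xs <- scale(X)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  yc <- y - mean(y)
  alpha <- max(scheme$mixing, 1e-3)
  lam_max <- max(abs(crossprod(xs, yc))) / (n * alpha)
  if (!is.finite(lam_max) || lam_max <= 0) lam_max <- 1
  exp(seq(log(lam_max), log(lam_max * scheme$lambda_min_ratio),
          length.out = scheme$n_lambda))
}

# glmnet needs >= 2 columns; pad single-variant genes with an all-zero
# dummy column that can never take weight.
pad_x <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, `.dummy` = 0)
}

#' Out-of-fold elastic-net predictions for one gene
#'
#' Nested cross-validation: individuals are split into `n_outer_folds`
#' (seeded); within each outer training set an inner `n_inner_folds` CV
#' selects the penalty minimizing mean squared error on the grid at the
#' configured mixing parameter; the model is refit on the full outer
#' training set at that penalty and predictions are emitted for the held-out
#' fold only. Concatenated predictions cover every individual exactly once,
#' and no fitting step ever sees a held-out individual's expression.
#' Dosage columns are standardized using training-fold statistics only
#' (glmnet internal standardization).
#'
#' @param X A [build_dosage_matrix()] result (or bare individuals x
#'   variants matrix).
#' @param y Expression vector, one value per individual.
#' @param scheme A [cv_scheme()].
#' @return List with `predictions` (out-of-fold, in input order), `fold`
#'   (outer fold per individual), `lambda` (chosen penalty per fold),
#'   `nonzero` (variant ids with nonzero coefficients in any fold), and
#'   `constant_y` flag.
#' @export
fit_out_of_fold <- function(X, y, scheme = cv_scheme()) {
  if (inherits(X, "DosageMatrix")) X <- X$dosages
  stopifnot(is.matrix(X), nrow(X) == length(y), ncol(X) >= 1)
  if (nrow(X) < 30) stop("need at least 30 individuals")
  if (any(!is.finite(y)) || any(!is.finite(X))) stop("non-finite values")
  n <- nrow(X)
  set.seed(scheme$seed)
  fold <- sample(rep(seq_len(scheme$n_outer_folds), length.out = n))
  preds <- rep(NA_real_, n)
  lambdas <- rep(NA_real_, scheme$n_outer_folds)
  nonzero <- character(0)
  constant_y <- stats::sd(y) == 0
  for (k in seq_len(scheme$n_outer_folds)) {
    tr <- fold != k
    Xtr <- pad_x(X[tr, , drop = FALSE])
    ytr <- y[tr]
    if (stats::sd(ytr) == 0 || all(apply(Xtr, 2, stats::sd) == 0)) {
      preds[!tr] <- mean(ytr)
      next
    }
    grid <- if (!is.null(scheme$lambda)) sort(scheme$lambda, decreasing = TRUE)
            else lambda_grid(Xtr, ytr, scheme)
    set.seed(derive_seed(scheme$seed, paste0("inner-fold-", k)))
    inner_id <- sample(rep(seq_len(scheme$n_inner_folds),
                           length.out = sum(tr)))
    cvfit <- glmnet::cv.glmnet(Xtr, ytr, alpha = scheme$mixing,
                               lambda = grid, foldid = inner_id,
                               standardize = TRUE, thresh = 1e-12)
    lam <- cvfit$lambda.min
    lambdas[k] <- lam
    cf <- as.matrix(stats::coef(cvfit$glmnet.fit, s = lam))
    nz <- rownames(cf)[-1][cf[-1, 1] != 0]
    nonzero <- union(nonzero, setdiff(nz, ".dummy"))
    preds[!tr] <- as.numeric(stats::predict(
      cvfit$glmnet.fit, newx = pad_x(X[!tr, , drop = FALSE]), s = lam))
  }
  list(predictions = preds, fold = fold, lambda = lambdas,
       nonzero = nonzero, constant_y = constant_y)
}

#' Cross-individual baseline performance for a gene set
#'
#' Fits the out-of-fold elastic net per gene and reports the Spearman
#' correlation between out-of-fold predictions and observed expression
#' across individuals. Genes with no qualifying cis variant are skipped and
#' carry `NA`.
#'
#' @param cohort `PhasedCohort`.
#' @param genes `GeneAnnotation` table.
#' @param expression Genes x individuals `ExpressionMatrix` with columns in
#'   cohort order.
#' @param scheme [cv_scheme()].
#' @param window_bp,maf_min Passed to [build_dosage_matrix()].
#' @return List with `rho` (named per-gene vector), `predictions` (genes x
#'   individuals out-of-fold matrix), and `n_skipped`.
#' @export
baseline_eval <- function(cohort, genes, expression, scheme = cv_scheme(),
                          window_bp = 98300, maf_min = 0.05) {
  stopifnot(identical(colnames(expression), cohort$individuals))
  ids <- genes$gene_id
  rho <- stats::setNames(rep(NA_real_, length(ids)), ids)
  pmat <- matrix(NA_real_, nrow = length(ids), ncol = length(cohort$individuals),
                 dimnames = list(ids, cohort$individuals))
  n_skipped <- 0L
  for (g in seq_along(ids)) {
    dm <- build_dosage_matrix(cohort, genes[g, ], window_bp, maf_min)
    if (ncol(dm$dosages) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    y <- expression[ids[g], ]
    fit <- fit_out_of_fold(dm, y, scheme)
    pmat[ids[g], ] <- fit$predictions
    rho[ids[g]] <- if (stats::sd(fit$predictions) == 0) NA_real_
                   else spearman_rho(fit$predictions, y)
  }
  if (n_skipped > 0)
    message(n_skipped, " gene(s) with no qualifying cis variant skipped")
  list(rho = rho, predictions = pmat, n_skipped = n_skipped)
}
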