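# Direction-of-effect classification for fine-mapped QTL variants from
# predictor ref/alt deltas, with bootstrap accuracy.

#' Filter a fine-mapped QTL table
#'
#' Keeps records with posterior inclusion probability strictly greater than
#' `pip_min`, then drops every variant whose retained records carry both
#' positive and negative signed effects across different target genes
#' (such variants have no single expected direction).
#'
#' @param records data.frame with columns `variant_id`, `gene_id`, `beta`
#'   (signed effect, nonzero), `pip`.
#' @param pip_min PIP threshold (records must exceed it).
#' @return Filtered data.frame; may be empty (with a warning).
#' @export
filter_fine_mapped <- function(records, pip_min = 0.9) {
  stopifnot(all(c("variant_id", "gene_id", "beta", "pip") %in% names(records)))
  if (any(records$beta == 0)) stop("signed effects must be nonzero")
  keep <- records[records$pip > pip_min, , drop = FALSE]
  if (nrow(keep) > 0) {
    sgn <- split(sign(keep$beta), keep$variant_id)
    conflicted <- names(sgn)[vapply(sgn, function(s) length(unique(s)) > 1,
                                    logical(1))]
    keep <- keep[!keep$variant_id %in% conflicted, , drop = FALSE]
  }
  if (nrow(keep) == 0)
    warning("no records pass the fine-mapping filters")
  rownames(keep) <- NULL
  keep
}

#' Predicted effect of a single variant substitution
#'
#' Difference between the predictor's output on the alternate and reference
#' sequence, both on the reference background with only this variant
#' toggled (an in-silico substitution, not a personal genome).
#'
#' In `"eqtl"` mode the window is anchored at the gene TSS and both
#' sequences are reduced with the gene-level TSS-window aggregation config.
#' In `"caqtl"` mode the window is anchored at the variant position and the
#' delta is the sum, over the 3 bins whose centers lie nearest the variant
#' (ties to the smaller bin index), of the alt-ref track difference.
#'
#' @param pred A [predictor()] (track type required for caqtl mode).
#' @param genome `ReferenceGenome`.
#' @param variant One-row data.frame or list with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param cfg [aggregation_config()] (eqtl mode).
#' @param mode `"eqtl"` or `"caqtl"`.
#' @param gene Gene annotation row (eqtl mode).
#' @param spec [window_spec()] defining the window extent.
#' @param n_bins Number of nearest bins summed in caqtl mode.
#' @return Single numeric delta (alt minus ref).
#' @export
variant_delta <- function(pred, genome, variant, cfg, mode = c("eqtl", "caqtl"),
                          gene = NULL, spec, n_bins = 3) {
  mode <- match.arg(mode)
  pos0 <- as.integer(variant$pos) - 1L
  if (mode == "eqtl") {
    stopifnot(!is.null(gene))
    itv <- resolve_window(gene, spec, genome)
  } else {
    itv <- list(chrom = as.character(variant$chrom),
                start = pos0 - spec$upstream_bp,
                end = pos0 + spec$downstream_bp)
    len <- nchar(get_contig(genome, itv$chrom))
    if (itv$start < 0 || itv$end > len)
      stop("caQTL window exceeds contig bounds for variant at ",
           variant$chrom, ":", variant$pos)
  }
  if (variant$chrom != itv$chrom || pos0 < itv$start || pos0 >= itv$end)
    stop(sprintf("variant %s:%d outside the predictor window",
                 variant$chrom, variant$pos))
  refwin <- substr(get_contig(genome, itv$chrom), itv$start + 1L, itv$end)
  off <- pos0 - itv$start + 1L
  if (substr(refwin, off, off) != variant$ref)
    stop(sprintf("variant REF %s disagrees with genome base %s at %s:%d",
                 variant$ref, substr(refwin, off, off),
                 variant$chrom, variant$pos))
  altwin <- refwin
  substr(altwin, off, off) <- as.character(variant$alt)

  if (mode == "eqtl") {
    rc <- spec$strand_aware && gene$strand == "-"
    if (rc) {
      refwin <- reverse_complement(refwin)
      altwin <- reverse_complement(altwin)
    }
    toff <- tss_offset(spec)
    predict_gene(pred, altwin, toff, cfg) - predict_gene(pred, refwin, toff, cfg)
  } else {
    if (pred$type != "track") stop("caqtl mode needs a track predictor")
    tr_ref <- pred$fn(refwin)
    tr_alt <- pred$fn(altwin)
    bs <- tr_ref$bin_size_bp
    n <- length(tr_ref$values)
    centers <- (seq_len(n) - 1L) * bs + (bs - 1) / 2
    voff <- pos0 - itv$start
    ord <- order(abs(centers - voff), seq_len(n))
    pick <- ord[seq_len(min(n_bins, n))]
    sum(tr_alt$values[pick]) - sum(tr_ref$values[pick])
  }
}

#' Direction-of-effect accuracy
#'
#' A variant's direction is called correctly when the sign of the predicted
#' delta matches the sign of its measured effect. Zero deltas have no sign:
#' they are excluded from the accuracy and reported separately.
#'
#' @param deltas Numeric vector of predicted alt-ref deltas.
#' @param effects Matched numeric vector of signed measured effects.
#' @return An object of class `DirectionResult` with `n_evaluated`,
#'   `n_correct`, `n_zero_delta`, `accuracy`.
#' @export
direction_accuracy <- function(deltas, effects) {
  stopifnot(length(deltas) == length(effects))
  if (any(effects == 0)) stop("signed effects must be nonzero")
  ok <- deltas != 0
  if (!any(ok)) stop("no evaluable records (all deltas are zero)")
  correct <- sign(deltas[ok]) == sign(effects[ok])
  structure(list(n_evaluated = sum(ok), n_correct = sum(correct),
                 n_zero_delta = sum(!ok),
                 accuracy = mean(correct)),
            class = "DirectionResult")
}

#' Bootstrap direction-of-effect accuracy
#'
#' Accuracy over `B` bootstrap resamples (with replacement) of the
#' evaluable record set, reported as mean, sample s.d., and 2.5/97.5
#' percentile interval. Fully reproducible under `seed`; the global RNG
#' state is left untouched.
#'
#' @inheritParams direction_accuracy
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return A `DirectionResult` with the point estimate plus a `bootstrap`
#'   list (`B`, `mean`, `sd`, `ci_lower`, `ci_upper`, `seed`).
#' @export
bootstrap_accuracy <- function(deltas, effects, B = 100, seed = 1) {
  res <- direction_accuracy(deltas, effects)
  ok <- deltas != 0
  d <- deltas[ok]; e <- effects[ok]
  n <- length(d)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  acc <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    mean(sign(d[idx]) == sign(e[idx]))
  }, numeric(1))
  res$bootstrap <- list(B = B, mean = mean(acc), sd = stats::sd(acc),
                        ci_lower = unname(stats::quantile(acc, 0.025)),
                        ci_upper = unname(stats::quantile(acc, 0.975)),
                        seed = seed)
  res
}

#' @export
print.DirectionResult <- function(x, ...) {
  cat(sprintf("Direction accuracy: %.3f (%d/%d correct, %d zero-delta excluded)\n",
              x$accuracy, x$n_correct, x$n_evaluated, x$n_zero_delta))
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap (B=%d): mean %.3f, sd %.4f, 95%% CI [%.3f, %.3f]\n",
                x$bootstrap$B, x$bootstrap$mean, x$bootstrap$sd,
                x$bootstrap$ci_lower, x$bootstrap$ci_upper))
  invisible(x)
}
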