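# Predictor contract and prediction-aggregation rules: forward/RC averaging,
# small sequence shifts, binned-track TSS-window aggregation, haplotype
# averaging, and cross-model ensembling. Also the synthetic sequence-level
# oracle predictors used in place of trained deep models.

#' Construct a predictor
#'
#' A predictor is a deterministic function of an input sequence. Track
#' predictors emit a [binned_track()] of `floor(nchar(seq) / bin_size_bp)`
#' bins (the convention of CAGE-style models predicting in fixed-width
#' bins); scalar predictors emit a single real value.
#'
#' @param name Display name.
#' @param fn Function of one sequence string returning a `BinnedTrack`
#'   (track type) or a single numeric (scalar type).
#' @param type `"track"` or `"scalar"`.
#' @param bin_size_bp Bin width in bp; required for track predictors.
#' @return An object of class `Predictor`.
#' @export
predictor <- function(name, fn, type = c("scalar", "track"),
                      bin_size_bp = NULL) {
  type <- match.arg(type)
  stopifnot(is.function(fn))
  if (type == "track") {
    stopifnot(!is.null(bin_size_bp), bin_size_bp >= 1)
    bin_size_bp <- as.integer(bin_size_bp)
  }
  structure(list(name = name, fn = fn, type = type,
                 bin_size_bp = bin_size_bp),
            class = "Predictor")
}

#' Construct a binned prediction track
#'
#' @param values Finite numeric vector, one value per bin.
#' @param bin_size_bp Bin width in bp.
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(values, bin_size_bp) {
  stopifnot(is.numeric(values), length(values) >= 1, all(is.finite(values)),
            bin_size_bp >= 1)
  structure(list(values = as.numeric(values),
                 bin_size_bp = as.integer(bin_size_bp)),
            class = "BinnedTrack")
}

#' Aggregation configuration for gene-level predictions
#'
#' @param rc_average Average predictions over the forward and
#'   reverse-complement sequence.
#' @param shift_bp Also average over sequences shifted by 1..`shift_bp`
#'   nucleotides in each direction (0 disables shifting).
#' @param tss_window_bins Number of track bins reduced around the TSS bin
#'   (10 is the convention used for CAGE-track expression readout).
#' @param window_reduce `"mean"` or `"sum"`.
#' @param haplotype_average Average the two haplotype predictions per
#'   individual (fixed `TRUE` in the pipeline).
#' @return An object of class `AggregationConfig`.
#' @export
aggregation_config <- function(rc_average = FALSE, shift_bp = 0,
                               tss_window_bins = 10,
                               window_reduce = c("mean", "sum"),
                               haplotype_average = TRUE) {
  window_reduce <- match.arg(window_reduce)
  shift_bp <- as.integer(shift_bp)
  tss_window_bins <- as.integer(tss_window_bins)
  stopifnot(shift_bp >= 0, tss_window_bins >= 1,
            is.logical(rc_average), is.logical(haplotype_average))
  structure(list(rc_average = rc_average, shift_bp = shift_bp,
                 tss_window_bins = tss_window_bins,
                 window_reduce = window_reduce,
                 haplotype_average = haplotype_average),
            class = "AggregationConfig")
}

#' Reduce a prediction track over a window of bins around the TSS
#'
#' With `W = tss_window_bins` and TSS bin `t = floor(tss_offset_bp /
#' bin_size_bp)` (0-based), the reduced window is the W bins
#' `t - floor((W-1)/2) .. t + ceiling((W-1)/2)` inclusive — centered on the
#' TSS bin with the extra bin downstream when W is even, so W = 10 reduces
#' bins `t-4 .. t+5`. A window extending past either end of the track is an
#' error.
#'
#' @param track A [binned_track()].
#' @param tss_offset_bp 0-based offset of the TSS base within the sequence
#'   the track was predicted from.
#' @param cfg An [aggregation_config()].
#' @return Single numeric: mean or sum of the window bins per
#'   `cfg$window_reduce`.
#' @export
aggregate_tss_window <- function(track, tss_offset_bp, cfg) {
  stopifnot(inherits(track, "BinnedTrack"), inherits(cfg, "AggregationConfig"))
  W <- cfg$tss_window_bins
  t <- floor(tss_offset_bp / track$bin_size_bp)
  lo <- t - floor((W - 1) / 2)
  hi <- t + ceiling((W - 1) / 2)
  n <- length(track$values)
  if (t < 0 || t >= n)
    stop(sprintf("TSS bin %d outside track of %d bins", t, n))
  if (lo < 0 || hi >= n)
    stop(sprintf("TSS window bins [%d, %d] exceed track bounds [0, %d]",
                 lo, hi, n - 1))
  vals <- track$values[(lo + 1L):(hi + 1L)]
  if (cfg$window_reduce == "mean") mean(vals) else sum(vals)
}

# Shift a sequence's content by k bases (k > 0 shifts content toward the
# 3' end, vacating the 5' edge). Vacated bases are filled from the matching
# reference flank when available, else with N.
shift_sequence <- function(seq, k, flank5 = "", flank3 = "") {
  L <- nchar(seq)
  a <- abs(k)
  if (a == 0) return(seq)
  if (a >= L) stop("shift larger than sequence")
  if (k > 0) {
    pad <- if (nchar(flank5) >= a)
      substr(flank5, nchar(flank5) - a + 1L, nchar(flank5))
    else strrep("N", a)
    paste0(pad, substr(seq, 1L, L - a))
  } else {
    pad <- if (nchar(flank3) >= a) substr(flank3, 1L, a) else strrep("N", a)
    paste0(substr(seq, a + 1L, L), pad)
  }
}

# Enumerate the (sequence, tss_offset) variants requested by cfg for one
# input sequence: identity, +-1..shift_bp shifts (TSS offset moves with the
# content so the biological anchor is preserved), and, when rc_average, the
# reverse complement of each with the mirrored offset L - 1 - offset.
sequence_variants <- function(seq, tss_offset_bp, cfg, flank5 = "",
                              flank3 = "") {
  L <- nchar(seq)
  shifts <- if (cfg$shift_bp > 0) (-cfg$shift_bp):cfg$shift_bp else 0L
  out <- lapply(shifts, function(k) {
    list(seq = shift_sequence(seq, k, flank5, flank3),
         offset = tss_offset_bp + k)
  })
  if (cfg$rc_average) {
    out <- c(out, lapply(out, function(v) {
      list(seq = reverse_complement(v$seq), offset = L - 1L - v$offset)
    }))
  }
  out
}

#' Predict an individual's expression for one gene
#'
#' Runs the predictor over every sequence variant requested by the
#' aggregation config (identity, shifts, reverse complement) for each
#' haplotype sequence, reduces track output over the TSS bin window, and
#' averages: first over sequence variants within a haplotype, then over
#' haplotypes. Scalar predictors skip the track reduction and are averaged
#' the same way.
#'
#' @param pred A [predictor()].
#' @param sequences Character vector of 1 or 2 equal-length haplotype
#'   sequences for one (gene, individual).
#' @param tss_offset_bp 0-based TSS offset within the sequences.
#' @param cfg An [aggregation_config()].
#' @param flank5,flank3 Optional reference flanking sequence used to pad
#'   shifted sequences; N-padding is used when absent.
#' @return Single numeric prediction.
#' @export
predict_gene <- function(pred, sequences, tss_offset_bp, cfg,
                         flank5 = "", flank3 = "") {
  stopifnot(inherits(pred, "Predictor"), inherits(cfg, "AggregationConfig"),
            length(sequences) %in% c(1L, 2L))
  if (length(unique(nchar(sequences))) != 1L)
    stop("haplotype sequences differ in length")
  hap_vals <- vapply(sequences, function(s) {
    vars <- sequence_variants(s, tss_offset_bp, cfg, flank5, flank3)
    mean(vapply(vars, function(v) {
      if (pred$type == "track") {
        aggregate_tss_window(pred$fn(v$seq), v$offset, cfg)
      } else {
        as.numeric(pred$fn(v$seq))
      }
    }, numeric(1)))
  }, numeric(1))
  mean(hap_vals)
}

#' Synthetic oracle weights for one gene
#'
#' An additive sequence-level scoring rule standing in for a trained
#' sequence-to-expression model, parameterized directly by the simulation's
#' causal truth: each stored window offset contributes `contribution` to the
#' score when the sequence carries the stored (alt) base there, with the
#' contribution sign-flipped at corrupted positions, plus a deterministic
#' per-sequence noise term.
#'
#' @param window_length Expected sequence length.
#' @param offsets 0-based offsets within the window.
#' @param bases Base whose presence at each offset triggers the
#'   contribution (the alt allele in window orientation).
#' @param contributions Signed numeric contributions.
#' @param baseline Score of a sequence carrying none of the stored bases.
#' @param corrupted Logical vector: sign-flip the contribution at these
#'   positions (fixed at construction).
#' @param noise_sd Standard deviation of the deterministic per-sequence
#'   noise (a seeded hash of the sequence, so the predictor stays a pure
#'   function).
#' @return An object of class `OracleWeights`.
#' @export
oracle_weights <- function(window_length, offsets = integer(0),
                           bases = character(0), contributions = numeric(0),
                           baseline = 0, corrupted = NULL, noise_sd = 0) {
  n <- length(offsets)
  stopifnot(length(bases) == n, length(contributions) == n, noise_sd >= 0)
  if (is.null(corrupted)) corrupted <- rep(FALSE, n)
  stopifnot(length(corrupted) == n)
  offsets <- as.integer(offsets)
  if (n > 0 && (min(offsets) < 0 || max(offsets) >= window_length))
    stop("oracle weight offset outside window")
  structure(list(window_length = as.integer(window_length),
                 offsets = offsets, bases = as.character(bases),
                 contributions = as.numeric(contributions),
                 baseline = as.numeric(baseline),
                 corrupted = as.logical(corrupted),
                 noise_sd = as.numeric(noise_sd)),
            class = "OracleWeights")
}

# Deterministic 31-bit hash of a sequence string.
seq_hash <- function(seq) {
  v <- utf8ToInt(seq)
  m <- rep_len(c(3, 7, 11, 19, 29, 37, 53, 87), length(v))
  as.integer(sum((v * m * seq_along(v)) %% 268435399) %% 2147483629)
}

# Deterministic standard-normal draw keyed by the sequence; leaves the
# global RNG state untouched.
hash_noise <- function(seq, sd) {
  if (sd <= 0) return(0)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seq_hash(seq))
  stats::rnorm(1) * sd
}

#' Score a sequence under synthetic oracle weights
#'
#' @param seq Sequence of length `weights$window_length`.
#' @param weights An [oracle_weights()] object.
#' @return `baseline + sum of matched (sign-adjusted) contributions + noise`;
#'   a pure function of the sequence.
#' @export
oracle_score <- function(seq, weights) {
  stopifnot(inherits(weights, "OracleWeights"))
  if (nchar(seq) != weights$window_length)
    stop(sprintf("sequence length %d != oracle window length %d",
                 nchar(seq), weights$window_length))
  total <- weights$baseline
  if (length(weights$offsets) > 0) {
    at <- substring(seq, weights$offsets + 1L, weights$offsets + 1L)
    sgn <- ifelse(weights$corrupted, -1, 1)
    total <- total + sum((at == weights$bases) * sgn * weights$contributions)
  }
  total + hash_noise(seq, weights$noise_sd)
}

#' Scalar oracle predictor from weights
#'
#' @param weights An [oracle_weights()] object.
#' @param name Display name.
#' @return A scalar [predictor()].
#' @export
oracle_predictor <- function(weights, name = "oracle") {
  force(weights)
  predictor(name, function(seq) oracle_score(seq, weights), type = "scalar")
}

#' Binned-track oracle predictor from weights
#'
#' Emits `floor(L / bin_size_bp)` bins; each bin carries the baseline plus
#' the sign-adjusted contributions of matched offsets falling in that bin.
#' Deterministic per-sequence noise is not applied to track output.
#'
#' @param weights An [oracle_weights()] object.
#' @param bin_size_bp Bin width in bp.
#' @param name Display name.
#' @return A track [predictor()].
#' @export
oracle_track_predictor <- function(weights, bin_size_bp = 128,
                                   name = "oracle-track") {
  force(weights); force(bin_size_bp)
  predictor(name, function(seq) {
    n_bins <- nchar(seq) %/% bin_size_bp
    vals <- rep(weights$baseline, n_bins)
    if (length(weights$offsets) > 0) {
      at <- substring(seq, weights$offsets + 1L, weights$offsets + 1L)
      hit <- at == weights$bases
      sgn <- ifelse(weights$corrupted, -1, 1)
      bins <- weights$offsets %/% bin_size_bp
      for (j in which(hit & bins < n_bins)) {
        vals[bins[j] + 1L] <- vals[bins[j] + 1L] +
          sgn[j] * weights$contributions[j]
      }
    }
    binned_track(vals, bin_size_bp)
  }, type = "track", bin_size_bp = bin_size_bp)
}

#' Run a predictor over all personal sequences and the reference
#'
#' @param pred A single [predictor()] applied to every gene, or a named list
#'   of predictors keyed by gene id (the per-gene oracle case).
#' @param sequences data.frame from [build_personal_sequences()].
#' @param ref_sequences Named character vector of reference window
#'   sequences, one per gene, in emitted orientation.
#' @param tss_offset_bp 0-based TSS offset within the windows.
#' @param cfg An [aggregation_config()].
#' @return List with `predictions` (genes x individuals matrix) and
#'   `reference` (named per-gene vector of reference-sequence predictions).
#' @export
run_predictions <- function(pred, sequences, ref_sequences, tss_offset_bp,
                            cfg) {
  genes <- unique(sequences$gene_id)
  individuals <- unique(sequences$individual_id)
  key <- paste(sequences$gene_id, sequences$individual_id)
  want <- as.vector(outer(genes, individuals, paste))
  missing <- setdiff(want, key)
  if (length(missing))
    stop("missing (gene, individual) pairs: ",
         paste(utils::head(missing, 5), collapse = "; "))
  if (!setequal(genes, names(ref_sequences)))
    stop("ref_sequences gene set does not match sequences")
  get_pred <- function(g) {
    if (inherits(pred, "Predictor")) pred
    else {
      p <- pred[[g]]
      if (is.null(p)) stop("no predictor for gene ", g)
      p
    }
  }
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(individuals),
                dimnames = list(genes, individuals))
  split_idx <- split(seq_len(nrow(sequences)), key)
  for (g in genes) {
    pg <- get_pred(g)
    for (ind in individuals) {
      rows <- split_idx[[paste(g, ind)]]
      mat[g, ind] <- predict_gene(pg, sequences$sequence[rows],
                                  tss_offset_bp, cfg)
    }
  }
  ref <- vapply(genes, function(g) {
    predict_gene(get_pred(g), ref_sequences[[g]], tss_offset_bp, cfg)
  }, numeric(1))
  list(predictions = mat, reference = ref)
}

#' Ensemble prediction matrices across models
#'
#' @param matrices List of genes x individuals matrices with identical
#'   dimnames.
#' @param mode `"raw_mean"` (elementwise mean) or `"zscore_mean"` (each
#'   matrix standardized per gene across individuals first; zero-variance
#'   gene rows pass through as zeros).
#' @return Ensemble matrix with the shared dimnames.
#' @export
ensemble <- function(matrices, mode = c("raw_mean", "zscore_mean")) {
  mode <- match.arg(mode)
  stopifnot(length(matrices) >= 1)
  dn <- dimnames(matrices[[1]])
  for (m in matrices) {
    if (!identical(dimnames(m), dn))
      stop("prediction matrices have mismatched gene/individual indices")
  }
  if (mode == "zscore_mean") {
    matrices <- lapply(matrices, function(m) {
      t(apply(m, 1, function(r) {
        s <- stats::sd(r)
        if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
      }))
    })
    matrices <- lapply(matrices, function(m) { dimnames(m) <- dn; m })
  }
  Reduce(`+`, matrices) / length(matrices)
}
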