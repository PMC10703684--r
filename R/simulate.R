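# Synthetic cohort generator: reference genome, phased SNV genotypes with a
# common-variant MAF spectrum, TSS-anchored genes, sparse causal cis
# architectures with signed effects, expression at a controlled
# heritability, and truth-consistent oracle predictor weights. Everything
# the pipeline consumes can be generated here, seeded, with no downloads.

#' Derive a reproducible sub-seed from a global seed and a stage label
#'
#' Gives each pipeline stage its own deterministic RNG substream so stages
#' are independently reproducible. The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Integer global seed.
#' @param label Stage name.
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483627) + 1L
}

#' Configuration for the synthetic cohort
#'
#' Defaults describe a small but realistic study: a diploid cohort with
#' common variants (MAF uniform on `[0.05, 0.5]`), sparse per-gene causal
#' architectures of 5 cis variants with Gaussian signed effects, and
#' expression heritability 0.5.
#'
#' @param n_individuals Cohort size.
#' @param n_genes Number of genes.
#' @param n_contigs,contig_length Synthetic genome shape.
#' @param upstream_bp,downstream_bp,strand_aware Input window; see
#'   [window_spec()].
#' @param variant_density Expected variants per bp.
#' @param maf_low,maf_high Uniform MAF spectrum bounds.
#' @param n_causal Causal cis variants per gene.
#' @param effect_sd S.d. of the Gaussian signed effect sizes.
#' @param h2 Expression heritability in `[0, 1]`; scalar or one value per
#'   gene.
#' @param sign_corruption_rate Probability that an oracle weight's sign is
#'   flipped (emulating a predictor that detects a variant but mistakes its
#'   direction).
#' @param noise_sd S.d. of the oracle's deterministic per-sequence noise.
#' @param ld_mode `"none"` (independent Bernoulli haplotypes,
#'   Hardy-Weinberg, no LD) or `"mosaic"` (haplotypes copied in blocks from
#'   a founder pool, inducing LD).
#' @param n_founders,founder_block_variants Mosaic-mode pool size and block
#'   length (in variants).
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(n_individuals = 100, n_genes = 30, n_contigs = 2,
                       contig_length = 50000, upstream_bp = 2000,
                       downstream_bp = 1000, strand_aware = TRUE,
                       variant_density = 0.01, maf_low = 0.05,
                       maf_high = 0.5, n_causal = 5, effect_sd = 1,
                       h2 = 0.5, sign_corruption_rate = 0, noise_sd = 0,
                       ld_mode = c("none", "mosaic"), n_founders = 10,
                       founder_block_variants = 25, seed = 1) {
  ld_mode <- match.arg(ld_mode)
  stopifnot(n_individuals >= 2, n_genes >= 1, n_contigs >= 1,
            contig_length >= 1, variant_density >= 0,
            maf_low > 0, maf_high <= 0.5, maf_low <= maf_high,
            n_causal >= 1, effect_sd > 0,
            all(h2 >= 0), all(h2 <= 1),
            length(h2) %in% c(1L, n_genes),
            sign_corruption_rate >= 0, sign_corruption_rate <= 1,
            noise_sd >= 0)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_genes = as.integer(n_genes),
                 n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp),
                 strand_aware = strand_aware,
                 variant_density = variant_density,
                 maf_low = maf_low, maf_high = maf_high,
                 n_causal = as.integer(n_causal), effect_sd = effect_sd,
                 h2 = h2, sign_corruption_rate = sign_corruption_rate,
                 noise_sd = noise_sd, ld_mode = ld_mode,
                 n_founders = as.integer(n_founders),
                 founder_block_variants = as.integer(founder_block_variants),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Window spec implied by a simulation config
#'
#' @param cfg A [sim_config()].
#' @return A [window_spec()].
#' @export
sim_window_spec <- function(cfg) {
  window_spec(cfg$upstream_bp, cfg$downstream_bp, cfg$strand_aware)
}

# One contig's worth of variants plus haplotype matrices.
simulate_contig_variants <- function(contig_seq, chrom, cfg) {
  L <- nchar(contig_seq)
  n_var <- round(cfg$variant_density * L)
  if (n_var == 0)
    return(list(variants = data.frame(chrom = character(0), pos = integer(0),
                                      variant_id = character(0),
                                      ref = character(0), alt = character(0),
                                      maf_sim = numeric(0),
                                      stringsAsFactors = FALSE),
                hap0 = matrix(integer(0), 0, cfg$n_individuals),
                hap1 = matrix(integer(0), 0, cfg$n_individuals)))
  pos <- sort(sample.int(L, n_var))
  ref <- substring(contig_seq, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(VALID_BASES, b), 1),
                character(1), USE.NAMES = FALSE)
  maf <- stats::runif(n_var, cfg$maf_low, cfg$maf_high)
  draw_haps <- function() {
    if (cfg$ld_mode == "none") {
      matrix(stats::rbinom(n_var * cfg$n_individuals, 1, maf), nrow = n_var)
    } else {
      founders <- matrix(stats::rbinom(n_var * cfg$n_founders, 1, maf),
                         nrow = n_var)
      blocks <- ceiling(seq_len(n_var) / cfg$founder_block_variants)
      out <- matrix(0L, n_var, cfg$n_individuals)
      for (i in seq_len(cfg$n_individuals)) {
        pick <- sample.int(cfg$n_founders, max(blocks), replace = TRUE)
        out[, i] <- founders[cbind(seq_len(n_var), pick[blocks])]
      }
      out
    }
  }
  # maf_sim records the drawn (population) MAF; realized cohort frequency
  # fluctuates around it binomially
  list(variants = data.frame(chrom = chrom, pos = pos,
                             variant_id = paste0(chrom, ":", pos),
                             ref = ref, alt = alt, maf_sim = maf,
                             stringsAsFactors = FALSE),
       hap0 = draw_haps(), hap1 = draw_haps())
}

#' Simulate a reference genome, phased cohort, and gene annotations
#'
#' The reference is i.i.d. uniform A/C/G/T; variant positions are uniform
#' without collision with per-variant MAF drawn from the configured
#' spectrum; haplotype alleles are i.i.d. Bernoulli(MAF) per haplotype
#' (Hardy-Weinberg, no LD) unless mosaic LD mode is on. Genes are placed so
#' their windows fit inside contigs with strands alternating, and variant
#' placement is redrawn (up to 20 attempts) until every gene window holds at
#' least `n_causal` variants.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (`ReferenceGenome`), `cohort`
#'   (`PhasedCohort`), `genes` (`GeneAnnotation`), and `spec`
#'   ([window_spec()]).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  spec <- sim_window_spec(cfg)
  margin <- max(cfg$upstream_bp, cfg$downstream_bp) + 10L
  if (2L * margin + 2L >= cfg$contig_length)
    stop("window does not fit inside the contig")
  set.seed(derive_seed(cfg$seed, "cohort"))
  contigs <- stats::setNames(
    vapply(seq_len(cfg$n_contigs), function(i)
      paste(sample(VALID_BASES, cfg$contig_length, replace = TRUE),
            collapse = ""), character(1)),
    paste0("chr", seq_len(cfg$n_contigs)))
  genome <- reference_genome(contigs)

  gene_chrom <- names(contigs)[rep_len(seq_len(cfg$n_contigs), cfg$n_genes)]
  tss <- integer(cfg$n_genes)
  for (cc in unique(gene_chrom)) {
    idx <- which(gene_chrom == cc)
    lo <- margin + 1L
    hi <- cfg$contig_length - margin
    tss[idx] <- sort(sample(seq(lo, hi), length(idx)))
  }
  genes <- gene_annotation(sprintf("gene%03d", seq_len(cfg$n_genes)),
                           gene_chrom, tss,
                           rep_len(c("+", "-"), cfg$n_genes))

  individuals <- sprintf("ind%04d", seq_len(cfg$n_individuals))
  for (attempt in seq_len(20)) {
    parts <- lapply(names(contigs), function(cc)
      simulate_contig_variants(contigs[[cc]], cc, cfg))
    variants <- do.call(rbind, lapply(parts, `[[`, "variants"))
    hap0 <- do.call(rbind, lapply(parts, `[[`, "hap0"))
    hap1 <- do.call(rbind, lapply(parts, `[[`, "hap1"))
    cohort <- phased_cohort(variants, individuals, hap0, hap1)
    if (cfg$variant_density == 0) break # zero-variant cohort is legitimate
    enough <- vapply(seq_len(nrow(genes)), function(g) {
      itv <- resolve_window(genes[g, ], spec)
      sum(cohort$variants$chrom == itv$chrom &
            cohort$variants$pos - 1L >= itv$start &
            cohort$variants$pos - 1L < itv$end) >= cfg$n_causal
    }, logical(1))
    if (all(enough)) break
    if (attempt == 20)
      stop("could not place >= n_causal variants in every gene window; ",
           "raise variant_density or widen the window")
  }
  list(genome = genome, cohort = cohort, genes = genes, spec = spec)
}

#' Simulate expression with an additive cis-genetic architecture
#'
#' For each gene, `n_causal` variants are sampled inside its input window
#' with effects `beta ~ N(0, effect_sd^2)`; the additive genetic value is
#' `g_i = sum_j beta_j d_ij` over alt-allele dosages, and expression is
#' `y_i = g_i + e_i` with noise variance `Var(g) (1 - h2) / h2` computed
#' from the realized sample variance of g (pure noise when `h2 = 0`).
#' Expression is shifted by a per-gene constant to be non-negative; the
#' shift is affine so every rank relation with g is preserved.
#'
#' @param cohort `PhasedCohort`.
#' @param genes `GeneAnnotation`.
#' @param cfg [sim_config()].
#' @param spec [window_spec()]; defaults to the config's.
#' @return List with `expression` (`ExpressionMatrix`) and `truth`
#'   (`SyntheticTruth`: per-gene causal ids, signed effects, genetic
#'   values, target and realized h2).
#' @export
simulate_expression <- function(cohort, genes, cfg, spec = sim_window_spec(cfg)) {
  stopifnot(inherits(cohort, "PhasedCohort"), inherits(cfg, "SimConfig"))
  set.seed(derive_seed(cfg$seed, "expression"))
  n <- length(cohort$individuals)
  h2s <- rep_len(cfg$h2, nrow(genes))
  d_all <- cohort$hap0 + cohort$hap1
  pos0 <- cohort$variants$pos - 1L
  y_mat <- matrix(NA_real_, nrow(genes), n,
                  dimnames = list(genes$gene_id, cohort$individuals))
  per_gene <- stats::setNames(vector("list", nrow(genes)), genes$gene_id)
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    itv <- resolve_window(gene, spec)
    in_win <- which(cohort$variants$chrom == itv$chrom &
                      pos0 >= itv$start & pos0 < itv$end)
    if (length(in_win) < cfg$n_causal)
      stop("gene ", gene$gene_id, " window has fewer than n_causal variants")
    g_val <- NULL
    for (try in seq_len(50)) {
      causal <- sort(sample(in_win, cfg$n_causal))
      # effects are rounded to dyadic rationals (multiples of 2^-26) so that
      # every additive genetic value and oracle score is exact in double
      # precision: equal genotype configurations yield bitwise-equal scores
      # and rank ties are well-defined, whatever the summation order
      beta <- round(stats::rnorm(cfg$n_causal, 0, cfg$effect_sd) * 2^26) / 2^26
      if (any(beta == 0)) next
      gv <- as.numeric(crossprod(d_all[causal, , drop = FALSE], beta))
      if (stats::var(gv) > 0) { g_val <- gv; break }
    }
    if (is.null(g_val))
      stop("gene ", gene$gene_id, ": zero genetic variance after retries")
    h2 <- h2s[g]
    y <- if (h2 == 0) {
      stats::rnorm(n, 0, 1)
    } else {
      g_val + stats::rnorm(n, 0, sqrt(stats::var(g_val) * (1 - h2) / h2))
    }
    y <- y - min(y)
    y_mat[g, ] <- y
    per_gene[[gene$gene_id]] <- list(
      gene_id = gene$gene_id,
      causal_ids = cohort$variants$variant_id[causal],
      beta = beta,
      genetic_value = stats::setNames(g_val, cohort$individuals),
      h2_target = h2,
      h2_realized = if (stats::var(y) > 0 && h2 > 0)
        stats::var(g_val) / stats::var(y) else 0)
  }
  truth <- structure(list(genes = per_gene, seed = cfg$seed,
                          sign_corruption_rate = cfg$sign_corruption_rate,
                          noise_sd = cfg$noise_sd),
                     class = "SyntheticTruth")
  list(expression = expression_matrix(y_mat), truth = truth)
}

#' Build truth-consistent oracle weights for every gene
#'
#' Places, for each causal variant, its signed effect as the contribution of
#' the alt base at the variant's offset in the emitted window (offset
#' mirrored and base complemented for negative-strand genes under
#' strand-aware specs; ref bases contribute 0). Under haplotype averaging
#' the individual-level oracle score is `baseline + (1/2) sum_j beta_j
#' d_ij` — monotone in the genetic value; the factor 1/2 is immaterial to
#' rank metrics. A seeded subset of weights of expected fraction
#' `sign_corruption_rate` has its sign flipped.
#'
#' @param truth `SyntheticTruth` from [simulate_expression()].
#' @param cohort `PhasedCohort`.
#' @param genes `GeneAnnotation`.
#' @param spec [window_spec()].
#' @param sign_corruption_rate,noise_sd Overrides; default from `truth`.
#' @param baselines Optional named per-gene baseline scores (default 0).
#' @param seed Seed for the corrupted-sign draw; default the truth's.
#' @return Named list of [oracle_weights()], one per gene.
#' @export
make_oracle_weights <- function(truth, cohort, genes, spec,
                                sign_corruption_rate = NULL, noise_sd = NULL,
                                baselines = NULL, seed = NULL) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  q <- if (is.null(sign_corruption_rate)) truth$sign_corruption_rate
       else sign_corruption_rate
  nsd <- if (is.null(noise_sd)) truth$noise_sd else noise_sd
  seed <- if (is.null(seed)) truth$seed else seed
  out <- list()
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    tg <- truth$genes[[gene$gene_id]]
    if (is.null(tg)) stop("no truth record for gene ", gene$gene_id)
    itv <- resolve_window(gene, spec)
    L <- itv$end - itv$start
    vi <- match(tg$causal_ids, cohort$variants$variant_id)
    if (anyNA(vi)) stop("truth causal variant missing from cohort")
    pos0 <- cohort$variants$pos[vi] - 1L
    off <- pos0 - itv$start
    base <- cohort$variants$alt[vi]
    if (spec$strand_aware && gene$strand == "-") {
      off <- (L - 1L) - off
      base <- complement_base(base)
    }
    set.seed(derive_seed(seed, paste0("corrupt:", gene$gene_id)))
    corrupted <- stats::runif(length(off)) < q
    bl <- if (is.null(baselines)) 0 else unname(baselines[gene$gene_id])
    out[[gene$gene_id]] <- oracle_weights(
      window_length = L, offsets = off, bases = base,
      contributions = tg$beta, baseline = bl, corrupted = corrupted,
      noise_sd = nsd)
  }
  out
}

#' Genotype-space oracle predictions
#'
#' The individual-level value the noiseless sequence oracle produces under
#' haplotype averaging, computed directly from dosages:
#' `baseline + (1/2) sum_j s_j beta_j d_ij`, with `s_j = -1` at
#' corrupted-sign weights. Equal to running the sequence pipeline
#' (personal sequences + oracle scoring) when `noise_sd = 0` — bitwise for
#' the default zero baseline, to within one ulp otherwise — an equivalence
#' the test suite verifies, so it serves as a fast route at large
#' simulation scales.
#'
#' @param truth `SyntheticTruth`.
#' @param cohort `PhasedCohort`.
#' @param weights Optional named list from [make_oracle_weights()]; when
#'   given, its corrupted-sign flags and baselines are honored (flag order
#'   follows the truth's causal id order). Default: no corruption,
#'   baseline 0.
#' @return Genes x individuals prediction matrix.
#' @export
oracle_dosage_predictions <- function(truth, cohort, weights = NULL) {
  stopifnot(inherits(truth, "SyntheticTruth"), inherits(cohort, "PhasedCohort"))
  d <- cohort$hap0 + cohort$hap1
  ids <- names(truth$genes)
  out <- matrix(NA_real_, length(ids), length(cohort$individuals),
                dimnames = list(ids, cohort$individuals))
  for (gid in ids) {
    tg <- truth$genes[[gid]]
    vi <- match(tg$causal_ids, cohort$variants$variant_id)
    if (anyNA(vi)) stop("truth causal variant missing from cohort")
    sgn <- rep(1, length(vi))
    bl <- 0
    if (!is.null(weights)) {
      w <- weights[[gid]]
      if (is.null(w)) stop("no weights for gene ", gid)
      sgn <- ifelse(w$corrupted, -1, 1)
      bl <- w$baseline
    }
    out[gid, ] <- bl +
      0.5 * as.numeric(crossprod(d[vi, , drop = FALSE], sgn * tg$beta))
  }
  out
}

#' Marginal cis-eQTL scan on the synthetic cohort
#'
#' For every (gene, cis variant) pair passing the distance and MAF filters,
#' a simple linear regression of expression on dosage yields a slope and a
#' two-sided t-test p-value; the minimum-p record per gene is retained,
#' ties broken by smaller `|distance_to_tss|` then lexicographic variant
#' id. The gene-level p-value is the minimum p Sidak-corrected for the
#' number of cis variants tested (`1 - (1 - p)^m`, exact under the
#' generator's independent-variant default and the analogue of the
#' permutation-adjusted gene-level p-values of eQTL pipelines); applying
#' Benjamini-Hochberg across genes to these defines the FDR < `fdr`
#' "eGene" subset used as the default evaluation gene set.
#'
#' @param cohort `PhasedCohort`.
#' @param expression Matched `ExpressionMatrix`.
#' @param genes `GeneAnnotation`.
#' @param window_bp Distance cutoff from the TSS.
#' @param maf_min Cohort MAF cutoff.
#' @param fdr FDR threshold for the eGene call.
#' @return data.frame with one row per scanned gene: `gene_id`,
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `beta`, `pvalue`, `pip`
#'   (`NA`; no fine-mapping here), `maf`, `distance_to_tss`, `p_gene`
#'   (Sidak-corrected), `padj` (BH across genes), `egene`. Genes with no
#'   testable variant are absent.
#' @export
marginal_eqtl_scan <- function(cohort, expression, genes, window_bp = 20000,
                               maf_min = 0.05, fdr = 0.05) {
  stopifnot(identical(colnames(expression), cohort$individuals))
  n <- length(cohort$individuals)
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    if (!gene$gene_id %in% rownames(expression)) next
    dm <- build_dosage_matrix(cohort, gene, window_bp, maf_min)
    if (ncol(dm$dosages) == 0) next
    y <- expression[gene$gene_id, ]
    if (stats::sd(y) == 0) next
    sds <- apply(dm$dosages, 2, stats::sd)
    ok <- sds > 0
    if (!any(ok)) next
    r <- as.numeric(stats::cor(dm$dosages[, ok, drop = FALSE], y))
    r2 <- pmin(r^2, 1 - 1e-15)
    tt <- r * sqrt((n - 2) / (1 - r2))
    pv <- 2 * stats::pt(-abs(tt), df = n - 2)
    slope <- r * stats::sd(y) / sds[ok]
    info <- dm$variants[ok, , drop = FALSE]
    best <- order(pv, abs(info$distance_to_tss), info$variant_id)[1]
    vrow <- cohort$variants[match(info$variant_id[best],
                                  cohort$variants$variant_id), ]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene$gene_id, variant_id = info$variant_id[best],
      chrom = vrow$chrom, pos = vrow$pos, ref = vrow$ref, alt = vrow$alt,
      beta = slope[best], pvalue = pv[best], pip = NA_real_,
      maf = info$maf[best], distance_to_tss = info$distance_to_tss[best],
      p_gene = 1 - (1 - pv[best])^sum(ok),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$padj <- stats::p.adjust(out$p_gene, method = "BH")
  out$egene <- out$padj < fdr
  rownames(out) <- NULL
  out
}

#' Fine-mapped-style QTL table from the simulation truth
#'
#' One record per causal variant per gene, carrying the true signed effect
#' and PIP 1 (the simulation knows its causal set exactly). This plays the
#' role of an external fine-mapping result when exercising the
#' direction-of-effect classifier.
#'
#' @param truth `SyntheticTruth`.
#' @param cohort `PhasedCohort`.
#' @param genes `GeneAnnotation`.
#' @return data.frame in the qtl table schema.
#' @export
truth_qtl_table <- function(truth, cohort, genes) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  af <- rowMeans(cohort$hap0 + cohort$hap1) / 2
  maf <- pmin(af, 1 - af)
  do.call(rbind, lapply(genes$gene_id, function(gid) {
    tg <- truth$genes[[gid]]
    vi <- match(tg$causal_ids, cohort$variants$variant_id)
    v <- cohort$variants[vi, ]
    tss0 <- genes$tss[genes$gene_id == gid] - 1L
    data.frame(gene_id = gid, variant_id = v$variant_id, chrom = v$chrom,
               pos = v$pos, ref = v$ref, alt = v$alt, beta = tg$beta,
               pvalue = NA_real_, pip = 1, maf = maf[vi],
               distance_to_tss = (v$pos - 1L) - tss0,
               stringsAsFactors = FALSE)
  }))
}

truth_to_list <- function(truth) {
  list(seed = truth$seed,
       sign_corruption_rate = truth$sign_corruption_rate,
       noise_sd = truth$noise_sd,
       genes = lapply(truth$genes, function(tg)
         list(gene_id = tg$gene_id, causal_ids = as.list(tg$causal_ids),
              beta = as.list(tg$beta),
              genetic_value = as.list(tg$genetic_value),
              h2_target = tg$h2_target, h2_realized = tg$h2_realized)))
}

#' Write the simulation truth as JSON
#'
#' @param truth `SyntheticTruth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  # 17 significant digits: doubles (including the dyadic effect sizes)
  # round-trip bitwise through the JSON text
  jsonlite::write_json(truth_to_list(truth), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a simulation truth JSON
#'
#' @param path Path written by [write_truth_json()].
#' @return A `SyntheticTruth`.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path)
  genes <- lapply(x$genes, function(tg) {
    gv <- unlist(tg$genetic_value)
    list(gene_id = tg$gene_id,
         causal_ids = as.character(unlist(tg$causal_ids)),
         beta = as.numeric(unlist(tg$beta)),
         genetic_value = stats::setNames(as.numeric(gv), names(gv)),
         h2_target = tg$h2_target, h2_realized = tg$h2_realized)
  })
  structure(list(genes = genes, seed = x$seed,
                 sign_corruption_rate = x$sign_corruption_rate,
                 noise_sd = x$noise_sd),
            class = "SyntheticTruth")
}

#' Write the full synthetic fixture set to a directory
#'
#' Emits `genome.fa`, `cohort.vcf`, `genes.tsv`, `expression.tsv`,
#' `qtl.tsv`, `truth.json`, and `config-echo.yaml`, all in the exact
#' formats the package's readers consume, and returns a manifest of paths
#' and MD5 content hashes (stable under a fixed seed).
#'
#' @param out_dir Output directory (created if needed).
#' @param genome,cohort,genes,expression,truth Simulation artifacts.
#' @param qtl Optional qtl-schema table; defaults to [truth_qtl_table()].
#' @param cfg Optional [sim_config()] echoed as YAML.
#' @return data.frame manifest with columns `file`, `path`, `md5`.
#' @export
emit_fixtures <- function(out_dir, genome, cohort, genes, expression, truth,
                          qtl = NULL, cfg = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir)
  p <- function(f) file.path(out_dir, f)
  write_fasta(genome, p("genome.fa"))
  write_vcf(cohort, p("cohort.vcf"), genome)
  utils::write.table(as.data.frame(unclass(genes)), p("genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  em <- data.frame(gene_id = rownames(expression),
                   apply(expression, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(em, p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (is.null(qtl)) qtl <- truth_qtl_table(truth, cohort, genes)
  utils::write.table(qtl, p("qtl.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_truth_json(truth, p("truth.json"))
  yaml::write_yaml(if (is.null(cfg)) list() else unclass(cfg),
                   p("config-echo.yaml"))
  files <- c("genome.fa", "cohort.vcf", "genes.tsv", "expression.tsv",
             "qtl.tsv", "truth.json", "config-echo.yaml")
  data.frame(file = files, path = vapply(files, p, character(1)),
             md5 = unname(tools::md5sum(vapply(files, p, character(1)))),
             stringsAsFactors = FALSE)
}
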