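# Small in-code fixtures shared across tests.

# A deterministic random genome.
toy_genome <- function(lengths = c(chr1 = 2000), seed = 11) {
  set.seed(seed)
  reference_genome(vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
}

# A hand-specified cohort: variants as data.frame, genotype strings "a|b"
# as a variants x individuals character matrix.
toy_cohort <- function(variants, gt, individuals = NULL) {
  if (is.null(individuals))
    individuals <- paste0("ind", seq_len(ncol(gt)))
  h0 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  h1 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  phased_cohort(variants, individuals, h0, h1)
}

# A genome guaranteed to carry the given ref alleles at the given positions.
genome_with_refs <- function(length, pos, ref, chrom = "chr1", seed = 11) {
  g <- toy_genome(stats::setNames(length, chrom), seed = seed)
  s <- get_contig(g, chrom)
  for (k in seq_along(pos)) substr(s, pos[k], pos[k]) <- ref[k]
  reference_genome(stats::setNames(s, chrom))
}

# Independent brute-force Spearman: explicit average ranks, explicit
# Pearson product-moment formula.
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(rx)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2)
  syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# A small simulated dataset for pipeline-ish tests.
quick_sim <- function(n_individuals = 30, n_genes = 8, h2 = 0.8, seed = 5,
                      ...) {
  cfg <- sim_config(n_individuals = n_individuals, n_genes = n_genes,
                    n_contigs = 2, contig_length = 20000,
                    upstream_bp = 400, downstream_bp = 250,
                    strand_aware = TRUE, variant_density = 0.02,
                    n_causal = 3, h2 = h2, seed = seed, ...)
  sim <- simulate_cohort(cfg)
  se <- simulate_expression(sim$cohort, sim$genes, cfg, sim$spec)
  c(sim, se, list(cfg = cfg))
}
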