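# Statistical structure and determinism of the synthetic cohort generator.

test_that("derive_seed is deterministic, label-sensitive, and in range", {
  expect_identical(derive_seed(1, "a"), derive_seed(1, "a"))
  expect_false(derive_seed(1, "a") == derive_seed(1, "b"))
  expect_false(derive_seed(1, "a") == derive_seed(2, "a"))
  for (s in c(1, 17, 2^30))
    expect_true(derive_seed(s, "stage") >= 1 &&
                  derive_seed(s, "stage") < 2^31)
})

test_that("sim_config validates its fields", {
  expect_error(sim_config(h2 = 1.5), "h2")
  expect_error(sim_config(maf_low = 0), "maf_low")
  expect_error(sim_config(sign_corruption_rate = 2))
  expect_error(sim_config(n_genes = 3, h2 = c(0.1, 0.5)), "h2")
  expect_s3_class(sim_config(n_genes = 2, h2 = c(0.1, 0.5)), "SimConfig")
})

test_that("a zero-density config yields a variant-free cohort", {
  cfg <- sim_config(n_individuals = 2, n_genes = 1, contig_length = 5000,
                    variant_density = 0, upstream_bp = 200,
                    downstream_bp = 200, strand_aware = FALSE, seed = 2)
  sim <- simulate_cohort(cfg)
  expect_identical(nrow(sim$cohort$variants), 0L)
})

test_that("cohort allele frequencies concentrate on their drawn MAFs", {
  cfg <- sim_config(n_individuals = 1000, n_genes = 2, n_contigs = 1,
                    contig_length = 20000, variant_density = 0.005,
                    upstream_bp = 300, downstream_bp = 300,
                    strand_aware = FALSE, n_causal = 2, seed = 33)
  sim <- simulate_cohort(cfg)
  af <- rowMeans(sim$cohort$hap0 + sim$cohort$hap1) / 2
  maf <- sim$cohort$variants$maf_sim
  expect_true(all(af >= 0 & af <= 1))
  # binomial concentration at 2n = 2000 draws: 4 sd < 0.05 everywhere
  expect_lt(max(abs(af - maf)), 0.05)
  expect_gt(cor(af, maf), 0.95)
})

test_that("genotypes are Hardy-Weinberg at the simulated MAFs", {
  cfg <- sim_config(n_individuals = 1000, n_genes = 2, n_contigs = 1,
                    contig_length = 20000, variant_density = 0.005,
                    upstream_bp = 300, downstream_bp = 300,
                    strand_aware = FALSE, n_causal = 2, seed = 34)
  sim <- simulate_cohort(cfg)
  d <- sim$cohort$hap0 + sim$cohort$hap1
  n <- ncol(d)
  pvals <- apply(d, 1, function(row) {
    p <- mean(row) / 2
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(row + 1L, nbins = 3L)
    suppressWarnings(stats::chisq.test(obs, p = expd / n)$p.value)
  })
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("expression follows the additive model at the target h2", {
  # h2 = 1: expression is the genetic value plus a per-gene constant
  sim1 <- quick_sim(n_individuals = 50, n_genes = 5, h2 = 1, seed = 41)
  for (gid in names(sim1$truth$genes)) {
    tg <- sim1$truth$genes[[gid]]
    resid <- sim1$expression[gid, ] - tg$genetic_value
    expect_lt(diff(range(resid)), 1e-12)
    expect_equal(spearman_rho(tg$genetic_value, sim1$expression[gid, ]), 1)
  }
  # h2 = 0: expression independent of the genetic value
  cfg0 <- sim_config(n_individuals = 1000, n_genes = 8, n_contigs = 2,
                     contig_length = 20000, variant_density = 0.02,
                     upstream_bp = 400, downstream_bp = 250,
                     strand_aware = TRUE, n_causal = 3, h2 = 0, seed = 42)
  sim0 <- simulate_cohort(cfg0)
  se0 <- simulate_expression(sim0$cohort, sim0$genes, cfg0, sim0$spec)
  rhos <- vapply(names(se0$truth$genes), function(gid)
    spearman_rho(se0$truth$genes[[gid]]$genetic_value,
                 se0$expression[gid, ]), numeric(1))
  expect_lt(max(abs(rhos)), 3 / sqrt(1000))
  expect_lt(abs(mean(rhos)), 2 / sqrt(8 * 1000))
  # h2 = 0.5: realized variance ratio close to target
  cfg5 <- cfg0; cfg5$h2 <- 0.5; cfg5$seed <- 43L
  sim5 <- simulate_cohort(cfg5)
  se5 <- simulate_expression(sim5$cohort, sim5$genes, cfg5, sim5$spec)
  h2r <- vapply(se5$truth$genes, function(tg) tg$h2_realized, numeric(1))
  expect_lt(max(abs(h2r - 0.5)), 0.05)
  # expression is non-negative and rank-preserving in g at h2 = 1
  expect_true(all(sim1$expression >= 0))
})

test_that("oracle weights rank like the genetic value, or its reverse", {
  sim <- quick_sim(n_individuals = 30, n_genes = 4, h2 = 0.5, seed = 44)
  wts <- make_oracle_weights(sim$truth, sim$cohort, sim$genes, sim$spec)
  pred <- oracle_dosage_predictions(sim$truth, sim$cohort, wts)
  for (gid in names(sim$truth$genes))
    expect_equal(spearman_rho(pred[gid, ],
                              sim$truth$genes[[gid]]$genetic_value), 1)
  # full corruption with one causal variant reverses the ranking
  cfg1 <- sim_config(n_individuals = 40, n_genes = 3, contig_length = 20000,
                     upstream_bp = 400, downstream_bp = 250,
                     strand_aware = TRUE, variant_density = 0.02,
                     n_causal = 1, h2 = 1, sign_corruption_rate = 1,
                     seed = 45)
  s1 <- simulate_cohort(cfg1)
  e1 <- simulate_expression(s1$cohort, s1$genes, cfg1, s1$spec)
  w1 <- make_oracle_weights(e1$truth, s1$cohort, s1$genes, s1$spec)
  p1 <- oracle_dosage_predictions(e1$truth, s1$cohort, w1)
  for (gid in names(e1$truth$genes))
    expect_equal(spearman_rho(p1[gid, ],
                              e1$truth$genes[[gid]]$genetic_value), -1)
  # non-causal positions carry no weight (sparse map)
  expect_identical(length(wts[[1]]$offsets), sim$cfg$n_causal)
})

test_that("the marginal eQTL scan pinpoints strong causal variants", {
  hits <- 0L; signs <- 0L; n_seeds <- 60L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_individuals = 400, n_genes = 1, n_contigs = 1,
                      contig_length = 6000, variant_density = 0.02,
                      upstream_bp = 400, downstream_bp = 250,
                      strand_aware = TRUE, n_causal = 1, h2 = 0.9,
                      seed = 1000 + s)
    sim <- simulate_cohort(cfg)
    se <- simulate_expression(sim$cohort, sim$genes, cfg, sim$spec)
    scan <- marginal_eqtl_scan(sim$cohort, se$expression, sim$genes,
                               window_bp = 400)
    tg <- se$truth$genes[[1]]
    if (scan$variant_id[1] == tg$causal_ids) hits <- hits + 1L
    # the causal variant's own marginal slope must carry the true sign
    d <- cohort_dosages(sim$cohort)[tg$causal_ids, ]
    if (sign(cov(d, se$expression[1, ])) == sign(tg$beta))
      signs <- signs + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
  expect_gte(signs / n_seeds, 0.99)
})

test_that("fixture emission is complete, stable, and round-trips", {
  sim <- quick_sim(n_individuals = 10, n_genes = 3, seed = 46)
  qtl <- truth_qtl_table(sim$truth, sim$cohort, sim$genes)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- emit_fixtures(dir1, sim$genome, sim$cohort, sim$genes,
                      sim$expression, sim$truth, qtl, sim$cfg)
  m2 <- emit_fixtures(dir2, sim$genome, sim$cohort, sim$genes,
                      sim$expression, sim$truth, qtl, sim$cfg)
  expect_identical(nrow(m1), 7L)
  expect_true(all(file.exists(m1$path)))
  expect_identical(m1$md5, m2$md5)

  g2 <- read_fasta(file.path(dir1, "genome.fa"))
  expect_identical(unclass(g2), unclass(sim$genome))
  co2 <- read_phased_vcf(file.path(dir1, "cohort.vcf"), g2)
  expect_identical(co2$variants[, c("chrom", "pos", "variant_id", "ref", "alt")],
                   sim$cohort$variants[, c("chrom", "pos", "variant_id",
                                           "ref", "alt")])
  expect_identical(unname(co2$hap0), unname(sim$cohort$hap0))
  ga2 <- read_table(file.path(dir1, "genes.tsv"), "gene_annotation")
  expect_equal(as.data.frame(unclass(ga2)), as.data.frame(unclass(sim$genes)))
  ex2 <- read_table(file.path(dir1, "expression.tsv"), "expression")
  expect_equal(unclass(ex2)[, ], unclass(sim$expression)[, ], tolerance = 1e-15)
  tr2 <- read_truth_json(file.path(dir1, "truth.json"))
  expect_equal(tr2$genes, sim$truth$genes)
  expect_identical(tr2$seed, sim$truth$seed)
})

test_that("the truth-derived qtl table matches the causal architecture", {
  sim <- quick_sim(n_individuals = 20, n_genes = 3, seed = 47)
  qtl <- truth_qtl_table(sim$truth, sim$cohort, sim$genes)
  expect_identical(nrow(qtl), 3L * sim$cfg$n_causal)
  expect_true(all(qtl$pip == 1))
  for (gid in unique(qtl$gene_id)) {
    sub <- qtl[qtl$gene_id == gid, ]
    expect_identical(sub$variant_id, sim$truth$genes[[gid]]$causal_ids)
    expect_equal(sub$beta, sim$truth$genes[[gid]]$beta)
  }
})

test_that("mosaic LD mode induces haplotype sharing", {
  cfg <- sim_config(n_individuals = 200, n_genes = 2, n_contigs = 1,
                    contig_length = 20000, variant_density = 0.01,
                    upstream_bp = 300, downstream_bp = 300,
                    strand_aware = FALSE, n_causal = 2, ld_mode = "mosaic",
                    n_founders = 6, founder_block_variants = 40, seed = 48)
  sim <- simulate_cohort(cfg)
  h <- cbind(sim$cohort$hap0, sim$cohort$hap1)
  # adjacent-variant squared correlation (LD r2) should clearly exceed the
  # independent-variant baseline
  r2_adj <- sapply(seq_len(nrow(h) - 1), function(i) {
    if (sd(h[i, ]) == 0 || sd(h[i + 1, ]) == 0) return(NA_real_)
    cor(h[i, ], h[i + 1, ])^2
  })
  cfg_ind <- cfg; cfg_ind$ld_mode <- "none"
  sim_ind <- simulate_cohort(cfg_ind)
  h_ind <- cbind(sim_ind$cohort$hap0, sim_ind$cohort$hap1)
  r2_ind <- sapply(seq_len(nrow(h_ind) - 1), function(i) {
    if (sd(h_ind[i, ]) == 0 || sd(h_ind[i + 1, ]) == 0) return(NA_real_)
    cor(h_ind[i, ], h_ind[i + 1, ])^2
  })
  expect_gt(mean(r2_adj, na.rm = TRUE), 5 * mean(r2_ind, na.rm = TRUE))
})
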