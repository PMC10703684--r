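# Aggregation rules and the synthetic oracle predictors.

test_that("aggregate_tss_window reduces the centered bin window", {
  # bins carry their own index: mean over bins 6..15 around t = 10
  tr <- binned_track(0:19, 128)
  cfg <- aggregation_config(tss_window_bins = 10)
  expect_equal(aggregate_tss_window(tr, 1280, cfg), mean(6:15))
  expect_equal(aggregate_tss_window(tr, 1280, cfg), 10.5)
  # W = 3 sum on [1..5], t = 2 -> 2+3+4
  tr2 <- binned_track(1:5, 1)
  cfg2 <- aggregation_config(tss_window_bins = 3, window_reduce = "sum")
  expect_equal(aggregate_tss_window(tr2, 2, cfg2), 9)
  # constant track, any W, mean -> the constant
  tr3 <- binned_track(rep(3.5, 40), 128)
  for (W in c(1, 2, 9, 10))
    expect_equal(aggregate_tss_window(
      tr3, 20 * 128, aggregation_config(tss_window_bins = W)), 3.5)
  # W = 1 sum equals the single TSS-bin value
  cfg1 <- aggregation_config(tss_window_bins = 1, window_reduce = "sum")
  expect_equal(aggregate_tss_window(tr, 7 * 128 + 3, cfg1), 7)
  # even W: extra bin downstream (W = 10 -> t-4..t+5)
  expect_equal(aggregate_tss_window(tr, 128 * 10,
                                    aggregation_config(tss_window_bins = 2,
                                                       window_reduce = "sum")),
               10 + 11)
})

test_that("TSS windows outside the track error", {
  tr <- binned_track(1:5, 10)
  cfg <- aggregation_config(tss_window_bins = 3)
  expect_error(aggregate_tss_window(tr, 0, cfg), "exceed")
  expect_error(aggregate_tss_window(tr, 49, cfg), "exceed")
  expect_silent(aggregate_tss_window(tr, 25, cfg))
})

test_that("predict_gene averages haplotypes and sequence variants", {
  const <- predictor("const", function(s) 4.2, type = "scalar")
  cfg <- aggregation_config(rc_average = TRUE, shift_bp = 1)
  expect_equal(predict_gene(const, c("ACGTACGT", "ACGTACGT"), 4, cfg), 4.2)
  # constant track predictor: aggregation never manufactures signal
  ctrack <- predictor("ct", function(s) binned_track(rep(2, nchar(s) %/% 2), 2),
                      type = "track", bin_size_bp = 2)
  cfg2 <- aggregation_config(rc_average = TRUE, shift_bp = 1,
                             tss_window_bins = 2)
  expect_equal(predict_gene(ctrack, "ACGTACGTACGT", 6, cfg2), 2)
  # two identical haplotypes equal the single-haplotype value
  w <- oracle_weights(8, offsets = 2, bases = "G", contributions = 1.5,
                      baseline = 1)
  orc <- oracle_predictor(w)
  cfg0 <- aggregation_config()
  expect_equal(predict_gene(orc, c("AAGAAAAA", "AAGAAAAA"), 4, cfg0),
               predict_gene(orc, "AAGAAAAA", 4, cfg0))
  # haplotype mean: one carrying, one not
  expect_equal(predict_gene(orc, c("AAGAAAAA", "AAAAAAAA"), 4, cfg0),
               1 + 1.5 / 2)
  expect_error(predict_gene(orc, c("AAGAAAAA", "AAAAAAA"), 4, cfg0),
               "length")
})

test_that("rc averaging with mirror-symmetric weights equals forward-only", {
  # weights at offset k for base B and at L-1-k for the complement of B:
  # the reverse complement scores identically, so the two-term mean equals
  # the forward value
  L <- 10L
  w <- oracle_weights(L, offsets = c(2L, 7L), bases = c("G", "C"),
                      contributions = c(0.8, 0.8), baseline = 2)
  orc <- oracle_predictor(w)
  s <- "AAGAAAACAA" # carries G at offset 2; C at offset 7 = complement pair
  fwd <- predict_gene(orc, s, 5, aggregation_config())
  both <- predict_gene(orc, s, 5, aggregation_config(rc_average = TRUE))
  expect_equal(both, fwd)
  expect_equal(fwd, 2 + 1.6)
})

test_that("oracle_score matches its additive definition", {
  w0 <- oracle_weights(6, baseline = 3.3)
  expect_equal(oracle_score("ACGTAC", w0), 3.3)
  w1 <- oracle_weights(6, offsets = 4L, bases = "T", contributions = 0.7,
                       baseline = 1)
  expect_equal(oracle_score("ACGTTC", w1), 1.7)
  expect_equal(oracle_score("ACGTAC", w1), 1)
  # all signs corrupted: score = baseline - sum of alt contributions
  w2 <- oracle_weights(6, offsets = c(1L, 4L), bases = c("C", "T"),
                       contributions = c(0.5, 0.7), baseline = 1,
                       corrupted = c(TRUE, TRUE))
  expect_equal(oracle_score("ACGTTC", w2), 1 - 1.2)
  expect_error(oracle_score("ACGT", w1), "length")
})

test_that("oracle noise is a deterministic pure function of the sequence", {
  w <- oracle_weights(8, baseline = 0, noise_sd = 0.3)
  a1 <- oracle_score("ACGTACGT", w)
  a2 <- oracle_score("ACGTACGT", w)
  b <- oracle_score("ACGTACGA", w)
  expect_identical(a1, a2)
  expect_false(identical(a1, b))
  # global RNG state is untouched
  set.seed(123); before <- .Random.seed
  invisible(oracle_score("ACGTACGT", w))
  expect_identical(.Random.seed, before)
})

test_that("run_predictions produces the full matrix plus reference arm", {
  sim <- quick_sim(n_individuals = 5, n_genes = 3, h2 = 1)
  wts <- make_oracle_weights(sim$truth, sim$cohort, sim$genes, sim$spec)
  preds <- lapply(wts, oracle_predictor)
  seqs <- build_personal_sequences(sim$genome, sim$genes, sim$cohort,
                                   sim$spec)
  refs <- stats::setNames(
    vapply(seq_len(nrow(sim$genes)), function(g)
      reference_window_sequence(sim$genome, sim$genes[g, ], sim$spec),
      character(1)), sim$genes$gene_id)
  rp <- run_predictions(preds, seqs, refs, tss_offset(sim$spec),
                        aggregation_config())
  expect_identical(dim(rp$predictions), c(3L, 5L))
  expect_identical(length(rp$reference), 3L)
  # all-reference cohort: every column equals the reference prediction
  cfg0 <- sim$cfg
  cfg0$variant_density <- 0
  sim0 <- simulate_cohort(cfg0)
  seqs0 <- build_personal_sequences(sim0$genome, sim0$genes, sim0$cohort,
                                    sim0$spec)
  refs0 <- stats::setNames(
    vapply(seq_len(nrow(sim0$genes)), function(g)
      reference_window_sequence(sim0$genome, sim0$genes[g, ], sim0$spec),
      character(1)), sim0$genes$gene_id)
  wts0 <- lapply(refs0, function(s)
    oracle_weights(nchar(s), baseline = 1))
  rp0 <- run_predictions(lapply(wts0, oracle_predictor), seqs0, refs0,
                         tss_offset(sim0$spec), aggregation_config())
  for (j in seq_len(ncol(rp0$predictions)))
    expect_equal(unname(rp0$predictions[, j]), unname(rp0$reference))
  # missing pair detection: drop both haplotype rows of one pair
  drop <- seqs$gene_id == sim$genes$gene_id[1] &
    seqs$individual_id == sim$cohort$individuals[1]
  expect_error(run_predictions(preds, seqs[!drop, ], refs,
                               tss_offset(sim$spec), aggregation_config()),
               "missing \\(gene, individual\\) pairs")
})

test_that("ensemble raw_mean is the identity on copies and is linear", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("i", 1:4)))
  expect_equal(ensemble(list(m, m, m), "raw_mean"), m)
  expect_equal(ensemble(list(m, -m), "raw_mean"),
               matrix(0, 3, 4, dimnames = dimnames(m)))
  a <- matrix(rnorm(12), 3, 4, dimnames = dimnames(m))
  b <- matrix(rnorm(12), 3, 4, dimnames = dimnames(m))
  expect_equal(ensemble(list(2 * a, 2 * b), "raw_mean"),
               2 * ensemble(list(a, b), "raw_mean"))
  bad <- m; rownames(bad) <- paste0("x", 1:3)
  expect_error(ensemble(list(m, bad)), "mismatched")
})

test_that("zscore_mean is invariant to per-gene positive affine transforms", {
  set.seed(8)
  a <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("i", 1:10)))
  scalefac <- c(2, 0.5, 3, 1)
  shift <- c(-1, 4, 0, 2)
  b <- a * scalefac + shift
  za <- ensemble(list(a), "zscore_mean")
  expect_equal(ensemble(list(a, b), "zscore_mean"), za)
  # zero-variance rows pass through as zeros
  a[2, ] <- 7
  expect_true(all(ensemble(list(a), "zscore_mean")[2, ] == 0))
})

test_that("shift averaging moves content and offset together", {
  # scalar oracle with a single offset-anchored weight: +-1 shifts move the
  # carried base off the stored offset, so only the identity term matches
  w <- oracle_weights(16, offsets = 5L, bases = "G", contributions = 0.9,
                      baseline = 2)
  orc <- oracle_predictor(w)
  s <- "AAAAAGAAAAAAAAAA"
  cfg <- aggregation_config(shift_bp = 1)
  expect_equal(predict_gene(orc, s, 8, cfg), 2 + 0.9 / 3)
  # a bin-content predictor (G count per bin): the TSS offset shifts with
  # the content, so the anchored bin value is shift-invariant
  gcount <- predictor("gc", function(x) {
    ch <- strsplit(x, "")[[1]]
    n_bins <- length(ch) %/% 4
    binned_track(vapply(seq_len(n_bins), function(b)
      sum(ch[(4 * (b - 1) + 1):(4 * b)] == "G"), numeric(1)), 4)
  }, type = "track", bin_size_bp = 4)
  cfg1 <- aggregation_config(shift_bp = 1, tss_window_bins = 1)
  expect_equal(predict_gene(gcount, s, 5, cfg1), 1)
})
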