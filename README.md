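# persexpr

Evaluation framework for **personal-genome gene expression prediction** in
R: given a reference genome, phased SNV genotypes, and a predictor that
scores DNA sequence, how well does the predictor explain expression
variation *between individuals* — as opposed to between genes?

Sequence-to-expression models (Enformer-, Basenji-, ExPecto-, or
Xpresso-style) are typically benchmarked across genes on the reference
genome. `persexpr` implements the complementary evaluation: build each
individual's two haplotype sequences around every gene TSS, run a
predictor with the field's aggregation conventions, and separate

- **reference correlation** — Spearman ρ across genes between
  reference-sequence predictions and median observed expression,
- **cross-gene ρ** — per individual, across genes,
- **cross-individual ρ** — per gene, across individuals (the
  personal-genome metric),

with two calibration instruments alongside:

- a per-gene **elastic-net baseline** (PrediXcan-style) predicting
  expression from cis common-variant dosages (MAF ≥ 0.05 within the
  predictor's receptive field; mixing α = 0.5; nested 10×10
  cross-validation yielding honest out-of-fold predictions) as a lower
  bound on the learnable genetic signal, and
- a **direction-of-effect classifier** for fine-mapped QTL variants
  (PIP > 0.9, sign-consistent across genes): is
  `sign(prediction(alt) − prediction(ref))` equal to the sign of the
  measured effect, with bootstrap uncertainty?

Because paired phased-genome/expression cohorts and trained deep models
cannot ship in a package, `persexpr` includes a seeded synthetic-cohort
generator with known cis-regulatory truth — phased Hardy–Weinberg
genotypes with a common-variant MAF spectrum, sparse causal
architectures, expression at a controlled heritability h², and a
truth-consistent sequence-level **oracle predictor** whose
haplotype-averaged score is `baseline + ½ Σⱼ βⱼ dᵢⱼ`. Corruption knobs
(sign flips, sequence-keyed noise) emulate the failure modes of real
models, so every pipeline stage is testable end to end.

## Worked example

```r
library(persexpr)

res <- run_demo("demo-out", seed = 1)
res$evaluate$eval
#> Evaluation result
#>   reference correlation (across genes): 0.985
#>   cross_individual: mean rho 0.176 (sd 0.479, n=40, undefined=0)
#>   cross_gene: mean rho 0.560 (sd 0.117, n=60, undefined=0)
mean(res$baseline$rho)
#> [1] 0.5320199
res$direction
#> Direction accuracy: 0.641 (109/170 correct, 0 zero-delta excluded)
#>   bootstrap (B=100): mean 0.645, sd 0.0356, 95% CI [0.573, 0.712]
```

This simulates a 60-individual × 40-gene cohort (h² = 0.5, 30% oracle
sign corruption), then runs the full chain. The numbers show the
signature pattern the framework is built to expose: the oracle ranks
genes almost perfectly from the reference sequence (0.985) and does well
across genes within each person (0.56), yet its mean cross-individual ρ
is only 0.18 with a wide spread — sign-corrupted genes land in a
negative tail — while the dosage-based elastic net extracts more
cross-individual signal (0.53) and direction accuracy sits near
1 − corruption rate. Artifacts (fixtures, prediction matrices,
per-gene/per-individual ρ tables, stratification fits, direction JSON,
provenance) are written under `demo-out/`, byte-stable under the seed.

Individual stages are plain functions (`run_simulate`, `run_evaluate`,
`run_baseline`, `run_direction`) over an on-disk fixture directory, and
`inst/cli/persexpr.R` wraps them as `simulate | evaluate | baseline |
direction | demo` subcommands. Real predictors plug in through
`predictor()` (scalar or binned-track contract) and are aggregated with
forward/reverse-complement averaging, ±1-nt shifts, TSS bin windows
(ten 128-bp bins by default), and haplotype averaging; `ensemble()`
averages across models.

## Layout

- `R/` — I/O and validated containers (`genomic_io`), personal-sequence
  construction (`personalize`), predictor contract and aggregation
  (`predictor`), metrics (`evaluation`), elastic-net baseline
  (`elasticnet`), QTL direction classification (`qtl_direction`),
  synthetic cohort (`simulate`), stage orchestration (`pipeline`).
- `vignettes/` — methods vignette: model, conventions, numerical
  choices, and what the synthetic tests do and do not establish.
- `tests/testthat/` — unit, property, and end-to-end suites with
  independent oracles (brute-force rank Pearson, string-edit and
  dual-route sequence oracles, per-fold OLS).
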