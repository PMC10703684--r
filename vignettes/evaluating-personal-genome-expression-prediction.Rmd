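---
title: "Evaluating personal-genome expression prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating personal-genome expression prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persexpr)
```

## The question this package operationalizes

Sequence-to-expression models score a DNA window around a gene's
transcription start site (TSS) and output a predicted expression level.
Such models are usually benchmarked *across genes*: different reference
windows, one prediction each, correlated with measured expression. That
benchmark says little about the harder question that matters for personal
genomics — whether substituting one person's variants into the window
moves the prediction in the right direction and by a meaningful amount
*across individuals*.

`persexpr` separates those two questions into three rank-correlation
metrics computed from a genes × individuals prediction matrix and a
matched observation matrix:

* **reference correlation** — Spearman correlation, across genes, of the
  reference-sequence prediction with the per-gene median observed
  expression;
* **cross-gene correlation** — for each individual, Spearman correlation
  across genes of that individual's predictions with their observations;
* **cross-individual correlation** — for each gene, Spearman correlation
  across individuals. This is the personal-genome metric; everything else
  in the package exists to contextualize it.

Two reference points accompany the metrics. A per-gene **elastic-net
baseline** regresses expression on cis common-variant dosages with nested
cross-validation; it cannot generalize to new sequences, but it bounds
from below the genetic signal available to any predictor for that gene.
A **direction-of-effect classifier** asks, for fine-mapped QTL variants,
whether the predicted ref→alt delta has the sign of the measured effect.

## Personal sequence construction

Inputs are a reference genome (FASTA), phased biallelic SNVs (VCF with
`GT`), and a TSS/strand annotation table. Indels and multiallelic rows
are skipped on load; unphased or missing genotypes and REF mismatches are
hard errors, because silently imputing either would contaminate the
evaluation itself.

Coordinates are handled with one rule: external formats are 1-based
inclusive, all internal arithmetic is 0-based half-open, converted once
at parse time. A window spec gives upstream/downstream extents in bp;
with 0-based TSS `t`, plus-strand (and all non-strand-aware) windows are
`[t - up, t + down)` with the TSS base opening the downstream segment.
For strand-aware specs on minus-strand genes the genomic interval is
mirrored to `[t - down, t + up)` and the edited sequence is
reverse-complemented, so emitted sequences are always 5'→3' in gene
orientation. Under that mirroring the TSS base sits at emitted offset
`up - 1` rather than `up` — a one-base asymmetry inherent to half-open
mirroring. We keep the mirrored interval as the primary convention and
treat the TSS anchor as accurate to one base; at the 128-bp bin sizes of
CAGE-style models the anchor stays in the same bin, and the test suite
pins the exact byte-level behavior through a dual-route oracle (edit
forward then reverse-complement, versus complement the alleles and edit
the reverse-complemented window directly).

Each (gene, individual) pair yields two sequences, one per haplotype.
Variants at window boundaries are included iff their 0-based position
falls in the half-open interval. Windows that would cross a contig edge
are errors at the operation level; the simulator places genes so this
cannot happen.

## Aggregation rules

Track predictors emit values in fixed-width bins (default 128 bp). A
gene-level scalar is produced by reducing a `W`-bin window around the TSS
bin `t = floor(offset / bin_size)`; we center the window on `t` with the
extra bin downstream for even `W`, so the conventional `W = 10` reduces
bins `t-4 … t+5`. The reduction is a mean by default ("average the
predicted signal"), with `sum` available for the accessibility use case.
Optionally, predictions are averaged over the reverse-complement sequence
(with the TSS offset mirrored to `L - 1 - offset`) and over ±1-nt content
shifts. Shifts move the TSS offset together with the content so the
biological anchor is preserved; the vacated edge base is filled from the
reference flank when provided, else `N`. Haplotype predictions are always
averaged. Because every aggregation step is a mean, the order of
averaging (haplotypes first or sequence variants first) is immaterial.

Cross-model ensembling offers `raw_mean` (elementwise) and `zscore_mean`
(per-gene standardization of each model's matrix first, zero-variance
rows passing through as zeros). `raw_mean` is the default: rank metrics
are computed per matrix anyway, and raw averaging is what "averaging
predictions across models" means when the models share an output scale.

## The synthetic cohort and its oracle

Real cohorts with paired phased genomes and expression cannot ship with a
package, and trained deep models are far outside desk scale. The
simulator therefore generates the *study conditions* rather than a
caricature of any dataset:

* reference contigs of i.i.d. uniform A/C/G/T;
* SNVs at uniform positions, population MAF drawn uniformly on
  `[0.05, 0.5]` (the common-variant spectrum eQTL analyses condition on),
  haplotype alleles i.i.d. Bernoulli(MAF) — Hardy–Weinberg, no LD. An
  optional mosaic mode copies haplotype blocks from a founder pool to
  induce LD for tagging-variant experiments; it is off by default so that
  sign-recovery tests identify causal variants unambiguously;
* per gene, a sparse causal architecture: 5 cis variants by default
  (sparse architectures of a handful of causal variants are the norm for
  cis-eQTLs), effects `beta ~ N(0, 1)`;
* expression `y = g + e` with `g` the additive dosage score and noise
  variance set from the realized `Var(g)` to hit a target heritability
  `h2` (default 0.5); `h2 = 0` yields pure noise. Expression is shifted
  per gene to be non-negative — an affine shift, so every rank relation
  is preserved exactly. No count-noise model is layered on top: all
  downstream metrics are rank-based, so a negative-binomial observation
  model would change nothing the package measures.

The **oracle predictor** is the linchpin: a sequence-level scoring rule
built from the simulation truth. Each causal variant contributes its
effect when the alt base is present at its window offset (complemented
and mirrored for minus-strand genes), so the haplotype-averaged score is
`baseline + ½ Σ beta_j d_ij` — monotone in the true genetic value. The
½ is left in place; Spearman metrics are scale-free. Two corruption
knobs emulate model pathologies: `sign_corruption_rate` flips the sign
of a seeded subset of weights (a model that detects a variant but
mistakes its direction — the failure mode of central interest), and
`noise_sd` adds sequence-keyed noise. The noise is a deterministic
function of a hash of the sequence, not a fresh random draw, so
predictors remain pure functions and all runs are bit-reproducible.

Two numerical choices make "exact" mean exact. Effect sizes are rounded
to multiples of 2⁻²⁶ (dyadic rationals), so additive scores are sums of
exactly representable doubles: individuals with identical genotype
configurations get bitwise-identical scores regardless of summation
order, rank ties are well-defined, and the sequence route agrees with
the genotype-space computation to error 0, not merely 1e-9. Truth JSON
is written with 17 significant digits so effects survive serialization
bitwise. Second, Spearman returns literal ±1 for identical or exactly
reversed rankings rather than the 1-minus-epsilon of product-moment
arithmetic.

## Heritability and what the oracle tests can show

If predictions are monotone in `g` and `y = g + e` with
`cor(g, y) = sqrt(h2)`, bivariate-normal theory gives a population
Spearman of `(6/π) asin(sqrt(h2)/2)`. The simulated `g` (a weighted sum
of a few binomial dosages) is only approximately normal, so we treat the
formula as a ±0.05 band rather than a point target; with 5 causal
variants the deviation is under 0.01 at every `h2` tested. This property
anchors what a *correct* predictor should score on this cohort — e.g.
about 0.30 at `h2 = 0.1` and 0.94 at `h2 = 0.9` — which is what makes a
near-zero observed cross-individual mean interpretable as model failure
rather than noise.

What passing these tests does **not** show: performance on real genomes.
The simulator has no LD (by default), no distal regulation, no
epistasis, no expression normalization artifacts, and its oracle knows
the causal map. The framework validates the *measurement machinery* —
sequence construction, aggregation, metrics, baselines — so that when a
real predictor is plugged in via the `predictor()` contract, the numbers
mean what they claim.

## The elastic-net baseline

Per gene, dosages of common variants (cohort MAF ≥ 0.05) within a
window matched to the predictor's receptive field enter an elastic net
with mixing `alpha = 0.5`, i.e. penalty
`lambda (0.5‖b‖₁ + 0.25‖b‖₂²)`. The published description specifies
tenfold penalty selection and ten holdout splits without stating their
nesting; we implement full nested CV — an inner 10-fold selection inside
each outer training set, refit, then prediction on the held-out fold —
because anything looser lets the penalty choice peek at evaluation
individuals. The penalty grid is 50 log-spaced values descending four
orders from the per-training-set `lambda_max`; dosages are standardized
with training-fold statistics only (whether the original analysis
standardized is unstated; we record this as an assumption). Out-of-fold
predictions cover each individual exactly once, and a permutation probe
(shuffling a held-out fold's expression must not change that fold's
predictions) is part of the test suite.

## Direction-of-effect classification

Fine-mapped records are filtered to posterior inclusion probability
strictly above 0.9, then any variant with opposite-signed effects on
different genes is dropped entirely. Deltas are computed on the
*reference background* — only the focal variant toggled — matching the
single-variant in-silico substitution style of published eQTL
benchmarks. eQTL-mode deltas reduce with the gene-level TSS-window
config (the exact window used in the original analyses is not fully
specified; the TSS window is our recorded default). caQTL-mode deltas
sum the three bins whose centers (0-based, center at
`bin_start + (bin_size - 1)/2`) lie nearest the variant, ties to the
smaller bin index. A zero delta has no sign: it is excluded and counted,
not scored as wrong (or right). Accuracy is bootstrapped (100 resamples
of variants, seeded) with mean, s.d., and a 2.5/97.5 percentile
interval.

## The marginal eQTL scan

For stratification and eGene selection the simulator includes a
per-variant simple regression scan. The per-gene record is the
minimum-p variant (ties: smaller |TSS distance|, then variant id). The
gene-level p-value Šidák-corrects that minimum for the number of cis
variants tested — exact under the independent-variant default, and the
desk-scale analogue of the permutation-adjusted gene-level p-values real
eQTL pipelines use — and Benjamini–Hochberg across genes at FDR 0.05
defines the eGene set. Without the within-gene correction the minimum-p
statistics are not uniform under the null and BH would manufacture
eGenes from noise; with it, the null eGene count stays within the FDR
budget, which the test suite checks over 100 seeded replicates.

Stratification covariates per gene: −log10 of the top-eQTL p-value (the
transform is our choice; it is the conventional axis), absolute TSS
distance, median observed expression, and the coefficient of variation
(sd/mean) of predicted expression across individuals. Pearson
correlations and OLS fits are reported for all genes and for the
positive- and negative-correlation subsets.

## Sizes, defaults, and reproducibility

The demo configuration — 60 individuals, 40 genes, 1.5 kb/1 kb
strand-aware windows, variant density 0.012/bp, `h2 = 0.5`, 30% sign
corruption, mild predictor noise — is sized so the full
simulate → evaluate → baseline → direction chain completes in about a
minute on one CPU while exhibiting the phenomena of interest: a
reference correlation near 1, cross-gene correlations far above the
cross-individual mean, a wide cross-individual spread with positive and
negative tails, a dosage baseline beating the corrupted oracle, and
direction accuracy near 1 minus the corruption rate. Property tests use
larger cohorts (up to 400 individuals × 200 genes) where a
distributional claim needs them.

Every run is driven by one integer seed fanned out to per-stage
sub-seeds via a labeled hash (`derive_seed`), so stages are
independently reproducible and fixture sets are byte-stable: the same
seed reproduces identical FASTA/VCF/TSV/JSON files, hash for hash. All
evaluation gene sets, undefined-correlation exclusions, and skipped-gene
counts are reported rather than silently absorbed.

## Known limitations

* SNVs only; indels and structural variants are out of scope throughout.
* No LD by default means the baseline's task is easier than on real
  cohorts, where tagging inflates apparent cis signal; mosaic mode
  exists for that regime but no coalescent realism is attempted.
* The oracle's corruption model is independent per variant; real models
  err in correlated, motif-dependent ways.
* The elastic net assumes additive effects, as does the simulation, so
  the baseline's dominance over a sign-corrupted oracle is a property of
  matched additive worlds, not a claim about real nonlinear biology.
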