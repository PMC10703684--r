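# Construction of per-haplotype personal input sequences around gene TSSs.
#
# Coordinate conventions, stated once: external tables (VCF, annotation) are
# 1-based inclusive; all internal interval arithmetic is 0-based half-open,
# converted exactly once at parse time. The 0-based TSS base is the first
# base of the downstream segment, so a window is an upstream segment of
# length `upstream_bp` followed by a downstream segment of length
# `downstream_bp` starting at the TSS base.

#' Specify a TSS-anchored input window
#'
#' @param upstream_bp,downstream_bp Non-negative window extents in bp;
#'   their sum must be positive.
#' @param strand_aware If `TRUE`, upstream/downstream are interpreted in
#'   gene orientation and negative-strand windows are mirrored then
#'   reverse-complemented; if `FALSE` the genome-orientation `+` rule is
#'   used for every gene. Non-strand-aware specs must be symmetric.
#' @return An object of class `WindowSpec`.
#' @export
window_spec <- function(upstream_bp, downstream_bp, strand_aware = FALSE) {
  upstream_bp <- as.integer(upstream_bp)
  downstream_bp <- as.integer(downstream_bp)
  stopifnot(upstream_bp >= 0, downstream_bp >= 0,
            upstream_bp + downstream_bp > 0,
            is.logical(strand_aware), length(strand_aware) == 1)
  if (!strand_aware && upstream_bp != downstream_bp)
    stop("non-strand-aware window specs must be symmetric")
  structure(list(upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                 strand_aware = strand_aware),
            class = "WindowSpec")
}

#' Window presets matching four published sequence-to-expression models
#'
#' Receptive fields: enformer 98.3 kb up/downstream, basenji2 27.5 kb,
#' expecto 20 kb (all symmetric about the TSS), and xpresso 7 kb upstream /
#' 3.5 kb downstream in gene orientation (strand-aware).
#'
#' @return Named list of [window_spec()] objects.
#' @export
window_presets <- function() {
  list(enformer = window_spec(98300, 98300),
       basenji2 = window_spec(27500, 27500),
       expecto  = window_spec(20000, 20000),
       xpresso  = window_spec(7000, 3500, strand_aware = TRUE))
}

#' Resolve a gene's input window to a genomic interval
#'
#' For strand-aware specs on `+` genes (and all non-strand-aware specs)
#' the interval is `[tss0 - upstream, tss0 + downstream)`; on `-` genes it
#' is mirrored to `[tss0 - downstream, tss0 + upstream)`, where `tss0` is
#' the 0-based TSS coordinate.
#'
#' @param gene Single-row gene annotation (fields `chrom`, `tss`, `strand`).
#' @param spec A [window_spec()].
#' @param genome Optional `ReferenceGenome`; when supplied the interval is
#'   checked against contig bounds and an out-of-bounds window is an error
#'   (never silently truncated).
#' @return List with `chrom`, `start` (0-based inclusive), `end` (exclusive).
#' @export
resolve_window <- function(gene, spec, genome = NULL) {
  stopifnot(inherits(spec, "WindowSpec"))
  tss0 <- as.integer(gene$tss) - 1L
  mirrored <- spec$strand_aware && gene$strand == "-"
  if (mirrored) {
    start <- tss0 - spec$downstream_bp
    end <- tss0 + spec$upstream_bp
  } else {
    start <- tss0 - spec$upstream_bp
    end <- tss0 + spec$downstream_bp
  }
  if (!is.null(genome)) {
    len <- nchar(get_contig(genome, gene$chrom))
    if (start < 0 || end > len)
      stop(sprintf("window [%d, %d) for gene %s exceeds contig %s bounds [0, %d)",
                   start, end, gene$gene_id, gene$chrom, len))
  } else if (start < 0) {
    stop(sprintf("window start %d < 0 for gene %s", start, gene$gene_id))
  }
  list(chrom = as.character(gene$chrom), start = start, end = end)
}

#' Reverse-complement a nucleotide sequence
#'
#' Standard Watson-Crick complement of an A/C/G/T/N string, reversed;
#' N maps to N. Any other character is an error.
#'
#' @param seq Single nucleotide string.
#' @return The reverse complement.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN characters")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

complement_base <- function(base) {
  chartr("ACGTN", "TGCAN", base)
}

#' Apply one haplotype's alleles to a reference window
#'
#' Every cohort variant falling inside the interval (half-open, 0-based)
#' whose allele indicator is 1 on the requested haplotype has its alt base
#' substituted at the corresponding window offset. Substitutions are
#' independent single-base edits (SNV-only), so order is immaterial. A
#' variant whose REF allele disagrees with the window base is an error.
#'
#' @param ref_window Reference slice of `interval` in genome orientation.
#' @param interval List with `chrom`, `start`, `end` as from
#'   [resolve_window()].
#' @param cohort A `PhasedCohort`.
#' @param individual_id Individual to personalize for.
#' @param haplotype 0 or 1.
#' @return List with `sequence` (edited window, genome orientation) and
#'   `n_applied` (number of substitutions made).
#' @export
apply_haplotype <- function(ref_window, interval, cohort, individual_id,
                            haplotype) {
  stopifnot(inherits(cohort, "PhasedCohort"), haplotype %in% c(0L, 1L))
  if (nchar(ref_window) != interval$end - interval$start)
    stop("ref_window length does not match interval")
  col <- match(individual_id, cohort$individuals)
  if (is.na(col)) stop("unknown individual: ", individual_id)
  v <- cohort$variants
  pos0 <- v$pos - 1L
  in_win <- v$chrom == interval$chrom &
    pos0 >= interval$start & pos0 < interval$end
  alleles <- if (haplotype == 0L) cohort$hap0[, col] else cohort$hap1[, col]
  idx <- which(in_win & alleles == 1L)
  # validate REF for every in-window variant, applied or not: a mismatch
  # means corrupt inputs regardless of this haplotype's allele
  for (k in which(in_win)) {
    off <- pos0[k] - interval$start + 1L
    have <- substr(ref_window, off, off)
    if (have == "N")
      stop(sprintf("window base is N at variant %s (%s:%d)",
                   v$variant_id[k], v$chrom[k], v$pos[k]))
    if (have != v$ref[k])
      stop(sprintf("variant %s REF %s disagrees with window base %s at %s:%d",
                   v$variant_id[k], v$ref[k], have, v$chrom[k], v$pos[k]))
  }
  seq <- ref_window
  for (k in idx) {
    off <- pos0[k] - interval$start + 1L
    substr(seq, off, off) <- v$alt[k]
  }
  list(sequence = seq, n_applied = length(idx))
}

#' Build personal sequences for all (gene, individual, haplotype) triples
#'
#' For each gene and individual, emits two records (haplotypes 0 and 1).
#' For strand-aware specs, negative-strand windows are mirrored, variants
#' applied in genome orientation, and the result reverse-complemented, so
#' emitted sequences are always 5'->3' in gene orientation; non-strand-aware
#' specs emit genome orientation.
#'
#' @param genome `ReferenceGenome`.
#' @param genes `GeneAnnotation` table.
#' @param cohort `PhasedCohort`.
#' @param spec [window_spec()].
#' @return data.frame with columns `gene_id`, `individual_id`, `haplotype`,
#'   `sequence`, `n_variants_applied`.
#' @export
build_personal_sequences <- function(genome, genes, cohort, spec) {
  stopifnot(inherits(genome, "ReferenceGenome"), inherits(spec, "WindowSpec"))
  out <- vector("list", nrow(genes) * length(cohort$individuals) * 2L)
  i <- 0L
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    itv <- resolve_window(gene, spec, genome)
    refwin <- substr(get_contig(genome, itv$chrom), itv$start + 1L, itv$end)
    rc <- spec$strand_aware && gene$strand == "-"
    for (ind in cohort$individuals) {
      for (h in c(0L, 1L)) {
        ap <- apply_haplotype(refwin, itv, cohort, ind, h)
        s <- if (rc) reverse_complement(ap$sequence) else ap$sequence
        i <- i + 1L
        out[[i]] <- data.frame(gene_id = gene$gene_id, individual_id = ind,
                               haplotype = h, sequence = s,
                               n_variants_applied = ap$n_applied,
                               stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Reference window sequence for a gene, in emitted orientation
#'
#' The same window [build_personal_sequences()] uses, with no variants
#' applied (reverse-complemented for negative-strand genes under
#' strand-aware specs).
#'
#' @inheritParams build_personal_sequences
#' @param gene Single-row gene annotation.
#' @return Single sequence string.
#' @export
reference_window_sequence <- function(genome, gene, spec) {
  itv <- resolve_window(gene, spec, genome)
  refwin <- substr(get_contig(genome, itv$chrom), itv$start + 1L, itv$end)
  if (spec$strand_aware && gene$strand == "-") reverse_complement(refwin)
  else refwin
}

#' TSS offset within the emitted window
#'
#' 0-based offset of the TSS base in the sequence emitted for a gene under
#' a spec. Equal to `upstream_bp` for `+` genes and for all strand-aware
#' emitted sequences (which are in gene orientation); for `-` genes under a
#' non-strand-aware (symmetric) spec the offset is also `upstream_bp` since
#' the window is symmetric.
#'
#' @param spec [window_spec()].
#' @return Integer offset.
#' @export
tss_offset <- function(spec) {
  spec$upstream_bp
}

#' Export personal sequences as FASTA
#'
#' One record per (gene, individual, haplotype), named
#' `gene|individual|hapK`.
#'
#' @param sequences data.frame from [build_personal_sequences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_personal_fasta <- function(sequences, path) {
  nm <- sprintf("%s|%s|hap%d", sequences$gene_id, sequences$individual_id,
                sequences$haplotype)
  ss <- Biostrings::DNAStringSet(stats::setNames(sequences$sequence, nm))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
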