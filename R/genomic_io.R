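# Readers/writers for the formats the pipeline touches (FASTA, VCF, TSV
# tables) and the validated in-memory containers they produce.

VALID_BASES <- c("A", "C", "G", "T")

#' Construct a reference genome container
#'
#' A reference genome is a named set of contig sequences. Sequences are
#' uppercased on construction and restricted to the alphabet A/C/G/T/N.
#'
#' @param contigs Named character vector, one uppercase nucleotide sequence
#'   per contig. Names are contig (chromosome) identifiers.
#' @return An object of class `ReferenceGenome`.
#' @export
reference_genome <- function(contigs) {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("every contig must be named")
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig name: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  contigs <- toupper(contigs)
  if (any(!nzchar(contigs)))
    stop("empty sequence for contig: ",
         paste(names(contigs)[!nzchar(contigs)], collapse = ", "))
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("non-ACGTN characters in contig: ",
         paste(names(contigs)[bad], collapse = ", "))
  storage.mode(contigs) <- "character"
  structure(contigs, class = "ReferenceGenome")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome with", length(x), "contig(s):\n")
  for (nm in names(x))
    cat(sprintf("  %s  (%d bp)\n", nm, nchar(x[[nm]])))
  invisible(x)
}

#' Look up a contig sequence by name
#'
#' @param genome A `ReferenceGenome`.
#' @param chrom Contig name. An unknown name is an error, never an empty
#'   string.
#' @return The contig sequence (single string).
#' @export
get_contig <- function(genome, chrom) {
  stopifnot(inherits(genome, "ReferenceGenome"), length(chrom) == 1L)
  if (!chrom %in% names(genome))
    stop("unknown contig: ", chrom)
  unclass(genome)[[chrom]]
}

#' Read a FASTA file into a reference genome
#'
#' Multi-line records are concatenated, sequences are uppercased, and the
#' header token before the first whitespace becomes the contig name.
#'
#' @param path Path to a FASTA file.
#' @return A [reference_genome()] object with contigs in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  reference_genome(stats::setNames(as.character(ss), nm))
}

#' Write a reference genome to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param genome A `ReferenceGenome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Construct a phased cohort container
#'
#' Holds biallelic SNV records plus per-individual phased haplotype alleles.
#' Variants are sorted by (chrom, pos); duplicate positions on a chromosome
#' are rejected. Allele matrices are variants x individuals, coded 0 (ref)
#' or 1 (alt).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `variant_id`, `ref`, `alt` (single bases, ref != alt).
#' @param individuals Character vector of individual identifiers.
#' @param hap0,hap1 Integer matrices (variants x individuals) of allele
#'   indicators for the first and second haplotype.
#' @return An object of class `PhasedCohort`.
#' @export
phased_cohort <- function(variants, individuals, hap0, hap1) {
  req <- c("chrom", "pos", "variant_id", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  n_var <- nrow(variants)
  if (anyDuplicated(individuals)) stop("duplicate individual ids")
  stopifnot(is.matrix(hap0), is.matrix(hap1),
            nrow(hap0) == n_var, nrow(hap1) == n_var,
            ncol(hap0) == length(individuals),
            ncol(hap1) == length(individuals))
  if (n_var > 0) {
    if (!all(variants$ref %in% VALID_BASES) || !all(variants$alt %in% VALID_BASES))
      stop("alleles must be single bases in A/C/G/T")
    if (any(variants$ref == variants$alt))
      stop("ref and alt alleles must differ")
    ord <- order(variants$chrom, variants$pos)
    variants <- variants[ord, , drop = FALSE]
    hap0 <- hap0[ord, , drop = FALSE]
    hap1 <- hap1[ord, , drop = FALSE]
    if (anyDuplicated(variants[, c("chrom", "pos")]))
      stop("duplicate (chrom, pos) variant records")
    if (!all(hap0 %in% c(0L, 1L)) || !all(hap1 %in% c(0L, 1L)))
      stop("haplotype alleles must be 0 or 1")
  }
  rownames(variants) <- NULL
  structure(list(variants = variants,
                 individuals = as.character(individuals),
                 hap0 = hap0, hap1 = hap1),
            class = "PhasedCohort")
}

#' @export
print.PhasedCohort <- function(x, ...) {
  cat(sprintf("PhasedCohort: %d variant(s) x %d individual(s)\n",
              nrow(x$variants), length(x$individuals)))
  invisible(x)
}

#' Alt-allele dosages for all variants
#'
#' @param cohort A `PhasedCohort`.
#' @return Integer matrix (variants x individuals) of 0/1/2 dosages, the sum
#'   of the two haplotype allele indicators.
#' @export
cohort_dosages <- function(cohort) {
  stopifnot(inherits(cohort, "PhasedCohort"))
  d <- cohort$hap0 + cohort$hap1
  dimnames(d) <- list(cohort$variants$variant_id, cohort$individuals)
  d
}

#' Read phased genotypes from a VCF file
#'
#' Only biallelic SNV records are retained: rows with multi-base REF or ALT
#' (indels) or comma-separated ALT (multiallelic) are skipped and counted.
#' Every retained genotype must be a phased pair `a|b`; an unphased (`/`) or
#' missing (`.`) call is a hard error naming the individual and site, as is
#' a REF allele that disagrees with the reference genome.
#'
#' @param path Path to an uncompressed VCF v4.x file with a GT FORMAT field.
#' @param genome `ReferenceGenome` used to validate REF alleles.
#' @return A [phased_cohort()]; the number of skipped non-SNV records is
#'   attached as attribute `n_skipped`.
#' @export
read_phased_vcf <- function(path, genome) {
  stopifnot(file.exists(path), inherits(genome, "ReferenceGenome"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  individuals <- colnames(gt)
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  is_snv <- !is.na(alt) & ref %in% VALID_BASES & alt %in% VALID_BASES
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0)
    message(n_skipped, " non-SNV (indel/multiallelic) record(s) skipped")
  fix <- fix[is_snv, , drop = FALSE]
  gt <- gt[is_snv, , drop = FALSE]
  ref <- ref[is_snv]; alt <- alt[is_snv]
  pos <- as.integer(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(chrom, ":", pos)[is.na(ids) | ids == "."]

  bad <- is.na(gt) | !grepl("^[01]\\|[01]$", gt)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unphased or missing genotype '%s' for individual %s at %s:%d",
                 gt[w[1], w[2]], individuals[w[2]], chrom[w[1]], pos[w[1]]))
  }
  # REF must match the reference base at pos
  for (k in seq_along(pos)) {
    base <- substr(get_contig(genome, chrom[k]), pos[k], pos[k])
    if (base != ref[k])
      stop(sprintf("REF mismatch at %s:%d: VCF has %s, genome has %s",
                   chrom[k], pos[k], ref[k], base))
  }
  h0 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt),
               dimnames = dimnames(gt))
  h1 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt),
               dimnames = dimnames(gt))
  out <- phased_cohort(
    data.frame(chrom = chrom, pos = pos, variant_id = ids,
               ref = ref, alt = alt, stringsAsFactors = FALSE),
    individuals, h0, h1)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a phased cohort to a VCF v4.2 text file
#'
#' @param cohort A `PhasedCohort`.
#' @param path Output path.
#' @param genome Optional `ReferenceGenome`; when given, `##contig` header
#'   lines with lengths are emitted.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path, genome = NULL) {
  stopifnot(inherits(cohort, "PhasedCohort"))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome), nchar(unclass(genome))))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", cohort$individuals),
                      collapse = "\t"))
  v <- cohort$variants
  gt <- matrix(paste0(cohort$hap0, "|", cohort$hap1), nrow = nrow(v))
  body <- if (nrow(v) > 0) {
    apply(cbind(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", gt), 1, paste, collapse = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a typed TSV table
#'
#' Three schemas are supported:
#' \describe{
#'   \item{gene_annotation}{columns `gene_id`, `chrom`, `tss`, `strand`;
#'     returns a validated data.frame of gene annotations.}
#'   \item{expression}{column `gene_id` plus one numeric column per
#'     individual; returns a genes x individuals matrix.}
#'   \item{qtl}{columns `gene_id`, `variant_id`, `chrom`, `pos`, `ref`,
#'     `alt`, `beta`, `pvalue`, `pip`, `maf`; returns a data.frame.}
#' }
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema One of `"gene_annotation"`, `"expression"`, `"qtl"`.
#' @return A validated table; see Details.
#' @export
read_table <- function(path, schema = c("gene_annotation", "expression", "qtl")) {
  schema <- match.arg(schema)
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  switch(schema,
    gene_annotation = {
      need_cols(df, c("gene_id", "chrom", "tss", "strand"), path)
      if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in ", path)
      df$tss <- check_numeric(df$tss, "tss", path)
      if (any(df$tss < 1)) stop("tss must be >= 1")
      if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
      gene_annotation(df$gene_id, df$chrom, df$tss, df$strand)
    },
    expression = {
      need_cols(df, "gene_id", path)
      if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in ", path)
      m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
      if (!is.numeric(m)) stop("non-numeric expression values in ", path)
      if (anyNA(m)) {
        w <- which(is.na(m), arr.ind = TRUE)[1, ]
        stop(sprintf("missing expression value for gene %s, individual %s",
                     df$gene_id[w[1]], colnames(m)[w[2]]))
      }
      rownames(m) <- df$gene_id
      expression_matrix(m)
    },
    qtl = {
      need_cols(df, c("gene_id", "variant_id", "chrom", "pos", "ref", "alt",
                      "beta", "pvalue", "pip", "maf"), path)
      for (cc in c("pos", "beta", "pvalue", "pip", "maf"))
        df[[cc]] <- check_numeric(df[[cc]], cc, path, na_ok = TRUE)
      df
    })
}

need_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
}

check_numeric <- function(x, name, path, na_ok = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(na_ok & (is.na(x) | x == "NA"))
  if (any(bad))
    stop(sprintf("unparsable numeric cell in column '%s' of %s: '%s'",
                 name, path, x[which(bad)[1]]))
  out
}

#' Construct a gene annotation table
#'
#' @param gene_id,chrom,tss,strand Parallel vectors: gene identifier,
#'   chromosome, 1-based TSS coordinate, strand (`"+"` or `"-"`).
#' @return A data.frame of class `GeneAnnotation`.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand) {
  stopifnot(length(gene_id) == length(chrom),
            length(gene_id) == length(tss),
            length(gene_id) == length(strand))
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tss <- as.integer(tss)
  if (any(tss < 1)) stop("tss must be >= 1")
  structure(data.frame(gene_id = as.character(gene_id),
                       chrom = as.character(chrom),
                       tss = tss, strand = as.character(strand),
                       stringsAsFactors = FALSE),
            class = c("GeneAnnotation", "data.frame"))
}

#' Construct an expression matrix
#'
#' @param values Numeric genes x individuals matrix with gene ids as row
#'   names and individual ids as column names; no missing entries, all
#'   values non-negative. Only ranks are consumed downstream, so the
#'   expression unit is arbitrary.
#' @return The matrix with class `ExpressionMatrix` prepended.
#' @export
expression_matrix <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and individual column names")
  if (anyNA(values)) stop("expression matrix has missing entries")
  if (any(values < 0)) stop("expression values must be non-negative")
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' Write an expression or prediction matrix as TSV
#'
#' @param m Genes x individuals matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix with a cohort's individuals
#'
#' Individuals present in only one of the two inputs are dropped with a
#' warning; the returned pair uses the intersection, with expression columns
#' reordered to cohort order.
#'
#' @param expr `ExpressionMatrix`.
#' @param cohort `PhasedCohort`.
#' @return List with elements `expression` (columns in cohort order) and
#'   `cohort` (subset to shared individuals).
#' @export
align_expression <- function(expr, cohort) {
  stopifnot(inherits(cohort, "PhasedCohort"))
  shared <- intersect(cohort$individuals, colnames(expr))
  if (length(shared) == 0) stop("no shared individuals")
  dropped <- setdiff(union(cohort$individuals, colnames(expr)), shared)
  if (length(dropped))
    warning(length(dropped), " individual(s) outside the intersection dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  keep <- match(shared, cohort$individuals)
  sub <- phased_cohort(cohort$variants, shared,
                       cohort$hap0[, keep, drop = FALSE],
                       cohort$hap1[, keep, drop = FALSE])
  em <- expr[, shared, drop = FALSE]
  class(em) <- c("ExpressionMatrix", "matrix", "array")
  list(expression = em, cohort = sub)
}
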