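# Core containers: genotype matrices and temporal sample pairs.

#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds biallelic SNP genotypes for a set of samples as
#' alternate-allele dosages (0, 1, 2, or `NA` for missing), together with the
#' per-locus chromosome label and 1-based physical position. Loci are kept
#' sorted by (chromosome, position).
#'
#' @param geno Integer/numeric matrix, samples x loci, values in
#'   \{0, 1, 2, NA\}.
#' @param chrom Character vector of per-locus chromosome labels.
#' @param pos Integer vector of per-locus 1-based positions.
#' @param sample_ids Optional character vector of sample identifiers.
#' @param population Optional per-sample population label.
#' @param locus_ids Optional per-locus identifiers (e.g. HapMap rs#).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, chrom, pos, sample_ids = NULL,
                            population = NULL, locus_ids = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_loci <- ncol(geno)
  if (length(chrom) != n_loci || length(pos) != n_loci) {
    stop("chrom/pos length must equal the number of loci (columns)")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(geno)))
  if (is.null(locus_ids)) locus_ids <- sprintf("L%05d", seq_len(n_loci))
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ord <- order(chrom, pos)
  gm <- structure(
    list(geno = geno[, ord, drop = FALSE],
         chrom = chrom[ord], pos = pos[ord],
         sample_ids = as.character(sample_ids),
         population = population,
         locus_ids = as.character(locus_ids)[ord]),
    class = "genotype_matrix")
  dup <- duplicated(paste(gm$chrom, gm$pos))
  if (any(dup)) stop("positions must be unique within a chromosome")
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d loci on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$chrom))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing: %.2f%%  mean het: %.2f%%\n",
              100 * miss, 100 * mean(x$geno == 1L, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

n_loci <- function(gm) ncol(gm$geno)
n_samples <- function(gm) nrow(gm$geno)

# subset loci by index, keeping metadata in step
subset_loci <- function(gm, idx) {
  genotype_matrix(gm$geno[, idx, drop = FALSE], gm$chrom[idx], gm$pos[idx],
                  sample_ids = gm$sample_ids, population = gm$population,
                  locus_ids = gm$locus_ids[idx])
}

# stack two matrices on identical loci (sample-wise)
rbind_genotypes <- function(a, b) {
  stopifnot(identical(a$chrom, b$chrom), identical(a$pos, b$pos))
  genotype_matrix(rbind(a$geno, b$geno), a$chrom, a$pos,
                  sample_ids = c(a$sample_ids, b$sample_ids),
                  population = c(rep_population(a), rep_population(b)),
                  locus_ids = a$locus_ids)
}

rep_population <- function(gm) {
  if (is.null(gm$population)) rep(NA_character_, n_samples(gm)) else gm$population
}

#' Pair two temporal samples of the same population
#'
#' @param sample_t0,sample_tau `genotype_matrix` objects on identical loci
#'   (the first and second collect).
#' @param tau Number of generations separating the two samples.
#' @param truth Optional list describing simulated ground truth (selected
#'   locus indices, allele-frequency trajectories).
#'
#' @return An object of class `temporal_pair`.
#' @export
temporal_pair <- function(sample_t0, sample_tau, tau, truth = NULL) {
  stopifnot(inherits(sample_t0, "genotype_matrix"),
            inherits(sample_tau, "genotype_matrix"))
  if (!identical(sample_t0$chrom, sample_tau$chrom) ||
      !identical(sample_t0$pos, sample_tau$pos)) {
    stop("the two samples must share an identical locus list")
  }
  tau <- as.integer(tau)
  if (tau < 1L) stop("tau must be >= 1 generation")
  structure(list(sample_t0 = sample_t0, sample_tau = sample_tau,
                 tau = tau, truth = truth),
            class = "temporal_pair")
}

#' @export
print.temporal_pair <- function(x, ...) {
  cat(sprintf("<temporal_pair> tau = %d generations, %d loci\n",
              x$tau, n_loci(x$sample_t0)))
  cat(sprintf("  t0: %d samples   t%d: %d samples\n",
              n_samples(x$sample_t0), x$tau, n_samples(x$sample_tau)))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: %d selected loci\n", length(x$truth$selected)))
  }
  invisible(x)
}

# per-locus genotype class counts (n0, n1, n2 = dosage 0/1/2 carriers)
genotype_class_counts <- function(gm) {
  g <- gm$geno
  cbind(n0 = colSums(g == 0L, na.rm = TRUE),
        n1 = colSums(g == 1L, na.rm = TRUE),
        n2 = colSums(g == 2L, na.rm = TRUE))
}

# per-locus alternate allele frequency (missing excluded)
allele_freq <- function(gm) {
  colMeans(gm$geno, na.rm = TRUE) / 2
}

#' IRGSP-1.0 rice chromosome lengths
#'
#' Lengths in bp of the 12 chromosomes of the Os-Nipponbare-Reference-IRGSP-1.0
#' assembly, used as the default when clipping extended candidate intervals.
#'
#' @return Named integer vector (chr01..chr12) of chromosome lengths.
#' @export
irgsp1_chrom_lengths <- function() {
  c(chr01 = 43270923L, chr02 = 35937250L, chr03 = 36413819L,
    chr04 = 35502694L, chr05 = 29958434L, chr06 = 31248787L,
    chr07 = 29697621L, chr08 = 28443022L, chr09 = 23012720L,
    chr10 = 23207287L, chr11 = 29021106L, chr12 = 27531856L)
}
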