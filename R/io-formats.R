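# Readers and writers for the file formats the pipeline touches:
# HapMap tabular genotypes, VCF, annotation interval tables, scan-result TSVs.

parse_report <- function(n_samples, n_loci_read, n_loci_dropped,
                         warnings = character()) {
  stopifnot(n_loci_dropped <= n_loci_read, n_loci_read >= 0, n_samples >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_loci_read = as.integer(n_loci_read),
                 n_loci_dropped = as.integer(n_loci_dropped),
                 warnings = as.character(warnings)),
            class = "parse_report")
}

#' @export
print.parse_report <- function(x, ...) {
  cat(sprintf("<parse_report> %d samples, %d loci read, %d dropped\n",
              x$n_samples, x$n_loci_read, x$n_loci_dropped))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# IUPAC ambiguity code for an unordered base pair
iupac_het <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Read a genotype matrix from HapMap or VCF
#'
#' HapMap input is the tab-delimited Tassel dialect: 11 leading metadata
#' columns (rs#, alleles, chrom, pos, strand, assembly#, center, protLSID,
#' assayLSID, panelLSID, QCcode) followed by one column per sample, with
#' genotypes coded either as single IUPAC letters or as two-letter base pairs.
#' VCF input is v4.x with a GT field. Genotypes are returned as
#' alternate-allele dosages (0/1/2, `NA` missing); multi-allelic sites and
#' indels are dropped and counted in the parse report. Genotype codes that do
#' not match the two declared alleles are set to missing.
#'
#' @param path Path to the genotype file.
#' @param format `"hapmap"` or `"vcf"`.
#'
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `report` (a parse report with counts of loci read/dropped).
#' @export
read_genotypes <- function(path, format = c("hapmap", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         hapmap = read_hapmap_impl(path),
         vcf = read_vcf_impl(path))
}

read_hapmap_impl <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  hdr <- tolower(names(dt))
  if (ncol(dt) < 12L || !all(c("alleles", "chrom", "pos") %in% hdr)) {
    stop("malformed HapMap header: expected 11 metadata columns ",
         "(rs#, alleles, chrom, pos, ...) plus sample columns")
  }
  meta <- dt[, 1:11]
  names(meta) <- hdr[1:11]
  samples <- dt[, -(1:11), drop = FALSE]
  n_read <- nrow(dt)
  warnings <- character()

  al <- strsplit(meta$alleles, "/", fixed = TRUE)
  is_snp <- vapply(al, function(a) {
    length(a) == 2L && all(nchar(a) == 1L) && all(a %in% c("A", "C", "G", "T"))
  }, logical(1))
  n_drop <- sum(!is_snp)
  if (n_drop > 0L) {
    warnings <- c(warnings, sprintf(
      "%d non-biallelic-SNP record(s) dropped", n_drop))
  }
  if (!any(is_snp)) stop("no parsable biallelic SNP loci in ", path)

  keep <- which(is_snp)
  ref <- vapply(al[keep], `[`, character(1), 1L)
  alt <- vapply(al[keep], `[`, character(1), 2L)
  raw <- toupper(as.matrix(samples)[keep, , drop = FALSE])

  geno <- matrix(NA_integer_, nrow = length(keep), ncol = ncol(raw))
  n_bad <- 0L
  for (i in seq_along(keep)) {
    pair <- sort(c(ref[i], alt[i]))
    codes <- c("N", "NN", "--", "-",                     # missing
               ref[i], paste0(ref[i], ref[i]),           # hom ref
               alt[i], paste0(alt[i], alt[i]),           # hom alt
               iupac_het[paste0(pair[1], pair[2])],      # het, IUPAC
               paste0(ref[i], alt[i]), paste0(alt[i], ref[i]))
    dose <- c(NA, NA, NA, NA, 0L, 0L, 2L, 2L, 1L, 1L, 1L)
    m <- match(raw[i, ], codes)
    n_bad <- n_bad + sum(is.na(m) )
    geno[i, ] <- dose[m]
  }
  if (n_bad > 0L) {
    warnings <- c(warnings, sprintf(
      "%d genotype call(s) not matching the declared alleles set to missing",
      n_bad))
  }
  gm <- genotype_matrix(t(geno), chrom = meta$chrom[keep],
                        pos = as.integer(meta$pos[keep]),
                        sample_ids = names(samples),
                        locus_ids = meta[[1]][keep])
  list(genotypes = gm,
       report = parse_report(ncol(samples), n_read, n_drop, warnings))
}

read_vcf_impl <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_read <- nrow(fix)
  is_snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  is_snp[is.na(is_snp)] <- FALSE
  n_drop <- sum(!is_snp)
  if (!any(is_snp)) stop("no parsable biallelic SNP loci in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[is_snp, , drop = FALSE]
  # dosage = number of '1' alleles in the GT string; any '.' makes it missing
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  a2[a2 == ""] <- a1[a2 == ""]  # haploid calls counted once on each strand
  dose <- (a1 == "1") + (a2 == "1")
  dose[a1 == "." | a2 == "." | is.na(gt)] <- NA_integer_
  dose <- matrix(as.integer(dose), nrow = sum(is_snp))
  warnings <- if (n_drop > 0L)
    sprintf("%d non-biallelic-SNP record(s) dropped", n_drop) else character()
  gm <- genotype_matrix(t(dose), chrom = fix[is_snp, "CHROM"],
                        pos = as.integer(fix[is_snp, "POS"]),
                        sample_ids = colnames(gt),
                        locus_ids = ifelse(is.na(fix[is_snp, "ID"]),
                                           paste0(fix[is_snp, "CHROM"], "_",
                                                  fix[is_snp, "POS"]),
                                           fix[is_snp, "ID"]))
  list(genotypes = gm,
       report = parse_report(ncol(gt), n_read, n_drop, warnings))
}

#' Write a genotype matrix as a HapMap file
#'
#' Emits the 11-metadata-column Tassel HapMap dialect with two-letter genotype
#' codes. Dosage 0 maps to the first declared allele, dosage 2 to the second;
#' missing genotypes are written as `NN`. Internal allele letters are
#' arbitrary (`A`/`G`) unless supplied.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param ref,alt Per-locus allele letters (recycled if length 1).
#' @export
write_hapmap <- function(gm, path, ref = "A", alt = "G") {
  L <- n_loci(gm)
  ref <- rep_len(ref, L); alt <- rep_len(alt, L)
  code <- function(d, r, a) {
    out <- rep("NN", length(d))
    out[!is.na(d) & d == 0L] <- paste0(r, r)
    out[!is.na(d) & d == 1L] <- paste0(r, a)
    out[!is.na(d) & d == 2L] <- paste0(a, a)
    out
  }
  cells <- vapply(seq_len(L), function(i) {
    code(gm$geno[, i], ref[i], alt[i])
  }, character(n_samples(gm)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = n_samples(gm))
  out <- data.frame(`rs#` = gm$locus_ids,
                    alleles = paste0(ref, "/", alt),
                    chrom = gm$chrom, pos = gm$pos, strand = "+",
                    `assembly#` = "NA", center = "NA", protLSID = "NA",
                    assayLSID = "NA", panelLSID = "NA", QCcode = "NA",
                    t(cells), check.names = FALSE)
  names(out)[12:ncol(out)] <- gm$sample_ids
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an annotation interval table (genes or QTLs)
#'
#' Accepts BED (0-based half-open) or 1-based inclusive delimited tables with
#' columns chrom, start, end and optionally id and kind. Intervals are
#' normalized to 1-based inclusive coordinates internally (matching RAP-DB
#' gene coordinates). Records whose end precedes their start after
#' normalization are dropped and reported.
#'
#' @param path Path to a delimited text file, no header for BED.
#' @param dialect `"bed"` or `"one_based_table"`.
#'
#' @return A data.frame with columns chrom, start, end, id, kind and an
#'   attribute `"errors"` listing any malformed records (also warned about).
#' @export
read_annotation_table <- function(path, dialect = c("bed", "one_based_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) < 3L) stop("annotation table needs at least chrom/start/end")
  df <- data.frame(chrom = as.character(dt[[1]]),
                   start = as.integer(dt[[2]]),
                   end = as.integer(dt[[3]]),
                   id = if (ncol(dt) >= 4L) as.character(dt[[4]])
                        else sprintf("feat%04d", seq_len(nrow(dt))),
                   kind = if (ncol(dt) >= 5L) as.character(dt[[5]]) else "gene",
                   stringsAsFactors = FALSE)
  if (dialect == "bed") df$start <- df$start + 1L  # 0-based half-open -> 1-based
  bad <- which(df$end < df$start)
  errors <- character()
  if (length(bad)) {
    errors <- sprintf("line %d: end (%d) < start (%d) for %s",
                      bad, df$end[bad], df$start[bad], df$id[bad])
    warning(length(bad), " malformed annotation record(s) dropped")
    df <- df[-bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "errors") <- errors
  df
}

#' Write annotation intervals as BED
#'
#' Converts internal 1-based inclusive intervals back to 0-based half-open.
#' @param annot Data.frame with chrom, start, end, id, kind columns.
#' @param path Output path.
#' @export
write_bed <- function(annot, path) {
  out <- data.frame(annot$chrom, annot$start - 1L, annot$end,
                    annot$id, annot$kind)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and re-read per-locus scan results
#'
#' @param results Data.frame with columns chrom, pos, fst, p, q, class,
#'   method (extra columns are preserved).
#' @param path Output TSV path.
#' @export
write_scan_results <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) stop("results must be non-empty")
  need <- c("chrom", "pos", "fst", "p", "q", "class", "method")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols)) {
    stop("results lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  results <- results[order(results$chrom, results$pos), , drop = FALSE]
  data.table::fwrite(results, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_scan_results
#' @export
read_scan_results <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    na.strings = "NA")
}
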