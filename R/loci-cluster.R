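# Aggregation of significant SNPs into independent loci under selection
# (ILUS), merging across genetic groups, M1/M2 classification and interval
# extension for annotation.

#' Cluster significant SNPs into independent loci
#'
#' Single-linkage chaining along each chromosome: two adjacent significant
#' SNPs belong to the same independent locus when their distance is below
#' `max_gap_kb` and (by default) their LD exceeds `r2_min` -- neighbouring
#' outliers within the span of strong LD are one selection signal, not
#' several. Singletons become one-SNP loci.
#'
#' @param sig_snps Data.frame of significant SNPs with columns chrom, pos and
#'   (optionally) per-method significance flags `sig_drift`, `sig_fdist` plus
#'   any p-value columns, and a `group` label.
#' @param r2 Either a function `f(chrom, pos1, pos2)` returning the pairwise
#'   r-squared, a [genotype_matrix()] from which adjacent-pair LD is computed,
#'   or `NULL` to apply the distance rule alone.
#' @param max_gap_kb Maximum adjacent-SNP distance within a locus.
#' @param r2_min LD threshold for chaining.
#' @param rule `"and"` (default: both distance and LD must pass) or `"or"`.
#' @return Data.frame of class `ilus_set`: chrom, start, end, n_snp, groups,
#'   with per-locus member SNP tables in the `members` attribute.
#' @export
cluster_snps <- function(sig_snps, r2 = NULL, max_gap_kb = 250, r2_min = 0.2,
                         rule = c("and", "or")) {
  rule <- match.arg(rule)
  sig_snps <- as.data.frame(sig_snps)
  if (!nrow(sig_snps)) return(empty_ilus())
  sig_snps <- sig_snps[order(sig_snps$chrom, sig_snps$pos), , drop = FALSE]
  r2_fun <- make_r2_accessor(r2)
  members <- list()
  rows <- list()
  for (ch in unique(sig_snps$chrom)) {
    snp <- sig_snps[sig_snps$chrom == ch, , drop = FALSE]
    cl <- 1L
    cluster_id <- integer(nrow(snp))
    cluster_id[1] <- cl
    for (i in seq_len(nrow(snp))[-1]) {
      gap_ok <- (snp$pos[i] - snp$pos[i - 1]) / 1000 < max_gap_kb
      ld <- r2_fun(ch, snp$pos[i - 1], snp$pos[i])
      ld_ok <- !is.na(ld) && ld > r2_min
      joined <- if (rule == "and") gap_ok && ld_ok else gap_ok || ld_ok
      if (!joined) cl <- cl + 1L
      cluster_id[i] <- cl
    }
    for (k in seq_len(cl)) {
      mem <- snp[cluster_id == k, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = min(mem$pos), end = max(mem$pos),
        n_snp = nrow(mem),
        groups = paste(sort(unique(as.character(
          if ("group" %in% names(mem)) mem$group else "pop"))), collapse = ","),
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- mem
    }
  }
  make_ilus(do.call(rbind, rows), members)
}

make_r2_accessor <- function(r2) {
  if (is.null(r2)) return(function(chrom, pos1, pos2) 1)
  if (is.function(r2)) return(r2)
  if (inherits(r2, "genotype_matrix")) {
    gm <- r2
    return(function(chrom, pos1, pos2) {
      i <- which(gm$chrom == chrom & gm$pos == pos1)
      j <- which(gm$chrom == chrom & gm$pos == pos2)
      if (!length(i) || !length(j)) return(NA_real_)
      ld_r2(gm, i[1], j[1])
    })
  }
  stop("r2 must be NULL, a function, or a genotype_matrix")
}

make_ilus <- function(df, members) {
  ord <- order(df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "members") <- members[ord]
  class(df) <- c("ilus_set", "data.frame")
  df
}

empty_ilus <- function() {
  make_ilus(data.frame(chrom = character(), start = integer(),
                       end = integer(), n_snp = integer(),
                       groups = character(), stringsAsFactors = FALSE),
            list())
}

#' Member SNPs of an independent-locus set
#' @param ilus An `ilus_set`.
#' @return List of per-locus member SNP data.frames, in row order.
#' @export
ilus_members <- function(ilus) attr(ilus, "members")

#' Merge independent loci detected in different genetic groups
#'
#' Loci on the same chromosome whose component SNPs lie within `max_gap_kb`
#' of each other are merged into one locus carrying the union of group
#' labels; merging is transitive.
#'
#' @param loci_a,loci_b `ilus_set` objects from the same genome build (either
#'   may be empty).
#' @param max_gap_kb Maximum distance between nearest component SNPs.
#' @return A merged `ilus_set`.
#' @export
merge_loci_groups <- function(loci_a, loci_b, max_gap_kb = 250) {
  all_df <- rbind(as.data.frame(loci_a), as.data.frame(loci_b))
  all_mem <- c(ilus_members(loci_a), ilus_members(loci_b))
  if (!nrow(all_df)) return(empty_ilus())
  ord <- order(all_df$chrom, all_df$start)
  all_df <- all_df[ord, , drop = FALSE]
  all_mem <- all_mem[ord]
  rows <- list(); members <- list()
  cur_df <- NULL; cur_mem <- NULL
  flush <- function() {
    if (is.null(cur_df)) return()
    rows[[length(rows) + 1L]] <<- cur_df
    members[[length(members) + 1L]] <<- cur_mem
  }
  for (i in seq_len(nrow(all_df))) {
    row <- all_df[i, , drop = FALSE]
    mem <- all_mem[[i]]
    same_chrom <- !is.null(cur_df) && cur_df$chrom == row$chrom
    # nearest component SNPs: loci are sorted by start, members by pos
    close_enough <- same_chrom &&
      (row$start - cur_df$end) / 1000 < max_gap_kb
    if (close_enough) {
      cur_df$end <- max(cur_df$end, row$end)
      cur_df$start <- min(cur_df$start, row$start)
      cur_df$n_snp <- cur_df$n_snp + row$n_snp
      cur_df$groups <- paste(sort(unique(c(
        strsplit(cur_df$groups, ",")[[1]], strsplit(row$groups, ",")[[1]]))),
        collapse = ",")
      shared <- intersect(names(cur_mem), names(mem))
      cur_mem <- rbind(cur_mem[, shared, drop = FALSE],
                       mem[, shared, drop = FALSE])
      cur_mem <- cur_mem[order(cur_mem$pos), , drop = FALSE]
    } else {
      flush()
      cur_df <- row; cur_mem <- mem
    }
  }
  flush()
  make_ilus(do.call(rbind, rows), members)
}

#' Classify independent loci (M1/M2), apply the discard rule, and extend
#'
#' A locus is type M2 when at least one member SNP is significant under both
#' detection methods, M1 otherwise. Single-SNP loci supported by only one
#' method are discarded when `drop_singletons_single_method` is set (they are
#' the weakest signals). Retained intervals are extended by `flank_kb` on
#' both sides -- accounting for the extent of LD around a selected site --
#' and clipped at position 1 and the chromosome end.
#'
#' @param loci An `ilus_set` whose members carry logical columns `sig_drift`
#'   and `sig_fdist`.
#' @param flank_kb Extension on each side, in kb.
#' @param drop_singletons_single_method Apply the discard rule.
#' @param chrom_lengths Named vector of chromosome lengths for clipping
#'   (defaults to IRGSP-1.0).
#' @return An `ilus_set` with columns type (`M1`/`M2`), start/end extended.
#' @export
classify_and_extend <- function(loci, flank_kb = 250,
                                drop_singletons_single_method = TRUE,
                                chrom_lengths = irgsp1_chrom_lengths()) {
  df <- as.data.frame(loci)
  mem <- ilus_members(loci)
  if (!nrow(df)) {
    df$type <- character(0)
    return(make_ilus(df, mem))
  }
  both <- vapply(mem, function(m) {
    any(m$sig_drift & m$sig_fdist)
  }, logical(1))
  one_method_only <- vapply(mem, function(m) {
    !any(m$sig_drift & m$sig_fdist) &&
      (all(!m$sig_drift) || all(!m$sig_fdist))
  }, logical(1))
  df$type <- ifelse(both, "M2", "M1")
  keep <- rep(TRUE, nrow(df))
  if (drop_singletons_single_method) {
    keep <- !(df$n_snp == 1L & one_method_only)
  }
  df <- df[keep, , drop = FALSE]
  mem <- mem[keep]
  if (!nrow(df)) return(make_ilus(df, mem))
  if (any(!df$chrom %in% names(chrom_lengths))) {
    stop("chromosome length missing for: ",
         paste(setdiff(df$chrom, names(chrom_lengths)), collapse = ", "))
  }
  df$start <- pmax(1L, df$start - as.integer(flank_kb * 1000))
  df$end <- pmin(as.integer(chrom_lengths[df$chrom]),
                 df$end + as.integer(flank_kb * 1000))
  make_ilus(df, mem)
}

#' Export an independent-locus set as a 1-based TSV
#'
#' Columns: locus number, type, n_snp, chrom, start, end, groups.
#' @param ilus An `ilus_set`.
#' @param path Output path.
#' @export
write_ilus <- function(ilus, path) {
  df <- as.data.frame(ilus)
  out <- data.frame(n = seq_len(nrow(df)),
                    type = if ("type" %in% names(df)) df$type else NA,
                    n_snp = df$n_snp, chrom = df$chrom,
                    start = df$start, end = df$end, groups = df$groups)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
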