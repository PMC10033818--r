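# End-to-end orchestration: filtering, diversity statistics, both genome
# scans, independent-locus construction and (optionally) annotation overlap,
# with every table written to an output directory and a self-documenting run
# log.

#' Run the full temporal genome scan
#'
#' Executes the whole pipeline on a temporal pair (or a pair of HapMap
#' files): locus filtering, per-locus summaries, multilocus FIS, LD decay
#' profile, the drift-based and heterozygosity-based scans, clustering of
#' significant SNPs into independent loci, M1/M2 classification with
#' interval extension, and annotation overlap when an annotation table is
#' supplied. All result tables are written as TSV under `out_dir` together
#' with a log of every threshold applied, so a run is self-documenting and
#' reproducible from its seed.
#'
#' @param pair A [temporal_pair()], or a list `list(t0 = path, tau = path)`
#'   of HapMap files plus `tau` generations.
#' @param out_dir Output directory (created if absent).
#' @param seed RNG seed propagated to every stochastic stage.
#' @param tau Generations between collects when reading from files.
#' @param group Genetic-group label attached to clustered loci.
#' @param maf_min,miss_max,het_max Locus filters (see [filter_loci()]).
#' @param drift List of [drift_scan()] arguments (e.g. `n_sim`).
#' @param fdist List of [fdist_scan()] arguments (e.g. `n_sim`, `k_groups`).
#' @param max_gap_kb,r2_min Clustering thresholds (see [cluster_snps()]).
#' @param flank_kb Interval extension (see [classify_and_extend()]).
#' @param annotations Optional annotation data.frame from
#'   [read_annotation_table()].
#' @param chrom_lengths Chromosome lengths for interval clipping.
#' @return Invisibly, a list with the filtered pair, summaries, fis, the two
#'   scan results, the clustered/classified loci, and overlap counts.
#' @export
run_full_scan <- function(pair, out_dir, seed = 1, tau = 31, group = "pop",
                          maf_min = 0.01, miss_max = 0.20, het_max = 0.05,
                          drift = list(), fdist = list(),
                          max_gap_kb = 250, r2_min = 0.2, flank_kb = 250,
                          annotations = NULL,
                          chrom_lengths = irgsp1_chrom_lengths()) {
  if (!inherits(pair, "temporal_pair")) {
    stopifnot(is.list(pair), !is.null(pair$t0), !is.null(pair$tau))
    g0 <- read_genotypes(pair$t0, "hapmap")$genotypes
    g1 <- read_genotypes(pair$tau, "hapmap")$genotypes
    pair <- temporal_pair(g0, g1, tau)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat(sprintf("temporal genome scan run log\npackage temposcan %s\nseed %d\n",
              as.character(utils::packageVersion("temposcan")), seed),
      file = log_path)

  filt <- filter_loci(pair, maf_min, miss_max, het_max)
  pair <- filt$pair
  logf("filter: maf_min=%g miss_max=%g het_max=%g -> %d loci kept, %d dropped",
       maf_min, miss_max, het_max, n_loci(pair$sample_t0),
       filt$report$n_loci_dropped)

  summ <- locus_summaries(pair)
  fis <- multilocus_fis(pair)
  pooled <- rbind_genotypes(pair$sample_t0, pair$sample_tau)
  ld <- ld_decay_profile(pooled)
  logf("FIS (multilocus, both collects) = %.4f", fis)
  data.table::fwrite(summ, file.path(out_dir, "locus_summaries.tsv"),
                     sep = "\t", na = "NA")
  data.table::fwrite(ld, file.path(out_dir, "ld_profile.tsv"),
                     sep = "\t", na = "NA")

  dres <- do.call(drift_scan, c(list(pair = pair, seed = seed + 1L), drift))
  logf("drift scan: tau=%d n_sim=%d FST=%.5f Ne_hat=%.1f -> %d loci q<0.05",
       dres$tau, dres$n_sim, dres$fst_temporal, dres$ne_hat,
       sum(dres$table$class == "sig"))
  write_scan_results(dres$table, file.path(out_dir, "drift_scan.tsv"))

  fres <- do.call(fdist_scan, c(list(pair = pair, seed = seed + 2L), fdist))
  logf("fdist scan: n_sim=%d k=%s d=%s target FST=%.5f -> %d sig5, %d sig1",
       fres$n_sim, deparse(fres$rates$k_groups), "-", fres$target_fst,
       sum(fres$table$class == "sig5"), sum(fres$table$class == "sig1"))
  write_scan_results(fres$table, file.path(out_dir, "fdist_scan.tsv"))
  data.table::fwrite(fres$cloud, file.path(out_dir, "fdist_cloud.tsv"),
                     sep = "\t", na = "NA")
  data.table::fwrite(fres$env5, file.path(out_dir, "fdist_envelope5.tsv"),
                     sep = "\t", na = "NA")
  data.table::fwrite(fres$env1, file.path(out_dir, "fdist_envelope1.tsv"),
                     sep = "\t", na = "NA")

  sig <- significant_snp_table(dres, fres, group)
  loci <- cluster_snps(sig, r2 = pooled, max_gap_kb = max_gap_kb,
                       r2_min = r2_min)
  ilus <- classify_and_extend(loci, flank_kb = flank_kb,
                              chrom_lengths = chrom_lengths)
  logf("clustering: gap<%g kb, r2>%g -> %d loci; after discard+extend: %d (%d M2)",
       max_gap_kb, r2_min, nrow(loci), nrow(ilus),
       sum(as.data.frame(ilus)$type == "M2"))
  if (nrow(ilus)) {
    write_ilus(ilus, file.path(out_dir, "ilus.tsv"))
    write_bed(data.frame(chrom = ilus$chrom, start = ilus$start,
                         end = ilus$end, id = sprintf("ilus%02d",
                                                      seq_len(nrow(ilus))),
                         kind = ilus$type),
              file.path(out_dir, "ilus.bed"))
  }

  overlap <- NULL
  if (!is.null(annotations) && nrow(as.data.frame(ilus))) {
    overlap <- overlap_annotations(ilus, annotations)
    hits <- overlap$per_interval
    hits$hits <- vapply(hits$hits, paste, character(1), collapse = ",")
    data.table::fwrite(hits, file.path(out_dir, "ilus_annotation.tsv"),
                       sep = "\t", na = "NA")
    logf("annotation overlap: %s",
         paste(names(overlap$total), overlap$total,
               sep = "=", collapse = " "))
  }

  invisible(list(pair = pair, filter_report = filt$report, summaries = summ,
                 fis = fis, ld_profile = ld, drift = dres, fdist = fres,
                 loci = loci, ilus = ilus, overlap = overlap))
}

# SNPs significant under either method, with per-method flags; drift
# significance is q < 0.05, heterozygosity-method significance is falling
# beyond the 5% envelope
significant_snp_table <- function(dres, fres, group = "pop") {
  dt <- dres$table; ft <- fres$table
  stopifnot(identical(dt$pos, ft$pos))
  sig_drift <- !is.na(dt$class) & dt$class == "sig"
  sig_fdist <- ft$class %in% c("sig5", "sig1")
  keep <- sig_drift | sig_fdist
  group <- rep_len(group, sum(keep))
  data.frame(chrom = dt$chrom[keep], pos = dt$pos[keep],
             locus_id = dt$locus_id[keep],
             p_drift = dt$p[keep], q_drift = dt$q[keep],
             p_fdist = ft$p[keep], class_fdist = ft$class[keep],
             sig_drift = sig_drift[keep], sig_fdist = sig_fdist[keep],
             group = group, stringsAsFactors = FALSE)
}
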