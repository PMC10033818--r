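#!/usr/bin/env Rscript
# Step 3: annotation overlap and enrichment statistics.
#
# Intersects the ILUS regions from 02_scan.R with a synthetic gene/QTL
# annotation, and reproduces the published fold-enrichment and QTL-density
# arithmetic from the reported counts. Writes results/enrichment/.

suppressPackageStartupMessages(library(temposcan))

out_dir <- "results/enrichment"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## overlap of scan regions with a synthetic annotation ------------------------
set.seed(20230103)
lens <- irgsp1_chrom_lengths()
annot <- do.call(rbind, lapply(names(lens), function(ch) {
  start <- sort(sample.int(lens[[ch]] - 5000L, 300))
  data.frame(chrom = ch, start = start, end = start + 4999L,
             id = sprintf("%s_g%03d", ch, seq_along(start)),
             kind = sample(c("gene", "qtl"), 300, TRUE, prob = c(0.8, 0.2)))
}))
write_bed(annot, file.path(out_dir, "synthetic_annotation.bed"))

if (file.exists("results/scan/ilus.tsv")) {
  ilus <- read.delim("results/scan/ilus.tsv")
  ov <- overlap_annotations(ilus, annot)
  write.table(ov$per_interval, file.path(out_dir, "ilus_overlap.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("overlap totals: %s\n",
              paste(names(ov$total), ov$total, sep = "=", collapse = ", ")))
} else {
  cat("no ILUS regions from step 2; skipping overlap\n")
}

## published-count arithmetic -------------------------------------------------
rows <- list(
  c(term = "GO reproduction", unlist(
    fold_enrichment(65, 133, 1240, 24075)[c("exp", "fold", "p_hyper")])),
  c(term = "GO pollination", unlist(
    fold_enrichment(20, 114, 1240, 24075)[c("exp", "fold", "p_hyper")])),
  c(term = "Panther reproduction", unlist(
    fold_enrichment(37, 587, 1464, 43658)[c("exp", "fold", "p_hyper")])))
enr <- as.data.frame(do.call(rbind, rows))
write.table(enr, file.path(out_dir, "fold_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

qtl <- rbind(
  data.frame(set = "M2 loci", density_fold(112, 23.26, 0.62)),
  data.frame(set = "all loci", density_fold(162, 30.77, 0.62)))
write.table(qtl, file.path(out_dir, "qtl_density.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("fold enrichment (reproduction):",
    round(as.numeric(enr$fold[1]), 2), "\n")
cat("QTL density on M2 loci:",
    round(qtl$density_mb_per_feature[1], 2), "Mb/QTL, fold",
    round(qtl$fold[1], 1), "\n")
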