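#!/usr/bin/env Rscript
# Step 1: simulate the study data set.
#
# A predominantly selfing population (95% selfing, Ne = 500) is evolved for
# 31 generations with 10 loci under positive fertility selection (s = 0.5),
# and genotyped samples of 100 individuals are taken at the start and end.
# The two samples are written as HapMap files, together with the true
# simulation state, under results/data/.

suppressPackageStartupMessages(library(temposcan))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

planted <- as.integer(seq(50, 950, length.out = 10))
pair <- simulate_temporal_population(
  n_loci = 1000, ne = 500, selfing_rate = 0.95, tau = 31,
  n0 = 100, n_tau = 100, selected = planted, sel_coef = 0.5, seed = 20230101)

write_hapmap(pair$sample_t0, file.path(out_dir, "collect1.hmp.txt"))
write_hapmap(pair$sample_tau, file.path(out_dir, "collect2.hmp.txt"))

truth <- data.frame(
  locus = seq_len(ncol(pair$truth$freq)),
  chrom = pair$sample_t0$chrom,
  pos = pair$sample_t0$pos,
  selected = seq_len(ncol(pair$truth$freq)) %in% pair$truth$selected,
  p_init = pair$truth$freq[1, ],
  p_final = pair$truth$freq[nrow(pair$truth$freq), ])
write.table(truth, file.path(out_dir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("wrote %s: 2 HapMap samples (%d loci), truth table (%d selected)\n",
            out_dir, ncol(pair$sample_t0$geno), length(pair$truth$selected)))
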