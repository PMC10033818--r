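sig_df <- function(pos, chrom = "chr01", sig_drift = TRUE, sig_fdist = TRUE,
                   group = "pop") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             sig_drift = rep_len(sig_drift, length(pos)),
             sig_fdist = rep_len(sig_fdist, length(pos)),
             group = group, stringsAsFactors = FALSE)
}

test_that("distance chaining groups SNPs as specified", {
  # positions 0, 100, 200, 600, 650 kb with gap < 250 kb chaining
  snps <- sig_df(c(0, 100e3, 200e3, 600e3, 650e3))
  out <- cluster_snps(snps, r2 = NULL, max_gap_kb = 250)
  expect_identical(nrow(out), 2L)
  expect_identical(out$start, c(0L, 600000L))
  expect_identical(out$end, c(200000L, 650000L))
  expect_identical(out$n_snp, c(3L, 2L))
})

test_that("LD requirement splits distance-joined chains under the and-rule", {
  snps <- sig_df(c(0, 100e3, 200e3))
  low_ld <- function(chrom, pos1, pos2) if (pos1 == 100e3) 0.05 else 0.9
  both <- cluster_snps(snps, r2 = low_ld, max_gap_kb = 250, rule = "and")
  expect_identical(nrow(both), 2L)       # chain broken at the low-LD step
  either <- cluster_snps(snps, r2 = low_ld, max_gap_kb = 250, rule = "or")
  expect_identical(nrow(either), 1L)     # distance alone suffices
})

test_that("chaining matches a union-find oracle on random configurations", {
  union_find_clusters <- function(pos, max_gap) {
    parent <- seq_along(pos)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(pos)[-1]) {
      if (pos[i] - pos[i - 1] < max_gap) {
        parent[find(i)] <- find(i - 1)
      }
    }
    length(unique(vapply(seq_along(pos), find, numeric(1))))
  }
  set.seed(31)
  for (rep in 1:10) {
    pos <- sort(sample.int(5e6, 40))
    out <- cluster_snps(sig_df(pos), r2 = NULL, max_gap_kb = 250)
    expect_identical(nrow(out), union_find_clusters(pos, 250e3))
  }
})

test_that("clustering respects chromosome boundaries and group labels", {
  snps <- rbind(sig_df(c(1e6, 1.1e6), chrom = "chr01", group = "Og"),
                sig_df(c(1.05e6), chrom = "chr02", group = "Osj"))
  out <- cluster_snps(snps, r2 = NULL)
  expect_identical(nrow(out), 2L)
  expect_identical(out$chrom, c("chr01", "chr02"))
  expect_identical(out$groups, c("Og", "Osj"))
  mem <- ilus_members(out)
  expect_identical(vapply(mem, nrow, integer(1)), c(2L, 1L))
})

test_that("merge_loci_groups unions nearby loci across groups transitively", {
  a <- cluster_snps(sig_df(c(1e6, 1.1e6), group = "Og"), r2 = NULL)
  b <- cluster_snps(sig_df(c(1.3e6), group = "Osj"), r2 = NULL)
  m <- merge_loci_groups(a, b, max_gap_kb = 250)
  expect_identical(nrow(m), 1L)
  expect_identical(m$groups, "Og,Osj")
  expect_identical(m$n_snp, 3L)
  expect_identical(m$start, 1000000L)
  expect_identical(m$end, 1300000L)

  far <- cluster_snps(sig_df(c(5e6), group = "Osi"), r2 = NULL)
  m2 <- merge_loci_groups(m, far, max_gap_kb = 250)
  expect_identical(nrow(m2), 2L)
  expect_identical(merge_loci_groups(a, temposcan:::empty_ilus())$n_snp,
                   a$n_snp)
})

test_that("classification, singleton discard, extension and clipping", {
  snps <- rbind(
    sig_df(c(1e6, 1.05e6), sig_drift = TRUE, sig_fdist = c(FALSE, TRUE)),
    sig_df(30e6, sig_drift = TRUE, sig_fdist = FALSE),   # M1 singleton
    sig_df(43.2e6, sig_drift = TRUE, sig_fdist = TRUE))  # M2 near chr end
  loci <- cluster_snps(snps, r2 = NULL)
  out <- classify_and_extend(loci, flank_kb = 250)
  df <- as.data.frame(out)
  # singleton supported by one method is discarded
  expect_identical(nrow(df), 2L)
  expect_identical(df$type, c("M2", "M2"))
  # extension by 250 kb, clipped at 1 and at the chr01 length
  expect_identical(df$start[1], 750000L)
  expect_identical(df$end[1], 1300000L)
  expect_identical(df$end[2], unname(irgsp1_chrom_lengths()["chr01"]))

  kept <- classify_and_extend(loci, flank_kb = 0,
                              drop_singletons_single_method = FALSE)
  expect_identical(nrow(as.data.frame(kept)), 3L)
  expect_identical(as.data.frame(kept)$type, c("M2", "M1", "M2"))

  expect_error(
    classify_and_extend(cluster_snps(sig_df(10, chrom = "chrX"), r2 = NULL)),
    "chromosome length missing")
})

test_that("a cluster is M2 only if one SNP is significant under both", {
  # two SNPs, one drift-only and one fdist-only: M1 despite both methods
  snps <- sig_df(c(1e6, 1.1e6), sig_drift = c(TRUE, FALSE),
                 sig_fdist = c(FALSE, TRUE))
  out <- classify_and_extend(cluster_snps(snps, r2 = NULL), flank_kb = 0)
  expect_identical(as.data.frame(out)$type, "M1")
})

test_that("write_ilus emits a readable 1-based table", {
  loci <- classify_and_extend(
    cluster_snps(sig_df(c(1e6, 1.2e6)), r2 = NULL), flank_kb = 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ilus(loci, path)
  back <- read.delim(path)
  expect_identical(back$n, 1L)
  expect_identical(back$start, 900000L)
  expect_identical(back$end, 1300000L)
  expect_identical(back$type, "M2")
})
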