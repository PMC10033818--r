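# independent ANOVA-style Weir-Cockerham oracle: allele-level sums of squares
wc_oracle <- function(d1, d2) {
  pops <- list(d1[!is.na(d1)], d2[!is.na(d2)])
  n <- vapply(pops, length, numeric(1))
  p <- vapply(pops, function(d) mean(d) / 2, numeric(1))
  het <- vapply(pops, function(d) mean(d == 1L), numeric(1))
  r <- 2; n_tot <- sum(n)
  pbar <- sum(2 * n * p) / sum(2 * n)
  ssg <- sum(vapply(pops, function(d) sum(d == 1L) / 2, numeric(1)))
  ssi <- sum(mapply(function(d, pi) sum(2 * (d / 2 - pi)^2), pops, p))
  ssp <- sum(2 * n * (p - pbar)^2)
  msg <- ssg / n_tot
  msi <- ssi / (n_tot - r)
  msp <- ssp / (r - 1)
  nc <- (n_tot - sum(n^2) / n_tot) / (r - 1)
  a <- (msp - msi) / (2 * nc)
  b <- (msi - msg) / 2
  cc <- msg
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

counts_to_dosages <- function(k) rep(c(0L, 1L, 2L), k)

test_that("Weir-Cockerham components match a brute-force ANOVA oracle", {
  k0 <- c(8L, 2L, 0L); k1 <- c(2L, 2L, 6L)
  wc <- temposcan:::wc_components(matrix(k0, 1), matrix(k1, 1))
  orc <- wc_oracle(counts_to_dosages(k0), counts_to_dosages(k1))
  expect_equal(wc$a, orc$a, tolerance = 1e-12)
  expect_equal(wc$b, orc$b, tolerance = 1e-12)
  expect_equal(wc$c, orc$c, tolerance = 1e-12)
  expect_equal(wc$theta, orc$theta, tolerance = 1e-12)

  set.seed(99)
  for (rep in 1:20) {
    ka <- as.integer(rmultinom(1, 30, c(0.5, 0.2, 0.3)))
    kb <- as.integer(rmultinom(1, 25, c(0.3, 0.1, 0.6)))
    if (sum(ka[2:3]) + sum(kb[2:3]) == 0) next
    wc <- temposcan:::wc_components(matrix(ka, 1), matrix(kb, 1))
    if (!wc$estimable) next
    orc <- wc_oracle(counts_to_dosages(ka), counts_to_dosages(kb))
    expect_equal(wc$theta, orc$theta, tolerance = 1e-10)
  }
})

test_that("identity probabilities match exhaustive gene-pair enumeration", {
  k0 <- c(5L, 3L, 2L); k1 <- c(1L, 4L, 5L)
  gm0 <- genotype_matrix(matrix(counts_to_dosages(k0), ncol = 1),
                         "chr01", 100L)
  gm1 <- genotype_matrix(matrix(counts_to_dosages(k1), ncol = 1),
                         "chr01", 100L)
  s <- locus_summaries(temporal_pair(gm0, gm1, tau = 31))

  # gene copies: one 0-allele per ref gene, one 1-allele per alt gene
  genes <- function(k) rep(c(0L, 1L), c(2 * k[1] + k[2], k[2] + 2 * k[3]))
  pair_identity <- function(g) {
    pairs <- combn(length(g), 2)
    mean(g[pairs[1, ]] == g[pairs[2, ]])
  }
  cross_identity <- function(ga, gb) {
    mean(outer(ga, gb, "=="))
  }
  g0 <- genes(k0); g1 <- genes(k1)
  expect_equal(s$f0_hat, (pair_identity(g0) + pair_identity(g1)) / 2,
               tolerance = 1e-12)
  expect_equal(s$f1_hat, cross_identity(g0, g1), tolerance = 1e-12)
  expect_equal(s$fst_bn, (s$f0_hat - s$f1_hat) / (1 - s$f1_hat),
               tolerance = 1e-12)
  expect_equal(s$h1_hat, 1 - s$f1_hat, tolerance = 1e-12)
})

test_that("fst_bn is NA when both samples are fixed for the same allele", {
  gm0 <- genotype_matrix(matrix(c(0L, 0L, 0L, 0L, 1L, 2L), 3),
                         c("chr01", "chr01"), c(10L, 20L))
  gm1 <- genotype_matrix(matrix(c(0L, 0L, 0L, 2L, 2L, 1L), 3),
                         c("chr01", "chr01"), c(10L, 20L))
  s <- locus_summaries(temporal_pair(gm0, gm1, tau = 5))
  expect_true(is.na(s$fst_bn[1]))
  expect_false(is.na(s$fst_bn[2]))
})

test_that("filter_loci applies strict MAF/missingness/heterozygosity rules", {
  geno <- cbind(rep(0L, 20),                       # monomorphic
                c(2L, rep(0L, 19)),                # MAF 0.05, no hets
                c(rep(NA, 5), rep(c(0L, 2L), length.out = 15)),  # 25% missing
                c(rep(1L, 3), rep(c(0L, 2L), length.out = 17)),  # 15% het
                rep(c(0L, 2L), 10))                # clean
  gm <- genotype_matrix(geno, rep("chr01", 5),
                        c(100L, 200L, 300L, 400L, 500L))
  out <- filter_loci(gm, maf_min = 0.01, miss_max = 0.20, het_max = 0.05)
  expect_identical(out$genotypes$pos, c(200L, 500L))
  expect_identical(out$report$n_loci_dropped, 3L)
  expect_error(filter_loci(gm, maf_min = 0.6), "all loci removed")
})

test_that("filter_loci on a pair keeps locus lists identical and prunes truth", {
  pair <- small_pair()
  out <- filter_loci(pair)
  expect_identical(out$pair$sample_t0$pos, out$pair$sample_tau$pos)
  expect_identical(ncol(out$pair$truth$freq), ncol(out$pair$sample_t0$geno))
})

test_that("multilocus FIS reflects genotype composition", {
  # all homozygotes -> FIS = 1; Hardy-Weinberg-ish mixtures -> lower
  gm0 <- genotype_matrix(matrix(rep(c(0L, 2L), 10), ncol = 2),
                         c("chr01", "chr01"), c(1L, 2L))
  gm1 <- genotype_matrix(matrix(rep(c(2L, 0L), 10), ncol = 2),
                         c("chr01", "chr01"), c(1L, 2L))
  expect_equal(multilocus_fis(temporal_pair(gm0, gm1, 3)), 1)
  mono <- genotype_matrix(matrix(0L, 10, 1), "chr01", 1L)
  expect_error(multilocus_fis(temporal_pair(mono, mono, 3)),
               "no polymorphic loci")
})

test_that("ld_r2 matches squared correlation and handles degenerate input", {
  gm <- tiny_gm()
  expect_equal(ld_r2(gm, 1, 2),
               cor(gm$geno[, 1], gm$geno[, 2])^2, tolerance = 1e-12)
  mono <- genotype_matrix(cbind(rep(1L, 4), rep(0L, 4)),
                          c("chr01", "chr01"), c(1L, 2L))
  expect_true(is.na(ld_r2(mono, 1, 2)))
})

test_that("LD decay profile bins pairs correctly and summary accessors work", {
  # three loci on one chromosome: pairs at 4 kb, 30 kb, 34 kb
  set.seed(5)
  base <- sample(c(0L, 2L), 40, replace = TRUE)
  flip <- function(x, k) { i <- sample(40, k); x[i] <- 2L - x[i]; x }
  geno <- cbind(base, flip(base, 4), flip(base, 18))
  gm <- genotype_matrix(geno, rep("chr01", 3), c(1000L, 5000L, 35000L))
  prof <- ld_decay_profile(gm, bin_width_kb = 50)
  expect_s3_class(prof, "ld_profile")
  expect_identical(prof$n_pairs[prof$bin_lo == 0], 1L)   # 4 kb pair
  expect_identical(prof$n_pairs[prof$bin_lo == 25], 2L)  # 30 and 34 kb pairs
  expect_identical(sum(prof$n_pairs), 3L)
  expect_equal(initial_ld(prof), prof$mean_r2[1])
  # strongly correlated pairs -> initial bin above 0.2; decay NA (no far bin)
  expect_gt(initial_ld(prof), 0.2)
  expect_true(is.na(decay_distance(prof, threshold = 1e-6)))

  # pairs across chromosomes are never counted
  gm2 <- genotype_matrix(geno, c("chr01", "chr02", "chr03"),
                         c(1000L, 1000L, 1000L))
  prof2 <- ld_decay_profile(gm2)
  expect_identical(sum(prof2$n_pairs), 0L)
})
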