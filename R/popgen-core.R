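# Locus filtering and the population-genetic statistics both genome scans
# rely on: identity-probability summaries, Weir-Cockerham F-statistics,
# and LD decay profiling.

#' Filter loci on MAF, missingness and heterozygosity
#'
#' Keeps loci with minor allele frequency strictly above `maf_min`, missing
#' fraction strictly below `miss_max` and heterozygote fraction strictly
#' below `het_max` (the defaults are the GBS filtering thresholds used for
#' highly homozygous landrace panels). For a temporal pair the statistics are
#' computed on the two samples pooled and the surviving loci applied to both.
#'
#' @param m A [genotype_matrix()] or [temporal_pair()].
#' @param maf_min,miss_max,het_max Thresholds in \[0, 1\].
#'
#' @return List with the filtered object (`genotypes` or `pair`) and a
#'   `report` counting loci read and dropped.
#' @export
filter_loci <- function(m, maf_min = 0.01, miss_max = 0.20, het_max = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 1, miss_max >= 0, miss_max <= 1,
            het_max >= 0, het_max <= 1)
  pooled <- if (inherits(m, "temporal_pair")) {
    rbind_genotypes(m$sample_t0, m$sample_tau)
  } else m
  g <- pooled$geno
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  miss <- colMeans(is.na(g))
  het <- colMeans(g == 1L, na.rm = TRUE)
  het[is.nan(het)] <- 0
  keep <- maf > maf_min & miss < miss_max & het < het_max
  if (!any(keep)) stop("all loci removed by filtering")
  report <- parse_report(n_samples(pooled), length(keep), sum(!keep))
  if (inherits(m, "temporal_pair")) {
    list(pair = temporal_pair(subset_loci(m$sample_t0, keep),
                              subset_loci(m$sample_tau, keep),
                              m$tau, truth = prune_truth(m$truth, keep)),
         report = report)
  } else {
    list(genotypes = subset_loci(m, keep), report = report)
  }
}

prune_truth <- function(truth, keep) {
  if (is.null(truth)) return(NULL)
  new_index <- cumsum(keep)
  truth$selected <- new_index[intersect(truth$selected, which(keep))]
  if (!is.null(truth$freq)) truth$freq <- truth$freq[, keep, drop = FALSE]
  truth
}

# probability that two distinct genes drawn from one population are identical
# (unbiased, from allele counts over N = 2 * callable individuals genes)
homozygosity_unbiased <- function(alt_genes, total_genes) {
  ref_genes <- total_genes - alt_genes
  num <- alt_genes * (alt_genes - 1) + ref_genes * (ref_genes - 1)
  out <- num / (total_genes * (total_genes - 1))
  out[total_genes < 2] <- NA_real_
  out
}

#' Per-locus identity-probability summaries and FST
#'
#' For each locus of a temporal pair, computes the average within-population
#' homozygosity \eqn{\hat f_0} (probability that two genes from the same
#' population are identical, with the unbiased small-sample correction), the
#' between-population identity \eqn{\hat f_1}, the corresponding
#' heterozygosities \eqn{\hat h_0 = 1 - \hat f_0} and
#' \eqn{h_1 = 1 - \hat f_1}, and two per-locus FST estimates: the
#' identity-based \eqn{\hat F_{ST} = (\hat f_0 - \hat f_1)/(1 - \hat f_1)}
#' (reported `NA` when both samples are fixed for the same allele) and the
#' Weir-Cockerham variance-component estimate.
#'
#' @param pair A [temporal_pair()].
#' @return Data.frame, one row per locus: chrom, pos, genotype counts per
#'   sample, f0_hat, f1_hat, h0_hat, h1_hat, fst_bn, fst_wc.
#' @export
locus_summaries <- function(pair) {
  stopifnot(inherits(pair, "temporal_pair"))
  c0 <- genotype_class_counts(pair$sample_t0)
  c1 <- genotype_class_counts(pair$sample_tau)
  n0 <- rowSums(c0); n1 <- rowSums(c1)
  alt0 <- c0[, "n1"] + 2 * c0[, "n2"]
  alt1 <- c1[, "n1"] + 2 * c1[, "n2"]
  f_pop0 <- homozygosity_unbiased(alt0, 2 * n0)
  f_pop1 <- homozygosity_unbiased(alt1, 2 * n1)
  f0 <- (f_pop0 + f_pop1) / 2
  p0 <- alt0 / (2 * n0); p1 <- alt1 / (2 * n1)
  f1 <- p0 * p1 + (1 - p0) * (1 - p1)
  fst_bn <- ifelse(f1 < 1, (f0 - f1) / (1 - f1), NA_real_)
  wc <- wc_components(c0, c1)
  data.frame(chrom = pair$sample_t0$chrom, pos = pair$sample_t0$pos,
             locus_id = pair$sample_t0$locus_ids,
             n0_t0 = c0[, 1], n1_t0 = c0[, 2], n2_t0 = c0[, 3],
             n0_t1 = c1[, 1], n1_t1 = c1[, 2], n2_t1 = c1[, 3],
             f0_hat = f0, f1_hat = f1,
             h0_hat = 1 - f0, h1_hat = 1 - f1,
             fst_bn = fst_bn, fst_wc = wc$theta,
             stringsAsFactors = FALSE)
}

# Weir & Cockerham (1984) variance components for two populations, from
# genotype class counts; individual-level components, valid under inbreeding.
# c0, c1: L x 3 matrices of (n0, n1, n2) dosage-class counts.
wc_components <- function(c0, c1) {
  ni1 <- rowSums(c0); ni2 <- rowSums(c1)
  p1 <- (c0[, 2] + 2 * c0[, 3]) / (2 * ni1)
  p2 <- (c1[, 2] + 2 * c1[, 3]) / (2 * ni2)
  h1 <- c0[, 2] / ni1
  h2 <- c1[, 2] / ni2
  r <- 2
  nbar <- (ni1 + ni2) / r
  nc <- r * nbar - (ni1^2 + ni2^2) / (r * nbar)
  pbar <- (ni1 * p1 + ni2 * p2) / (r * nbar)
  s2 <- (ni1 * (p1 - pbar)^2 + ni2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (ni1 * h1 + ni2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  estimable <- ni1 >= 2 & ni2 >= 2 & pbar > 0 & pbar < 1 & nc > 0
  a[!estimable] <- NA_real_; b[!estimable] <- NA_real_; cc[!estimable] <- NA_real_
  theta <- ifelse(estimable & (a + b + cc) != 0, a / (a + b + cc), NA_real_)
  list(a = a, b = b, c = cc, theta = theta, estimable = estimable)
}

#' Weir-Cockerham FST between the two temporal samples
#'
#' Per-locus variance-component estimates and the multilocus (global)
#' estimate as the ratio of summed components across loci. Negative per-locus
#' estimates are retained in the global sums; loci that are non-estimable
#' (fewer than two callable genotypes in a sample, or monomorphic pooled)
#' are excluded from the sums and flagged `NA`.
#'
#' @param pair A [temporal_pair()].
#' @return List with `per_locus` (numeric vector, `NA` where non-estimable)
#'   and `global` (scalar).
#' @export
fst_weir_cockerham <- function(pair) {
  stopifnot(inherits(pair, "temporal_pair"))
  wc <- wc_components(genotype_class_counts(pair$sample_t0),
                      genotype_class_counts(pair$sample_tau))
  ok <- wc$estimable & !is.na(wc$a)
  denom <- sum(wc$a[ok] + wc$b[ok] + wc$c[ok])
  global <- if (denom == 0) NA_real_ else sum(wc$a[ok]) / denom
  list(per_locus = wc$theta, global = global)
}

#' Multilocus inbreeding coefficient
#'
#' Weir-Cockerham multilocus \eqn{\hat F_{IS}} (their small-f) computed from
#' the two temporal samples treated as two populations:
#' \eqn{\hat f = 1 - \sum_l c_l / \sum_l (b_l + c_l)}.
#'
#' @param pair A [temporal_pair()].
#' @return Scalar in \[-1, 1\].
#' @export
multilocus_fis <- function(pair) {
  stopifnot(inherits(pair, "temporal_pair"))
  wc <- wc_components(genotype_class_counts(pair$sample_t0),
                      genotype_class_counts(pair$sample_tau))
  ok <- wc$estimable & !is.na(wc$b)
  denom <- sum(wc$b[ok] + wc$c[ok])
  if (!any(ok) || denom <= 0) stop("FIS not estimable: no polymorphic loci")
  1 - sum(wc$c[ok]) / denom
}

#' Composite LD between two loci
#'
#' Squared Pearson correlation of genotype dosages (composite LD on unphased
#' genotypes; in a >98% homozygous population dosages are effectively
#' haplotypes). Pairwise-complete observations.
#'
#' @param m A [genotype_matrix()].
#' @param locus_i,locus_j Locus column indices.
#' @return r-squared in \[0, 1\], or `NA` when either locus is monomorphic
#'   among the shared callable samples.
#' @export
ld_r2 <- function(m, locus_i, locus_j) {
  x <- m$geno[, locus_i]; y <- m$geno[, locus_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L || var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

# all pairwise r2 within one chromosome, with distances (kb); used by the
# decay profile and by the clustering accessor
pairwise_r2_chrom <- function(geno, pos) {
  L <- ncol(geno)
  if (L < 2L) return(data.frame(i = integer(), j = integer(),
                                dist_kb = numeric(), r2 = numeric()))
  cm <- suppressWarnings(cor(geno, use = "pairwise.complete.obs"))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             dist_kb = abs(pos[idx[, 2]] - pos[idx[, 1]]) / 1000,
             r2 = cm[idx]^2)
}

#' LD decay profile by distance class
#'
#' Computes r-squared for all within-chromosome marker pairs and averages by
#' distance class. The first class is the sub-25 kb "initial LD" bin; the
#' remaining classes have width `bin_width_kb`.
#'
#' @param m A [genotype_matrix()].
#' @param bin_width_kb Width of the distance classes beyond 25 kb.
#' @param max_dist_kb Pairs farther apart are ignored.
#' @return Data.frame of class `ld_profile`: bin_lo, bin_hi, mid_kb,
#'   mean_r2, sd_r2, n_pairs.
#' @export
ld_decay_profile <- function(m, bin_width_kb = 50, max_dist_kb = 2500) {
  pieces <- lapply(split(seq_len(n_loci(m)), m$chrom), function(idx) {
    pairwise_r2_chrom(m$geno[, idx, drop = FALSE], m$pos[idx])
  })
  pairs <- do.call(rbind, pieces)
  pairs <- pairs[!is.na(pairs$r2) & pairs$dist_kb <= max_dist_kb, , drop = FALSE]
  edges <- unique(c(0, 25, seq(25 + bin_width_kb, max_dist_kb + bin_width_kb,
                               by = bin_width_kb)))
  bin <- cut(pairs$dist_kb, breaks = edges, right = FALSE)
  prof <- data.frame(
    bin_lo = head(edges, -1), bin_hi = tail(edges, -1),
    mid_kb = (head(edges, -1) + tail(edges, -1)) / 2,
    mean_r2 = as.numeric(tapply(pairs$r2, bin, mean)),
    sd_r2 = as.numeric(tapply(pairs$r2, bin, sd)),
    n_pairs = as.integer(table(bin)))
  prof$mean_r2[prof$n_pairs == 0L] <- NA_real_
  class(prof) <- c("ld_profile", "data.frame")
  prof
}

#' Distance at which LD decays below a threshold
#'
#' @param profile An `ld_profile` from [ld_decay_profile()].
#' @param threshold r-squared threshold (0.2 is the usual convention).
#' @return Midpoint distance (kb) of the first occupied distance class whose
#'   mean r-squared falls below the threshold, or `NA` if none does.
#' @export
decay_distance <- function(profile, threshold = 0.2) {
  occ <- !is.na(profile$mean_r2)
  hit <- which(occ & profile$mean_r2 < threshold)
  if (!length(hit)) return(NA_real_)
  profile$mid_kb[hit[1]]
}

#' Initial LD (mean r-squared of the sub-25 kb class)
#' @param profile An `ld_profile`.
#' @export
initial_ld <- function(profile) {
  profile$mean_r2[profile$bin_lo == 0][1]
}
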