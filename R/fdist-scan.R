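# Heterozygosity-based FDist outlier test: the joint (heterozygosity, FST)
# null is simulated with a structured coalescent under a hierarchical island
# model calibrated to the observed global FST; observed loci get
# kernel-density p-values and are classified against empirical one-sided
# quantile envelopes.

#' Heterozygosity-weighted global FST
#'
#' \eqn{\hat F_{ST} = \sum_i w_i \hat F_{STi} / \sum_i w_i} with weights
#' \eqn{w_i = h_{1i} = 1 - \hat f_{1i}}, the between-population
#' heterozygosity of each locus.
#'
#' @param summaries Output of [locus_summaries()].
#' @return Scalar global FST.
#' @export
global_fst_weighted <- function(summaries) {
  w <- summaries$h1_hat
  fst <- summaries$fst_bn
  ok <- !is.na(fst) & !is.na(w) & w > 0
  if (!any(ok)) stop("no locus with positive heterozygosity weight")
  sum(w[ok] * fst[ok]) / sum(w[ok])
}

#' Between-population heterozygosity inferred from the average
#'
#' \eqn{\hat H_1 = \hat h_0 / (1 - \hat F_{ST})}.
#'
#' @param h0 Average within-population heterozygosity.
#' @param fst Global FST (< 1).
#' @export
infer_h1 <- function(h0, fst) {
  if (is.na(fst) || fst >= 1) stop("H1 undefined for FST >= 1")
  h0 / (1 - fst)
}

# summaries of a simulated haploid biallelic partition: derived counts d1, d2
# out of n1, n2 lineages -> (h1, fst_bn) per locus
haploid_cloud_stats <- function(d1, d2, n1, n2) {
  f_pop1 <- homozygosity_unbiased(d1, rep(n1, length(d1)))
  f_pop2 <- homozygosity_unbiased(d2, rep(n2, length(d2)))
  f0 <- (f_pop1 + f_pop2) / 2
  p1 <- d1 / n1; p2 <- d2 / n2
  f1 <- p1 * p2 + (1 - p1) * (1 - p2)
  data.frame(h1 = 1 - f1, fst = (f0 - f1) / (1 - f1))
}

#' Simulate the neutral joint (heterozygosity, FST) cloud
#'
#' For each locus an independent structured-coalescent genealogy of the
#' pooled sample is simulated under the hierarchical island model (k groups
#' of d demes; all sampled lineages come from two demes of one group, one
#' deme per temporal sample), one mutation is placed uniformly on the tree
#' (single-SNP model, so no simulated locus is monomorphic), and the
#' resulting biallelic partition is summarised as (h1, FST) with the same
#' identity-probability estimator used for the observed loci.
#'
#' @param n_sim Number of simulated loci.
#' @param rates List with `m_within` and `m_between`: scaled migration rates
#'   (4Nm) as returned by [calibrate_migration()].
#' @param k_groups,d_demes Hierarchical island dimensions.
#' @param sample_sizes Length-2 haploid sample sizes (lineages per deme).
#' @param seed Optional RNG seed.
#' @return Data.frame of class `fdist_cloud` with columns h1 and fst.
#' @export
simulate_island_null <- function(n_sim, rates, k_groups = 50, d_demes = 10,
                                 sample_sizes = c(100, 100), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_sim >= 1, length(sample_sizes) == 2)
  cnt <- .island_cloud_cpp(as.integer(n_sim), as.integer(k_groups),
                           as.integer(d_demes),
                           as.integer(sample_sizes[1]),
                           as.integer(sample_sizes[2]),
                           rates$m_within, rates$m_between)
  cloud <- haploid_cloud_stats(cnt[, 1], cnt[, 2],
                               sample_sizes[1], sample_sizes[2])
  class(cloud) <- c("fdist_cloud", "data.frame")
  cloud
}

#' Calibrate island-model migration rates to a target global FST
#'
#' Bisection on the scaled within-group migration rate (log scale), with the
#' between-group rate held at a fixed fraction of it, until the
#' heterozygosity-weighted mean FST of a pilot simulation matches the target
#' within 10% relative. The closed-form island expectation
#' \eqn{F_{ST} \approx 1 / (1 + M (d/(d-1))^2)} seeds the search.
#'
#' @param target_fst Global FST to reproduce, in (0, 1).
#' @param k_groups,d_demes Island-model dimensions.
#' @param sample_sizes Haploid sample sizes for the pilot clouds.
#' @param ratio_between Between-group rate as a fraction of the within-group
#'   rate (villages interact preferentially with themselves; default 1:10).
#' @param n_pilot Pilot loci per evaluation (>= 2000 recommended).
#' @param rel_tol Relative tolerance on the pilot mean.
#' @param max_iter Bisection iterations before giving up.
#' @param seed Optional RNG seed.
#' @return List with `m_within`, `m_between`, `achieved_fst`, `n_eval`.
#' @export
calibrate_migration <- function(target_fst, k_groups = 50, d_demes = 10,
                                sample_sizes = c(100, 100),
                                ratio_between = 0.1, n_pilot = 2000,
                                rel_tol = 0.10, max_iter = 14, seed = NULL) {
  if (is.na(target_fst) || target_fst <= 0 || target_fst >= 1) {
    stop("target_fst must lie in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  pilot_fst <- function(m_w) {
    cloud <- simulate_island_null(n_pilot,
                                  list(m_within = m_w,
                                       m_between = m_w * ratio_between),
                                  k_groups, d_demes, sample_sizes)
    ok <- cloud$h1 > 0 & !is.na(cloud$fst)
    sum(cloud$h1[ok] * cloud$fst[ok]) / sum(cloud$h1[ok])
  }
  corr <- (d_demes / (d_demes - 1))^2
  m0 <- max((1 / target_fst - 1) / corr, 1e-4)
  lo <- m0 / 50; hi <- m0 * 50  # FST is decreasing in the migration rate
  n_eval <- 0L
  mid <- m0
  for (iter in seq_len(max_iter)) {
    f_mid <- pilot_fst(mid); n_eval <- n_eval + 1L
    if (abs(f_mid - target_fst) <= rel_tol * target_fst) {
      return(list(m_within = mid, m_between = mid * ratio_between,
                  achieved_fst = f_mid, n_eval = n_eval))
    }
    if (f_mid > target_fst) lo <- mid else hi <- mid
    if (hi / lo < 1.0001) break
    mid <- sqrt(lo * hi)
  }
  stop(sprintf(
    "migration calibration failed: target FST %.4g, last achieved %.4g",
    target_fst, f_mid))
}

#' Kernel-density p-value for one locus against the null cloud
#'
#' One-sided (upper-tail) probability of a simulated FST at least as large
#' as the observed one, conditional on heterozygosity near the observed h1:
#' cloud points are weighted by a Gaussian kernel on the heterozygosity axis
#' (bandwidth: Silverman's rule on the cloud's h1 values unless supplied).
#' The p-value is floored at 1/(n_points + 1).
#'
#' @param cloud An `fdist_cloud` (>= 1000 points for stable estimates).
#' @param h1_obs,fst_obs Observed locus heterozygosity and FST.
#' @param bandwidth Optional kernel bandwidth override.
#' @return Scalar p-value, or `NA` (with a warning) when `h1_obs` lies
#'   outside the simulated heterozygosity support.
#' @export
kernel_pvalue <- function(cloud, h1_obs, fst_obs, bandwidth = NULL) {
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(cloud$h1)
  if (is.na(h1_obs) || h1_obs < min(cloud$h1) || h1_obs > max(cloud$h1)) {
    warning("observed heterozygosity outside the simulated support")
    return(NA_real_)
  }
  w <- dnorm((cloud$h1 - h1_obs) / bandwidth)
  p <- sum(w * (cloud$fst >= fst_obs)) / sum(w)
  n <- nrow(cloud)
  min(max(p, 1 / (n + 1)), 1)
}

#' Empirical FST quantile envelope over heterozygosity bins
#'
#' For a grid of heterozygosity bins, the empirical upper (1 - alpha) FST
#' quantile of the null cloud; bins with fewer than `min_points` points get
#' a missing envelope value. Used to classify observed loci as beyond the 1%
#' or 5% one-sided confidence limits.
#'
#' @param cloud An `fdist_cloud`.
#' @param alpha Upper-tail probability in (0, 0.5\].
#' @param n_bins Number of equal-width heterozygosity bins.
#' @param min_points Minimum cloud points per bin.
#' @return Data.frame: h1_lo, h1_hi, h1_mid, fst_q, n_points; the bin breaks
#'   are attached as attribute `"breaks"`.
#' @export
quantile_envelope <- function(cloud, alpha, n_bins = 25, min_points = 50) {
  stopifnot(alpha > 0, alpha <= 0.5)
  breaks <- seq(min(cloud$h1), max(cloud$h1), length.out = n_bins + 1)
  bin <- cut(cloud$h1, breaks, include.lowest = TRUE)
  qs <- tapply(cloud$fst, bin, quantile, probs = 1 - alpha, names = FALSE)
  n <- as.integer(table(bin))
  qs[n < min_points] <- NA_real_
  out <- data.frame(h1_lo = head(breaks, -1), h1_hi = tail(breaks, -1),
                    h1_mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
                    fst_q = as.numeric(qs), n_points = n)
  attr(out, "breaks") <- breaks
  attr(out, "alpha") <- alpha
  out
}

#' Classify loci against 5% and 1% quantile envelopes
#'
#' Assigns each (h1, FST) pair to `"ns"`, `"sig5"` (beyond the 5% limit but
#' not the 1% limit) or `"sig1"` (beyond the 1% limit), using envelopes from
#' [quantile_envelope()] that share the same heterozygosity breaks. Loci
#' falling in a bin without an envelope value (outside the simulated
#' support, or too few simulated points) are `NA`.
#'
#' @param h1,fst Observed per-locus total heterozygosity and FST.
#' @param env5,env1 Envelopes at alpha = 0.05 and 0.01.
#' @return Character vector of classes.
#' @export
classify_envelope <- function(h1, fst, env5, env1) {
  breaks <- attr(env5, "breaks")
  bin <- findInterval(h1, breaks, rightmost.closed = TRUE)
  bin[bin < 1 | bin > nrow(env5)] <- NA_integer_
  q5 <- env5$fst_q[bin]
  q1 <- env1$fst_q[bin]
  cls <- rep("ns", length(h1))
  cls[!is.na(q5) & !is.na(fst) & fst > q5] <- "sig5"
  cls[!is.na(q1) & !is.na(fst) & fst > q1] <- "sig1"
  cls[is.na(bin) | is.na(fst)] <- "ns"
  cls
}

#' FDist-style heterozygosity-based genome scan
#'
#' Orchestrates the heterozygosity-based outlier test on a temporal pair:
#' per-locus identity summaries, heterozygosity-weighted global FST,
#' migration-rate calibration of the hierarchical island model to that
#' global FST, coalescent simulation of the neutral (h1, FST) cloud, and
#' per-locus kernel p-values plus classification against the 5% and 1%
#' one-sided envelopes (`ns`, `sig5`, `sig1`). Calibration targets below
#' 0.005 are floored at 0.005 (the panmixia limit of the island model at
#' practical migration rates).
#'
#' @param pair A filtered [temporal_pair()].
#' @param k_groups,d_demes Island-model dimensions (50 and 10 mimic many
#'   villages holding few varieties each).
#' @param n_sim Simulated loci for the null cloud (50,000 at full scale;
#'   5,000 is a desk-scale default).
#' @param ratio_between,n_pilot Passed to [calibrate_migration()].
#' @param n_bins Heterozygosity bins for the envelopes.
#' @param seed Optional RNG seed.
#' @return Object of class `fdist_result`: list with `fst_global`, `h1_global`,
#'   `rates`, `cloud`, `env5`, `env1` and `table` (chrom, pos, h1_hat, fst,
#'   p, class, method).
#' @export
fdist_scan <- function(pair, k_groups = 50, d_demes = 10, n_sim = 5000,
                       ratio_between = 0.1, n_pilot = 2000, n_bins = 25,
                       seed = NULL) {
  stopifnot(inherits(pair, "temporal_pair"))
  if (!is.null(seed)) set.seed(seed)
  summaries <- locus_summaries(pair)
  fst_global <- global_fst_weighted(summaries)
  h0_bar <- mean(summaries$h0_hat, na.rm = TRUE)
  h1_global <- infer_h1(h0_bar, max(fst_global, 0))
  target <- max(fst_global, 0.005)
  sizes <- c(2L * n_samples(pair$sample_t0), 2L * n_samples(pair$sample_tau))
  rates <- calibrate_migration(target, k_groups, d_demes, sizes,
                               ratio_between = ratio_between,
                               n_pilot = n_pilot)
  cloud <- simulate_island_null(n_sim, rates, k_groups, d_demes, sizes)
  env5 <- quantile_envelope(cloud, 0.05, n_bins = n_bins)
  env1 <- quantile_envelope(cloud, 0.01, n_bins = n_bins)

  bw <- stats::bw.nrd0(cloud$h1)
  lo <- min(cloud$h1); hi <- max(cloud$h1)
  p <- rep(NA_real_, nrow(summaries))
  flo <- 1 / (nrow(cloud) + 1)
  n_outside <- 0L
  for (i in seq_len(nrow(summaries))) {
    h1o <- summaries$h1_hat[i]; fo <- summaries$fst_bn[i]
    if (is.na(h1o) || is.na(fo)) next
    if (h1o < lo || h1o > hi) { n_outside <- n_outside + 1L; next }
    w <- dnorm((cloud$h1 - h1o) / bw)
    p[i] <- min(max(sum(w * (cloud$fst >= fo)) / sum(w), flo), 1)
  }
  if (n_outside > 0L) {
    warning(n_outside,
            " locus/loci outside the simulated heterozygosity support")
  }
  cls <- classify_envelope(summaries$h1_hat, summaries$fst_bn, env5, env1)
  tab <- data.frame(chrom = summaries$chrom, pos = summaries$pos,
                    locus_id = summaries$locus_id,
                    h1_hat = summaries$h1_hat, fst = summaries$fst_bn,
                    p = p, q = NA_real_, class = cls, method = "fdist",
                    stringsAsFactors = FALSE)
  structure(list(fst_global = fst_global, h1_global = h1_global,
                 target_fst = target, rates = rates, n_sim = n_sim,
                 cloud = cloud, env5 = env5, env1 = env1, table = tab),
            class = "fdist_result")
}

#' @export
print.fdist_result <- function(x, ...) {
  cat("<fdist_result>\n")
  cat(sprintf("  global FST (weighted) = %.5f  H1_hat = %.4f\n",
              x$fst_global, x$h1_global))
  cat(sprintf("  cloud: %d loci, calibrated 4Nm within/between = %.3g/%.3g (achieved FST %.4f)\n",
              nrow(x$cloud), x$rates$m_within, x$rates$m_between,
              x$rates$achieved_fst))
  cat(sprintf("  observed loci: %d  sig5: %d  sig1: %d\n",
              nrow(x$table), sum(x$table$class == "sig5"),
              sum(x$table$class == "sig1")))
  invisible(x)
}

#' @export
as.data.frame.fdist_result <- function(x, ...) x$table

#' Plot the joint (heterozygosity, FST) cloud with confidence envelopes
#'
#' Observed loci over the 5% and 1% one-sided envelope curves, colour-coded
#' by significance class. Requires ggplot2.
#'
#' @param result An `fdist_result`.
#' @export
plot_fdist_cloud <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  tab <- result$table
  env <- rbind(cbind(result$env5, limit = "5%"),
               cbind(result$env1, limit = "1%"))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = env[!is.na(env$fst_q), ],
                       ggplot2::aes(x = h1_mid, y = fst_q,
                                    linetype = limit)) +
    ggplot2::geom_point(data = tab,
                        ggplot2::aes(x = h1_hat, y = fst,
                                     colour = class), alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(ns = "grey40", sig5 = "blue",
                                            sig1 = "red")) +
    ggplot2::labs(x = "heterozygosity between populations (h1)",
                  y = expression(F[ST]))
}
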