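# Drift-based temporal outlier test for partially selfing populations:
# per-locus null distributions of Weir-Cockerham FST generated by simulating
# binomial genetic drift at the genome-wide effective size, with genotype
# sampling structured by the multilocus inbreeding coefficient.

#' Effective population size from temporal FST
#'
#' \eqn{\hat N_e = \tau (1 - \hat F_{ST}) / (4 \hat F_{ST})}, where
#' \eqn{\hat F_{ST}} is the global Weir-Cockerham estimate between the two
#' temporal samples and \eqn{\tau} the number of generations separating them.
#' Under partial selfing this is the variance effective size, roughly
#' census size / (1 + FIS).
#'
#' @param fst_temporal Global temporal FST (> 0).
#' @param tau Generations between samples.
#' @return Scalar effective size estimate.
#' @export
estimate_ne <- function(fst_temporal, tau) {
  if (is.na(fst_temporal) || fst_temporal <= 0) {
    stop("Ne not estimable: temporal FST must be > 0")
  }
  tau * (1 - fst_temporal) / (4 * fst_temporal)
}

# vectorised multinomial draw of genotype-class counts: n trials with class
# probabilities (g0, g1, g2) per row; returns a k x 3 matrix
rmultinom3 <- function(n, g0, g1, g2) {
  k <- length(g0)
  n <- rep_len(n, k)
  x2 <- rbinom(k, n, pmin(pmax(g2, 0), 1))
  rest <- n - x2
  p1 <- ifelse(g2 >= 1, 0, g1 / (1 - g2))
  x1 <- rbinom(k, rest, pmin(pmax(p1, 0), 1))
  cbind(n0 = rest - x1, n1 = x1, n2 = x2)
}

# genotype-class frequencies from allele frequency pi and inbreeding F
genotype_freqs_from_pi <- function(pi, f) {
  q <- 1 - pi
  cbind(g0 = q^2 + f * pi * q,
        g1 = 2 * pi * q * (1 - f),
        g2 = pi^2 + f * pi * q)
}

#' Simulate null temporal FST draws for one locus
#'
#' One draw of the drift null: genotype frequencies at time 0 are drawn from
#' the posterior Dirichlet(K0 + 1) given the observed genotype counts; both
#' samples are then resampled -- the time-0 sample from Mult(n0, gamma0) and
#' the time-tau sample from Mult(n_tau, gamma_tau), where the allele
#' frequency drifts for tau generations as
#' \eqn{\pi_t \sim Binomial(2 N_e, \pi_{t-1}) / (2 N_e)} and gamma_tau
#' combines \eqn{\pi_\tau} with the inbreeding coefficient
#' (F clipped to \[0, 1\]). Returns the Weir-Cockerham FST between the two
#' simulated samples; draws in which the pooled simulated sample is
#' monomorphic are non-estimable and returned as `NA`.
#'
#' @param K0 Length-3 observed genotype-class counts (n0, n1, n2 = carriers
#'   of 0/1/2 copies of the alternate allele) at time 0.
#' @param n_tau Sample size (individuals) at time tau.
#' @param ne Effective population size driving the drift chain; 2*ne is
#'   rounded to the nearest even integer >= 2.
#' @param fis Multilocus inbreeding coefficient (clipped to \[0, 1\] when
#'   constructing genotype frequencies).
#' @param tau Number of generations of drift.
#' @param n_draws Number of independent null draws to return.
#' @param n0 Sample size at time 0 (defaults to `sum(K0)`).
#' @return Numeric vector of `n_draws` simulated FST values.
#' @export
simulate_null_fst <- function(K0, n_tau, ne, fis, tau, n_draws = 1,
                              n0 = sum(K0)) {
  stopifnot(length(K0) == 3L, all(K0 >= 0), ne >= 1, tau >= 1, n_draws >= 1)
  two_ne <- max(2L, 2L * as.integer(round(ne)))
  f <- min(max(fis, 0), 1)
  # gamma0 ~ Dir(K0 + 1) via normalised gammas
  g <- cbind(rgamma(n_draws, K0[1] + 1), rgamma(n_draws, K0[2] + 1),
             rgamma(n_draws, K0[3] + 1))
  g <- g / rowSums(g)
  k0_star <- rmultinom3(n0, g[, 1], g[, 2], g[, 3])
  pi <- g[, 3] + g[, 2] / 2
  for (t in seq_len(tau)) {
    pi <- rbinom(n_draws, two_ne, pi) / two_ne
  }
  gt <- genotype_freqs_from_pi(pi, f)
  kt_star <- rmultinom3(n_tau, gt[, 1], gt[, 2], gt[, 3])
  wc_components(k0_star, kt_star)$theta
}

#' Empirical false-discovery-rate q-values
#'
#' @param p Vector of p-values in (0, 1\].
#' @param method `"bh"` (Benjamini-Hochberg, default) or `"storey"`
#'   (BH rescaled by a fixed-lambda estimate of the null proportion,
#'   \eqn{\hat\pi_0 = \min(1, \; mean(p > 0.5) / 0.5)}).
#' @return Vector of q-values, same order as `p`.
#' @export
qvalues <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (!length(p)) stop("empty p-value vector")
  stopifnot(all(is.na(p) | (p > 0 & p <= 1)))
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5, na.rm = TRUE) / 0.5)
    q <- pmin(q * pi0, 1)
  }
  q
}

#' Drift-based temporal genome scan
#'
#' Estimates the global temporal FST and effective size once, then builds a
#' per-locus null distribution of FST by drift simulation
#' ([simulate_null_fst()]) and computes empirical upper-tail p-values
#' \eqn{\hat p = (1 + \#\{F^*_{ST} \ge F^l_{ST}\}) / (1 + n_{sim})}.
#' Simulated draws that are non-estimable do not count toward the tail.
#' Loci monomorphic in the pooled pair are skipped (`NA`, excluded from the
#' FDR correction). Loci with q-value below `q_threshold` are flagged
#' significant.
#'
#' @param pair A filtered [temporal_pair()].
#' @param n_sim Null draws per locus (the full-scale analysis uses 50,000;
#'   1,000 is a desk-scale default).
#' @param tau Generations between samples (defaults to `pair$tau`).
#' @param fdr_method Passed to [qvalues()].
#' @param q_threshold Significance threshold on the q-value.
#' @param seed Optional RNG seed.
#' @param keep_draws If `TRUE`, the simulated null FST draws are returned
#'   (`L x n_sim` matrix) for audit.
#'
#' @return Object of class `drift_scan_result`: a list with `ne_hat`,
#'   `fst_temporal`, `fis_hat`, `n_sim`, and `table` (per-locus chrom, pos,
#'   fst, p, q, class, method).
#' @export
drift_scan <- function(pair, n_sim = 1000, tau = NULL,
                       fdr_method = c("bh", "storey"), q_threshold = 0.05,
                       seed = NULL, keep_draws = FALSE) {
  stopifnot(inherits(pair, "temporal_pair"), n_sim >= 100)
  fdr_method <- match.arg(fdr_method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tau)) tau <- pair$tau

  obs <- fst_weir_cockerham(pair)
  if (is.na(obs$global) || obs$global <= 0) {
    stop("scan aborted: global temporal FST <= 0, Ne not estimable")
  }
  ne_hat <- estimate_ne(obs$global, tau)
  fis_hat <- multilocus_fis(pair)

  c0 <- genotype_class_counts(pair$sample_t0)
  c1 <- genotype_class_counts(pair$sample_tau)
  L <- nrow(c0)
  p <- rep(NA_real_, L)
  draws <- if (keep_draws) matrix(NA_real_, L, n_sim) else NULL
  for (l in seq_len(L)) {
    fobs <- obs$per_locus[l]
    if (is.na(fobs)) next                  # monomorphic / non-estimable
    sim <- simulate_null_fst(c0[l, ], n_tau = sum(c1[l, ]), ne = ne_hat,
                             fis = fis_hat, tau = tau, n_draws = n_sim)
    p[l] <- (1 + sum(sim >= fobs, na.rm = TRUE)) / (1 + n_sim)
    if (keep_draws) draws[l, ] <- sim
  }
  q <- rep(NA_real_, L)
  ok <- !is.na(p)
  q[ok] <- qvalues(p[ok], method = fdr_method)
  tab <- data.frame(chrom = pair$sample_t0$chrom, pos = pair$sample_t0$pos,
                    locus_id = pair$sample_t0$locus_ids,
                    fst = obs$per_locus, p = p, q = q,
                    class = ifelse(!is.na(q) & q < q_threshold, "sig", "ns"),
                    method = "drift", stringsAsFactors = FALSE)
  structure(list(ne_hat = ne_hat, fst_temporal = obs$global,
                 fis_hat = fis_hat, n_sim = n_sim, tau = tau,
                 table = tab, draws = draws),
            class = "drift_scan_result")
}

#' @export
print.drift_scan_result <- function(x, ...) {
  cat("<drift_scan_result>\n")
  cat(sprintf("  temporal FST = %.5f  Ne_hat = %.1f  FIS_hat = %.3f\n",
              x$fst_temporal, x$ne_hat, x$fis_hat))
  cat(sprintf("  %d loci, %d significant (q < 0.05), n_sim = %d\n",
              nrow(x$table), sum(x$table$class == "sig"), x$n_sim))
  invisible(x)
}

#' @export
as.data.frame.drift_scan_result <- function(x, ...) x$table
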