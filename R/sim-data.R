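# Forward individual-based simulator of a partially selfing population
# sampled at two time points, plus matching climate and phenotype generators.
# This is the synthetic data source for the whole pipeline.

#' Simulate two temporal samples of a partially selfing population
#'
#' Forward individual-based simulation of a diploid Wright-Fisher population
#' of census size `ne`. Each offspring is produced by selfing with
#' probability `selfing_rate`, otherwise by outcrossing between two distinct
#' parents. Selection is fertility selection: a parent's sampling weight is
#' multiplied by `(1 + sel_coef)` per copy of the favoured (alternate) allele
#' it carries at each selected locus. Loci are unlinked by default; the
#' linked mode places recombination between neighbouring loci on the same
#' chromosome (Haldane map from physical distance) so LD profiles can be
#' exercised. Samples of `n0` and `n_tau` individuals are drawn without
#' replacement at generations 0 and `tau`.
#'
#' Initial alternate-allele frequencies are drawn from a U-shaped
#' Beta(0.5, 0.5) truncated at MAF 0.01, mimicking a MAF-filtered GBS panel,
#' and initial genotypes are at the selfing-equilibrium inbreeding
#' coefficient F = s/(2 - s).
#'
#' @param n_loci Number of biallelic loci.
#' @param ne Census population size (diploid individuals).
#' @param selfing_rate Probability an offspring is selfed.
#' @param tau Generations between the two samples.
#' @param n0,n_tau Sample sizes at generation 0 and tau.
#' @param selected Integer indices of loci under directional selection.
#' @param sel_coef Multiplicative fitness advantage per favoured allele copy.
#' @param maf_min Truncation of the initial allele-frequency distribution.
#' @param missing_rate Fraction of genotype calls set to missing in the
#'   emitted samples (0 = complete data, as after imputation).
#' @param linkage `"unlinked"` (default; loci transmitted independently) or
#'   `"linked"` (recombination along chromosomes).
#' @param cM_per_Mb Recombination rate used in linked mode.
#' @param seed Optional RNG seed.
#'
#' @return A [temporal_pair()] whose `truth` element records the selected
#'   indices and the population allele-frequency trajectories (a
#'   `(tau + 1) x n_loci` matrix).
#' @export
simulate_temporal_population <- function(n_loci = 1000, ne = 500,
                                         selfing_rate = 0.95, tau = 31,
                                         n0 = 100, n_tau = 100,
                                         selected = integer(0), sel_coef = 0,
                                         maf_min = 0.01, missing_rate = 0,
                                         linkage = c("unlinked", "linked"),
                                         cM_per_Mb = 4, seed = NULL) {
  linkage <- match.arg(linkage)
  if (!is.null(seed)) set.seed(seed)
  if (ne < 2) stop("ne must be >= 2")
  stopifnot(selfing_rate >= 0, selfing_rate <= 1, sel_coef >= 0,
            n0 <= ne, n_tau <= ne, tau >= 1)
  selected <- as.integer(selected)
  if (length(selected) && (min(selected) < 1L || max(selected) > n_loci)) {
    stop("selected indices out of range")
  }

  # genome coordinates: loci spread over the 12 rice chromosomes
  chr_len <- irgsp1_chrom_lengths()
  chrom_of <- sample(names(chr_len), n_loci, replace = TRUE,
                     prob = chr_len / sum(chr_len))
  pos <- integer(n_loci)
  for (ch in unique(chrom_of)) {
    idx <- chrom_of == ch
    pos[idx] <- sort(sample.int(chr_len[[ch]], sum(idx)))
  }
  ord <- order(chrom_of, pos)
  chrom_of <- chrom_of[ord]; pos <- pos[ord]
  sel_mask <- seq_len(n_loci) %in% selected  # indices refer to sorted order

  # initial frequencies, truncated U-shaped
  p <- rbeta(n_loci, 0.5, 0.5)
  while (any(bad <- pmin(p, 1 - p) < maf_min)) {
    p[bad] <- rbeta(sum(bad), 0.5, 0.5)
  }

  # initial diploid genotypes at selfing-equilibrium FIS
  f_eq <- selfing_rate / (2 - selfing_rate)
  pm <- matrix(p, nrow = ne, ncol = n_loci, byrow = TRUE)
  g_aa <- pm^2 + f_eq * pm * (1 - pm)
  g_het <- 2 * pm * (1 - pm) * (1 - f_eq)
  u <- matrix(runif(ne * n_loci), ne, n_loci)
  dose <- matrix(0L, ne, n_loci)
  dose[u < g_aa] <- 2L
  dose[u >= g_aa & u < g_aa + g_het] <- 1L
  h1 <- matrix(0L, ne, n_loci); h2 <- matrix(0L, ne, n_loci)
  h1[dose >= 1L] <- 1L
  h2[dose == 2L] <- 1L

  # recombination fractions between neighbouring loci (linked mode)
  rec <- NULL
  if (linkage == "linked") {
    d_mb <- c(0, diff(pos)) / 1e6
    new_chr <- c(TRUE, chrom_of[-1] != chrom_of[-n_loci])
    morgans <- d_mb * cM_per_Mb / 100
    rec <- 0.5 * (1 - exp(-2 * morgans))  # Haldane
    rec[new_chr] <- 0.5
  }

  draw_gamete <- function(h1, h2, parents) {
    a <- h1[parents, , drop = FALSE]
    b <- h2[parents, , drop = FALSE]
    if (is.null(rec)) {
      pick <- matrix(runif(length(parents) * n_loci) < 0.5,
                     length(parents), n_loci)
    } else {
      sw <- matrix(runif(length(parents) * n_loci), length(parents), n_loci) <
        matrix(rec, length(parents), n_loci, byrow = TRUE)
      # cumulative XOR along loci: switch parental strand where sw is TRUE
      state <- runif(length(parents)) < 0.5
      pick <- matrix(FALSE, length(parents), n_loci)
      for (j in seq_len(n_loci)) {
        state <- xor(state, sw[, j])
        pick[, j] <- state
      }
    }
    out <- a
    out[pick] <- b[pick]
    out
  }

  freq <- matrix(NA_real_, tau + 1, n_loci)
  freq[1, ] <- colMeans(h1 + h2) / 2

  idx0 <- sample.int(ne, n0)
  samp0 <- (h1 + h2)[idx0, , drop = FALSE]

  for (t in seq_len(tau)) {
    w <- if (any(sel_mask) && sel_coef > 0) {
      (1 + sel_coef)^rowSums((h1 + h2)[, sel_mask, drop = FALSE])
    } else rep(1, ne)
    par1 <- sample.int(ne, ne, replace = TRUE, prob = w)
    is_self <- runif(ne) < selfing_rate
    par2 <- par1
    if (any(!is_self)) {
      out_idx <- which(!is_self)
      par2[out_idx] <- sample.int(ne, length(out_idx), replace = TRUE, prob = w)
      clash <- which(!is_self & par2 == par1)
      while (length(clash)) {
        par2[clash] <- sample.int(ne, length(clash), replace = TRUE, prob = w)
        clash <- clash[par2[clash] == par1[clash]]
      }
    }
    new_h1 <- draw_gamete(h1, h2, par1)
    new_h2 <- draw_gamete(h1, h2, par2)
    h1 <- new_h1; h2 <- new_h2
    freq[t + 1, ] <- colMeans(h1 + h2) / 2
  }

  idx1 <- sample.int(ne, n_tau)
  samp1 <- (h1 + h2)[idx1, , drop = FALSE]

  if (missing_rate > 0) {
    samp0[matrix(runif(length(samp0)) < missing_rate, nrow(samp0))] <- NA_integer_
    samp1[matrix(runif(length(samp1)) < missing_rate, nrow(samp1))] <- NA_integer_
  }

  gm0 <- genotype_matrix(samp0, chrom_of, pos,
                         sample_ids = sprintf("C1_%03d", seq_len(n0)),
                         population = rep("collect1", n0))
  gm1 <- genotype_matrix(samp1, chrom_of, pos,
                         sample_ids = sprintf("C2_%03d", seq_len(n_tau)),
                         population = rep("collect2", n_tau))
  temporal_pair(gm0, gm1, tau,
                truth = list(selected = which(sel_mask), freq = freq,
                             selfing_rate = selfing_rate, ne = ne,
                             sel_coef = sel_coef))
}

#' Simulate a monthly climate series
#'
#' Monthly values are a fixed seasonal profile plus a linear trend plus
#' Gaussian noise. The default rain profile is a single-peak monsoon regime
#' (June-October wet season) typical of the West African stations the
#' anomaly analysis targets.
#'
#' @param years Integer vector of years.
#' @param variable `"rain"` (mm), `"tmin"` or `"tmax"` (degrees C).
#' @param trend_per_decade Linear trend added per decade (same units as the
#'   variable, applied to every month).
#' @param sd_noise Gaussian noise standard deviation per month.
#' @param profile Optional length-12 seasonal profile overriding the default.
#' @param station Station label.
#' @param seed Optional RNG seed.
#' @return Data.frame of class `climate_series`: station, variable, year,
#'   month, value.
#' @export
simulate_climate_series <- function(years, variable = c("rain", "tmin", "tmax"),
                                    trend_per_decade = 0, sd_noise = 0,
                                    profile = NULL, station = "synthetic",
                                    seed = NULL) {
  variable <- match.arg(variable)
  if (!length(years)) stop("years must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(profile)) {
    profile <- switch(variable,
      rain = c(5, 10, 40, 90, 160, 230, 290, 310, 260, 150, 30, 8),
      tmin = c(18, 19, 21, 22, 22, 21.5, 21, 20.8, 21, 21, 20, 18.5),
      tmax = c(33, 34.5, 35, 34, 32.5, 31, 29.5, 29, 30, 31.5, 32, 32.5))
  }
  stopifnot(length(profile) == 12L)
  grid <- expand.grid(month = 1:12, year = as.integer(years))
  decades <- (grid$year - min(years)) / 10
  value <- profile[grid$month] + trend_per_decade * decades +
    rnorm(nrow(grid), 0, sd_noise)
  if (variable == "rain") value <- pmax(value, 0)
  out <- data.frame(station = station, variable = variable,
                    year = grid$year, month = grid$month, value = value,
                    stringsAsFactors = FALSE)
  class(out) <- c("climate_series", "data.frame")
  out
}

#' Simulate days-to-heading phenotype records
#'
#' Gaussian DTHD per accession with programmed group-by-collect means; the
#' noise in each group-by-collect cell is centred so realized cell means
#' equal the programmed means exactly. The
#' default design encodes the study conditions of the landrace panel this
#' package emulates: three genetic groups (Og, Osi, Osj), two collects
#' roughly 30 years apart, a 10.3-day heading advance in Og, 3.4 days in
#' Osj, a 4.27-day delay in Osi, and a 12-day within-group standard
#' deviation.
#'
#' @param n_per_group 3 x 2 matrix of sample sizes (rows Og, Osi, Osj;
#'   columns collect 1, 2).
#' @param means 3 x 2 matrix of group-by-collect mean DTHD (days).
#' @param sd_days Residual standard deviation (days).
#' @param seed Optional RNG seed.
#' @return Data.frame of phenotype records: accession, group, collect, dthd.
#' @export
simulate_phenotypes <- function(n_per_group = NULL, means = NULL, sd_days = 12,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sd_days >= 0)
  groups <- c("Og", "Osi", "Osj")
  if (is.null(n_per_group)) {
    n_per_group <- matrix(c(59, 85, 73, 180, 107, 147), nrow = 3, byrow = TRUE,
                          dimnames = list(groups, c("c1", "c2")))
  }
  if (is.null(means)) {
    means <- matrix(c(150.1, 139.8, 114.67, 118.94, 107.7, 104.3),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(groups, c("c1", "c2")))
  }
  rows <- list()
  for (g in seq_along(groups)) {
    for (col in 1:2) {
      n <- n_per_group[g, col]
      # centred noise: each group-by-collect cell reproduces its target
      # mean exactly, so contrasts of cell means are deterministic while
      # within-cell spread stays stochastic
      noise <- rnorm(n, 0, sd_days)
      rows[[length(rows) + 1L]] <- data.frame(
        accession = sprintf("%s-%d_%03d", groups[g], col, seq_len(n)),
        group = groups[g], collect = col,
        dthd = means[g, col] + noise - mean(noise),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
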