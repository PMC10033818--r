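test_that("simulator output is well-formed and seed-reproducible", {
  a <- simulate_temporal_population(n_loci = 50, ne = 40, tau = 5,
                                    n0 = 10, n_tau = 12, seed = 3)
  b <- simulate_temporal_population(n_loci = 50, ne = 40, tau = 5,
                                    n0 = 10, n_tau = 12, seed = 3)
  expect_s3_class(a, "temporal_pair")
  expect_identical(a$sample_t0$geno, b$sample_t0$geno)
  expect_identical(a$sample_tau$geno, b$sample_tau$geno)
  expect_identical(a$sample_t0$pos, a$sample_tau$pos)
  expect_identical(dim(a$truth$freq), c(6L, 50L))
  expect_true(all(a$sample_t0$geno %in% 0:2))
  expect_error(simulate_temporal_population(ne = 1), "ne must be >= 2")
  expect_error(simulate_temporal_population(n_loci = 10, selected = 11L),
               "out of range")
})

test_that("no-drift limit: huge ne, minimal tau gives near-zero FST", {
  pair <- simulate_temporal_population(n_loci = 400, ne = 5000, tau = 1,
                                       selfing_rate = 0.95,
                                       n0 = 150, n_tau = 150, seed = 11)
  pair <- filter_loci(pair)$pair
  fst <- fst_weir_cockerham(pair)$global
  expect_lt(abs(fst), 0.01)
})

test_that("selfing closure: fully homozygous start stays homozygous", {
  pair <- simulate_temporal_population(n_loci = 100, ne = 50,
                                       selfing_rate = 1, tau = 20,
                                       n0 = 25, n_tau = 25, seed = 4)
  expect_true(all(pair$sample_t0$geno != 1L))
  expect_true(all(pair$sample_tau$geno != 1L))
})

test_that("neutral drift matches E(FST) ~ tau/(tau + 4*Ne) at selfing 0", {
  fst <- vapply(1:10, function(i) {
    pair <- simulate_temporal_population(n_loci = 500, ne = 300,
                                         selfing_rate = 0, tau = 31,
                                         n0 = 100, n_tau = 100,
                                         seed = 5000 + i)
    pair <- filter_loci(pair, het_max = 1)$pair
    fst_weir_cockerham(pair)$global
  }, numeric(1))
  expected <- 31 / (31 + 4 * 300)
  expect_lt(abs(mean(fst) - expected), 0.3 * expected)
})

test_that("selected-allele frequency gain increases with sel_coef", {
  gain <- function(s) {
    mean(vapply(1:5, function(i) {
      pair <- simulate_temporal_population(
        n_loci = 60, ne = 200, selfing_rate = 0.95, tau = 15,
        n0 = 50, n_tau = 50, selected = 1:10, sel_coef = s,
        seed = 900 + i)
      fr <- pair$truth$freq
      mean(fr[nrow(fr), pair$truth$selected] - fr[1, pair$truth$selected])
    }, numeric(1)))
  }
  g <- c(gain(0), gain(0.2), gain(1))
  expect_lt(g[1], g[2])
  expect_lt(g[2], g[3])
})

test_that("linked mode yields higher short-range LD than unlinked mode", {
  args <- list(n_loci = 300, ne = 100, selfing_rate = 0.95, tau = 10,
               n0 = 80, n_tau = 80, seed = 21)
  unl <- do.call(simulate_temporal_population, c(args, linkage = "unlinked"))
  lin <- do.call(simulate_temporal_population, c(args, linkage = "linked"))
  short_ld <- function(pair) {
    gm <- temposcan:::rbind_genotypes(pair$sample_t0, pair$sample_tau)
    gm <- filter_loci(gm)$genotypes
    prof <- ld_decay_profile(gm, bin_width_kb = 500, max_dist_kb = 1000)
    weighted.mean(prof$mean_r2, prof$n_pairs, na.rm = TRUE)
  }
  expect_gt(short_ld(lin), short_ld(unl))
})

test_that("missing_rate introduces missing calls", {
  pair <- simulate_temporal_population(n_loci = 100, ne = 50, tau = 3,
                                       n0 = 30, n_tau = 30,
                                       missing_rate = 0.2, seed = 8)
  frac <- mean(is.na(pair$sample_t0$geno))
  expect_gt(frac, 0.1); expect_lt(frac, 0.3)
})

test_that("flat zero-noise climate series gives all-zero anomalies", {
  flat <- simulate_climate_series(1961:2000, variable = "rain",
                                  trend_per_decade = 0, sd_noise = 0)
  yearly <- season_aggregate(flat)
  expect_true(all(yearly$value == yearly$value[1]))
  anom <- lamb_index(yearly)
  expect_true(all(anom$index == 0))
  # zero-variance reference with real departures is undefined
  bumped <- yearly; bumped$value[bumped$year == 2000] <- bumped$value[1] + 5
  expect_error(lamb_index(bumped), "zero reference-period standard deviation")
})

test_that("climate trend is recovered by period_contrast", {
  tr <- simulate_climate_series(1961:2010, variable = "tmin",
                                trend_per_decade = 0.5, sd_noise = 0)
  yearly <- season_aggregate(tr)
  ctr <- period_contrast(yearly, c(1961, 1990), c(1991, 2010))
  # period mean gap: (mean decade index of b) - (of a) times 0.5/decade
  expected <- (mean(1991:2010) - mean(1961:1990)) / 10 * 0.5
  expect_equal(ctr$difference, expected, tolerance = 1e-10)
  a <- simulate_climate_series(1990:1995, variable = "tmax", sd_noise = 1,
                               seed = 2)
  b <- simulate_climate_series(1990:1995, variable = "tmax", sd_noise = 1,
                               seed = 2)
  expect_identical(a$value, b$value)
})

test_that("phenotype generator reproduces programmed cell means exactly", {
  ph <- simulate_phenotypes(seed = 6)
  og1 <- ph$dthd[ph$group == "Og" & ph$collect == 1]
  og2 <- ph$dthd[ph$group == "Og" & ph$collect == 2]
  expect_equal(mean(og1), 150.1, tolerance = 1e-10)
  expect_equal(mean(og2), 139.8, tolerance = 1e-10)
  expect_identical(length(og1), 59L)
  expect_identical(length(og2), 85L)
  zero <- simulate_phenotypes(sd_days = 0, seed = 1)
  expect_equal(unique(zero$dthd[zero$group == "Osj" & zero$collect == 2]),
               104.3, tolerance = 1e-10)
  a <- simulate_phenotypes(seed = 9); b <- simulate_phenotypes(seed = 9)
  expect_identical(a$dthd, b$dthd)
})
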