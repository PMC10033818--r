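test_that("weighted global FST and H1 inference behave as defined", {
  s <- data.frame(h1_hat = c(0.5, 0.25, 0), fst_bn = c(0.1, 0.4, 0.9))
  expect_equal(global_fst_weighted(s), (0.5 * 0.1 + 0.25 * 0.4) / 0.75)
  expect_error(global_fst_weighted(
    data.frame(h1_hat = c(0, 0), fst_bn = c(0.1, 0.2))),
    "no locus with positive heterozygosity weight")
  expect_equal(infer_h1(0.3, 0.25), 0.4)
  expect_error(infer_h1(0.3, 1), "undefined")
})

test_that("island coalescent matches the closed-form FST expectation", {
  # single group (k = 1), d = 10 demes, scaled migration M = 5:
  # E[FST] ~ 1 / (1 + M * (d/(d-1))^2)
  m <- 5
  cloud <- simulate_island_null(4000, list(m_within = m, m_between = 0),
                                k_groups = 1, d_demes = 10,
                                sample_sizes = c(100, 100), seed = 61)
  ok <- cloud$h1 > 0 & !is.na(cloud$fst)
  fst <- sum(cloud$h1[ok] * cloud$fst[ok]) / sum(cloud$h1[ok])
  expected <- 1 / (1 + m * (10 / 9)^2)
  expect_lt(abs(fst - expected), 0.2 * expected)
})

test_that("cloud is well-formed: single mutation implies polymorphism", {
  cloud <- simulate_island_null(500, list(m_within = 10, m_between = 1),
                                k_groups = 5, d_demes = 4,
                                sample_sizes = c(30, 30), seed = 9)
  expect_identical(nrow(cloud), 500L)
  # single mutation on the genealogy of the pooled sample: every simulated
  # locus is polymorphic in the pooled sample, so h1 > 0
  expect_true(all(cloud$h1 > 0))
  expect_true(all(cloud$fst <= 1 + 1e-12))
  a <- simulate_island_null(100, list(m_within = 10, m_between = 1),
                            k_groups = 5, d_demes = 4,
                            sample_sizes = c(30, 30), seed = 33)
  b <- simulate_island_null(100, list(m_within = 10, m_between = 1),
                            k_groups = 5, d_demes = 4,
                            sample_sizes = c(30, 30), seed = 33)
  expect_identical(a$fst, b$fst)
})

test_that("migration calibration reaches the target within tolerance", {
  rates <- calibrate_migration(0.10, k_groups = 8, d_demes = 10,
                               sample_sizes = c(80, 80), n_pilot = 2000,
                               rel_tol = 0.10, seed = 13)
  expect_lt(abs(rates$achieved_fst - 0.10), 0.10 * 0.10 + 1e-12)
  expect_equal(rates$m_between, rates$m_within * 0.1)
  expect_error(calibrate_migration(0), "target_fst")
  expect_error(calibrate_migration(1), "target_fst")
})

test_that("kernel p-value agrees with a binned tail-count oracle", {
  cloud <- simulate_island_null(4000, list(m_within = 8, m_between = 0.8),
                                k_groups = 8, d_demes = 10,
                                sample_sizes = c(80, 80), seed = 17)
  bw <- stats::bw.nrd0(cloud$h1)
  h1o <- median(cloud$h1)
  for (fo in quantile(cloud$fst, c(0.5, 0.9, 0.97))) {
    p_kernel <- kernel_pvalue(cloud, h1o, fo)
    near <- abs(cloud$h1 - h1o) <= bw
    p_binned <- mean(cloud$fst[near] >= fo)
    expect_lt(abs(p_kernel - p_binned), 0.02)
  }
  # p-values are floored and capped
  expect_gte(kernel_pvalue(cloud, h1o, 2), 1 / (nrow(cloud) + 1))
  expect_lte(kernel_pvalue(cloud, h1o, -2), 1)
  expect_warning(p_out <- kernel_pvalue(cloud, max(cloud$h1) + 0.1, 0.1),
                 "outside the simulated")
  expect_true(is.na(p_out))
})

test_that("quantile envelopes are ordered and classification is consistent", {
  cloud <- simulate_island_null(3000, list(m_within = 8, m_between = 0.8),
                                k_groups = 8, d_demes = 10,
                                sample_sizes = c(80, 80), seed = 19)
  env5 <- quantile_envelope(cloud, 0.05)
  env1 <- quantile_envelope(cloud, 0.01)
  ok <- !is.na(env5$fst_q) & !is.na(env1$fst_q)
  expect_true(any(ok))
  expect_true(all(env1$fst_q[ok] >= env5$fst_q[ok]))
  # sparse bins carry no envelope
  expect_true(all(is.na(env5$fst_q[env5$n_points < 50])))
  cls <- classify_envelope(cloud$h1, cloud$fst, env5, env1)
  expect_true(all(cls %in% c("ns", "sig5", "sig1")))
  # sig1 points exceed the 1% limit of their bin, hence also the 5% limit
  expect_true(mean(cls == "sig1") <= mean(cls != "ns"))
})

test_that("fdist_scan runs end-to-end and flags nothing on duplicate samples", {
  pair <- filter_loci(small_pair())$pair
  res <- suppressWarnings(
    fdist_scan(pair, k_groups = 6, d_demes = 10, n_sim = 1500,
               n_pilot = 600, seed = 23))
  expect_s3_class(res, "fdist_result")
  expect_identical(nrow(res$table), ncol(pair$sample_t0$geno))
  expect_true(all(res$table$class %in% c("ns", "sig5", "sig1")))
  expect_true(all(na.omit(res$table$p) >= 1 / (res$n_sim + 1)))
  expect_identical(unique(res$table$method), "fdist")

  # a sample paired with itself has FST 0 at every locus; with the
  # calibration floored at FST = 0.005 nothing exceeds the 1% envelope
  gm <- small_pair()$sample_t0
  dup <- filter_loci(temporal_pair(gm, gm, tau = 31))$pair
  res0 <- suppressWarnings(
    fdist_scan(dup, k_groups = 4, d_demes = 6, n_sim = 1200,
               n_pilot = 600, seed = 29))
  expect_identical(sum(res0$table$class == "sig1"), 0L)
  expect_equal(res0$target_fst, 0.005)
})
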