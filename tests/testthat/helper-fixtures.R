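# Small shared fixtures. Built once per test run.

# a modest neutral temporal pair used by several files
small_pair <- local({
  pair <- NULL
  function() {
    if (is.null(pair)) {
      pair <<- simulate_temporal_population(
        n_loci = 300, ne = 300, selfing_rate = 0.95, tau = 31,
        n0 = 60, n_tau = 60, seed = 1234)
    }
    pair
  }
})

# a tiny deterministic genotype matrix: 6 samples x 4 loci on two chromosomes
tiny_gm <- function() {
  geno <- matrix(c(0L, 0L, 1L, 2L, 2L, 2L,
                   0L, 1L, 1L, 1L, 2L, 2L,
                   2L, 2L, 2L, 0L, 0L, 0L,
                   0L, 0L, 0L, 0L, 1L, 2L),
                 nrow = 6, ncol = 4)
  genotype_matrix(geno, chrom = c("chr01", "chr01", "chr02", "chr02"),
                  pos = c(1000L, 5000L, 2000L, 400000L),
                  sample_ids = sprintf("s%d", 1:6))
}
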