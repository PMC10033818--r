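#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Structured coalescent under a hierarchical island model: k_groups groups of
// d_demes demes. Time is scaled in units of 2N generations of one deme, so a
// pair of lineages in the same deme coalesces at rate 1 and each lineage
// migrates at total rate (Mw + Mb) / 2 with Mw = 4N m_within (target a deme of
// the same group) and Mb = 4N m_between (target a deme of another group).
// The sampled lineages come from two demes of one group (the two temporal
// samples of one village). One mutation per locus is placed uniformly on the
// genealogy (single-SNP infinite-sites model), giving a biallelic partition.

namespace {

struct Lineage {
  int deme;
  double birth;
  std::vector<uint64_t> mask;
};

inline int popcount_first(const std::vector<uint64_t>& mask, int n_bits) {
  // count set bits among the first n_bits positions
  int full = n_bits / 64, rem = n_bits % 64, cnt = 0;
  for (int w = 0; w < full; ++w) cnt += __builtin_popcountll(mask[w]);
  if (rem > 0) {
    uint64_t m = (rem == 64) ? ~0ULL : ((1ULL << rem) - 1ULL);
    cnt += __builtin_popcountll(mask[full] & m);
  }
  return cnt;
}

}  // namespace

// Simulate n_loci independent genealogies and return the derived-allele count
// in each of the two sampled demes (columns d1, d2) for sample sizes n1, n2
// haploid lineages.
// [[Rcpp::export(name = ".island_cloud_cpp")]]
IntegerMatrix island_cloud_cpp(int n_loci, int k_groups, int d_demes,
                               int n1, int n2,
                               double m_within, double m_between) {
  if (k_groups < 1 || d_demes < 2) stop("need k >= 1 and d >= 2");
  if (n1 < 1 || n2 < 1) stop("need at least one lineage per sample");
  if (k_groups == 1) m_between = 0.0;
  const int n = n1 + n2;
  const int D = k_groups * d_demes;
  const int words = (n + 63) / 64;
  const double mig_rate_per_lineage = (m_within + m_between) / 2.0;
  const double p_within = (m_within + m_between > 0)
    ? m_within / (m_within + m_between) : 1.0;

  IntegerMatrix out(n_loci, 2);

  std::vector<Lineage> lin;
  std::vector<int> occ(D);
  std::vector<std::pair<std::vector<uint64_t>, double>> branches;
  branches.reserve(2 * n);

  for (int locus = 0; locus < n_loci; ++locus) {
    lin.clear();
    lin.reserve(n);
    std::fill(occ.begin(), occ.end(), 0);
    branches.clear();
    for (int i = 0; i < n; ++i) {
      Lineage L;
      L.deme = (i < n1) ? 0 : 1;  // two demes of group 0
      L.birth = 0.0;
      L.mask.assign(words, 0ULL);
      L.mask[i / 64] |= (1ULL << (i % 64));
      occ[L.deme]++;
      lin.push_back(std::move(L));
    }
    double W = 0.0;  // total coalescence weight sum c*(c-1)/2
    for (int dm = 0; dm < D; ++dm) W += occ[dm] * (occ[dm] - 1) / 2.0;
    double t = 0.0;
    int guard = 0;

    while ((int)lin.size() > 1) {
      if (++guard > 500000000) stop("coalescent did not finish (rate underflow?)");
      const int nact = lin.size();
      const double Rm = nact * mig_rate_per_lineage;
      const double total = W + Rm;
      t += R::exp_rand() / total;
      if (unif_rand() * total < W) {
        // coalescence: pick deme proportional to c*(c-1)/2
        double u = unif_rand() * W, acc = 0.0;
        int deme = -1;
        for (int dm = 0; dm < D; ++dm) {
          acc += occ[dm] * (occ[dm] - 1) / 2.0;
          if (u <= acc) { deme = dm; break; }
        }
        if (deme < 0) deme = D - 1;
        // pick two distinct lineages in that deme
        const int c = occ[deme];
        int pick1 = (int)(unif_rand() * c), pick2 = (int)(unif_rand() * (c - 1));
        if (pick2 >= pick1) pick2++;
        int idx1 = -1, idx2 = -1, seen = 0;
        for (int i = 0; i < nact; ++i) {
          if (lin[i].deme == deme) {
            if (seen == pick1) idx1 = i;
            if (seen == pick2) idx2 = i;
            seen++;
          }
        }
        branches.emplace_back(lin[idx1].mask, t - lin[idx1].birth);
        branches.emplace_back(lin[idx2].mask, t - lin[idx2].birth);
        for (int w = 0; w < words; ++w) lin[idx1].mask[w] |= lin[idx2].mask[w];
        lin[idx1].birth = t;
        lin[idx2] = std::move(lin.back());
        lin.pop_back();
        occ[deme]--;
        W -= (c - 1);
      } else {
        // migration: uniform lineage, choose a target deme
        const int i = (int)(unif_rand() * nact);
        const int old_deme = lin[i].deme;
        const int g = old_deme / d_demes;
        int new_deme;
        if (unif_rand() < p_within) {
          int off = (int)(unif_rand() * (d_demes - 1));
          int j = old_deme % d_demes;
          if (off >= j) off++;
          new_deme = g * d_demes + off;
        } else {
          int g2 = (int)(unif_rand() * (k_groups - 1));
          if (g2 >= g) g2++;
          new_deme = g2 * d_demes + (int)(unif_rand() * d_demes);
        }
        W -= (occ[old_deme] - 1);
        occ[old_deme]--;
        W += occ[new_deme];
        occ[new_deme]++;
        lin[i].deme = new_deme;
      }
    }

    // place one mutation uniformly on the total branch length
    double total_len = 0.0;
    for (auto& br : branches) total_len += br.second;
    double x = unif_rand() * total_len, acc = 0.0;
    int hit = (int)branches.size() - 1;
    for (int b = 0; b < (int)branches.size(); ++b) {
      acc += branches[b].second;
      if (x <= acc) { hit = b; break; }
    }
    const std::vector<uint64_t>& mask = branches[hit].first;
    int d1 = popcount_first(mask, n1);
    int d_all = popcount_first(mask, n);
    out(locus, 0) = d1;
    out(locus, 1) = d_all - d1;
  }
  return out;
}
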