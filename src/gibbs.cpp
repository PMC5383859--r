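#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for genotype probabilities with a Hardy-Weinberg prior.
//
// Per locus and per group (population supplying the allele-frequency prior),
// alternate: (i) sample each individual's genotype from
// P(g | data, p) ∝ L(data | g) * HWE(g | p); (ii) sample p from
// Beta(1 + alt count, 1 + ref count) (flat Beta(1,1) prior on p).
// Retained-sample means give posterior genotype probabilities (indicator
// means), composite genotypes, and posterior-mean allele frequencies.
//
// l0,l1,l2: N x L max-normalised likelihood matrices.
// group: 1-based group index per individual (G groups).
// Returns posterior genotype probabilities (three N x L matrices) and
// G x L allele-frequency posterior means. Uses R's RNG (set.seed applies).

// [[Rcpp::export]]
List gibbs_genotype_model(NumericMatrix l0, NumericMatrix l1, NumericMatrix l2,
                          IntegerVector group, int n_groups,
                          int n_steps, int burn_in, int thin) {
  const int N = l0.nrow(), L = l0.ncol();
  NumericMatrix post0(N, L), post1(N, L), post2(N, L);
  NumericMatrix freqs(n_groups, L);
  std::vector<std::vector<int>> members(n_groups);
  for (int i = 0; i < N; ++i) members[group[i] - 1].push_back(i);

  const int n_retained = (n_steps - burn_in) / thin;
  std::vector<int> geno(N);

  for (int l = 0; l < L; ++l) {
    for (int g = 0; g < n_groups; ++g) {
      const std::vector<int>& idx = members[g];
      const int n = idx.size();
      // init: likelihood-weighted naive frequency and argmax genotypes
      double esum = 0.0;
      for (int t = 0; t < n; ++t) {
        const int i = idx[t];
        const double a = l0(i, l), b = l1(i, l), c = l2(i, l);
        esum += (b + 2.0 * c) / (a + b + c);
        geno[i] = (a >= b && a >= c) ? 0 : (b >= c ? 1 : 2);
      }
      double p = esum / (2.0 * n);
      if (p < 1e-6) p = 1e-6;
      if (p > 1.0 - 1e-6) p = 1.0 - 1e-6;

      double acc0, acc1, acc2;
      for (int step = 1; step <= n_steps; ++step) {
        const double h0 = (1.0 - p) * (1.0 - p);
        const double h1 = 2.0 * p * (1.0 - p);
        const double h2 = p * p;
        int alt = 0;
        for (int t = 0; t < n; ++t) {
          const int i = idx[t];
          const double w0 = l0(i, l) * h0;
          const double w1 = l1(i, l) * h1;
          const double w2 = l2(i, l) * h2;
          const double u = R::runif(0.0, w0 + w1 + w2);
          const int gi = (u < w0) ? 0 : (u < w0 + w1 ? 1 : 2);
          geno[i] = gi;
          alt += gi;
        }
        p = R::rbeta(1.0 + alt, 1.0 + 2 * n - alt);
        if (step > burn_in && (step - burn_in) % thin == 0) {
          for (int t = 0; t < n; ++t) {
            const int i = idx[t];
            if (geno[i] == 0) post0(i, l) += 1.0;
            else if (geno[i] == 1) post1(i, l) += 1.0;
            else post2(i, l) += 1.0;
          }
          freqs(g, l) += p;
        }
      }
      freqs(g, l) /= n_retained;
      for (int t = 0; t < n; ++t) {
        const int i = idx[t];
        acc0 = post0(i, l) / n_retained;
        acc1 = post1(i, l) / n_retained;
        acc2 = post2(i, l) / n_retained;
        post0(i, l) = acc0; post1(i, l) = acc1; post2(i, l) = acc2;
      }
    }
    if (l % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["post0"] = post0, _["post1"] = post1,
                      _["post2"] = post2, _["freqs"] = freqs,
                      _["n_retained"] = n_retained);
}
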