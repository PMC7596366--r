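// Event-driven structured coalescent with migration and population
// mergers, accumulating joint-SFS branch lengths (probability that a
// uniformly placed mutation subtends d_k sampled copies in pop k) and one
// sampled segregating site per locus (infinite-sites, mutation uniform on
// the tree).

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
List coal_sfs_cpp(IntegerVector sample_sizes,   // allele copies per pop (K)
                  NumericVector pop_sizes,      // diploid Ne per pop (K)
                  NumericMatrix mig,            // K x K backward rates/gen
                  NumericMatrix merges,         // time, child, parent, new_size (0-based pops, sorted)
                  int n_loci) {
  const int K = sample_sizes.size();
  int total = 0;
  std::vector<int> stride(K), dims(K);
  for (int k = 0; k < K; ++k) {
    stride[k] = (k == 0) ? 1 : stride[k - 1] * (sample_sizes[k - 1] + 1);
    dims[k] = sample_sizes[k] + 1;
    total += sample_sizes[k];
  }
  const int S = stride[K - 1] * dims[K - 1];
  if (total < 2) stop("need at least 2 sampled copies");
  const int nmerge = merges.nrow();

  NumericVector lens(S);
  IntegerVector counts(S);
  std::vector<double> tmp(S);
  std::vector<int> pop(total), desc(total * K), bin(total);
  std::vector<double> N(K), migrow(K);
  std::vector<int> npop(K);

  for (int locus = 0; locus < n_loci; ++locus) {
    std::memset(tmp.data(), 0, S * sizeof(double));
    NumericMatrix m = clone(mig);
    for (int k = 0; k < K; ++k) N[k] = pop_sizes[k];
    int nlin = 0;
    std::fill(npop.begin(), npop.end(), 0);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < sample_sizes[k]; ++i) {
        pop[nlin] = k;
        for (int j = 0; j < K; ++j) desc[nlin * K + j] = (j == k);
        bin[nlin] = stride[k];
        npop[k]++;
        nlin++;
      }
    double t = 0.0;
    int mi = 0;
    while (nlin > 1) {
      double crtot = 0.0, mrtot = 0.0;
      double cr[8];
      for (int k = 0; k < K; ++k) {
        cr[k] = npop[k] > 1 ? npop[k] * (npop[k] - 1) / 2.0 / (2.0 * N[k])
                            : 0.0;
        crtot += cr[k];
        double row = 0.0;
        for (int j = 0; j < K; ++j) if (j != k) row += m(k, j);
        migrow[k] = row;
        mrtot += npop[k] * row;
      }
      const double R = crtot + mrtot;
      double dt = (R > 0) ? R::exp_rand() / R : R_PosInf;
      double tnext = (mi < nmerge) ? merges(mi, 0) : R_PosInf;
      if (t + dt >= tnext) {
        if (!R_finite(tnext)) stop("no coalescence possible: check sizes/merges");
        for (int l = 0; l < nlin; ++l) tmp[bin[l]] += tnext - t;
        t = tnext;
        int child = (int) merges(mi, 1), parent = (int) merges(mi, 2);
        for (int l = 0; l < nlin; ++l)
          if (pop[l] == child) { pop[l] = parent; npop[parent]++; }
        npop[child] = 0;
        N[parent] = merges(mi, 3);
        for (int j = 0; j < K; ++j) { m(child, j) = 0.0; m(j, child) = 0.0; }
        mi++;
        continue;
      }
      for (int l = 0; l < nlin; ++l) tmp[bin[l]] += dt;
      t += dt;
      double u = R::unif_rand() * R;
      if (u < crtot) {                      // coalescence
        int k = 0;
        while (u >= cr[k]) { u -= cr[k]; ++k; }
        int a = -1, b = -1;
        int pick1 = (int)(R::unif_rand() * npop[k]);
        int pick2 = (int)(R::unif_rand() * (npop[k] - 1));
        int seen = 0;
        for (int l = 0; l < nlin; ++l) if (pop[l] == k) {
          if (seen == pick1) a = l;
          ++seen;
        }
        seen = 0;
        for (int l = 0; l < nlin; ++l) if (pop[l] == k && l != a) {
          if (seen == pick2) b = l;
          ++seen;
        }
        int ib = 0;
        for (int j = 0; j < K; ++j) {
          desc[a * K + j] += desc[b * K + j];
          ib += desc[a * K + j] * stride[j];
        }
        bin[a] = ib;
        npop[k]--;
        nlin--;
        if (b != nlin) {                    // move last into b's slot
          pop[b] = pop[nlin];
          bin[b] = bin[nlin];
          for (int j = 0; j < K; ++j) desc[b * K + j] = desc[nlin * K + j];
        }
      } else {                              // migration
        u -= crtot;
        int l = 0;
        while (l < nlin && u >= migrow[pop[l]]) { u -= migrow[pop[l]]; ++l; }
        if (l == nlin) l = nlin - 1;
        int from = pop[l];
        double v = R::unif_rand() * migrow[from];
        int dest = -1;
        for (int j = 0; j < K; ++j) {
          if (j == from) continue;
          if (v < m(from, j)) { dest = j; break; }
          v -= m(from, j);
        }
        if (dest < 0) { for (int j = K - 1; j >= 0; --j) if (j != from && m(from, j) > 0) { dest = j; break; } }
        pop[l] = dest;
        npop[from]--;
        npop[dest]++;
      }
    }
    double tot = 0.0;
    for (int i = 0; i < S; ++i) tot += tmp[i];
    for (int i = 0; i < S; ++i) lens[i] += tmp[i];
    double v = R::unif_rand() * tot;
    for (int i = 0; i < S; ++i) {
      v -= tmp[i];
      if (v <= 0) { counts[i]++; break; }
    }
  }
  lens.attr("dim") = IntegerVector(dims.begin(), dims.end());
  counts.attr("dim") = IntegerVector(dims.begin(), dims.end());
  return List::create(_["branch_lengths"] = lens, _["site_counts"] = counts);
}
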