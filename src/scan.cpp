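#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Genome-scan inner loops. calls is an n_samples x n_snps integer matrix of
// genotype codes {0,1,2, NA}; one call covers one chromosome. Missing calls
// break identity everywhere: a sample with a missing call inside a window is
// its own genotype class, and a missing call terminates an identity tract.

// G12 per focal SNP for a fixed symmetric window. Focal SNPs closer than
// (window-1)/2 to either end get NA. Pairwise identity inside a window is
// resolved in O(1) per pair via per-pair mismatch prefix sums.
// [[Rcpp::export(name = ".g12_scan_core")]]
NumericVector g12_scan_core(IntegerMatrix calls, int window) {
  const int n = calls.nrow(), L = calls.ncol();
  const int half = (window - 1) / 2;
  NumericVector out(L, NA_REAL);
  if (L < window || n < 1) return out;

  // prefix sums: missing calls per sample, mismatches per pair
  std::vector<std::vector<int>> nacum(n, std::vector<int>(L + 1, 0));
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < L; ++t)
      nacum[i][t + 1] = nacum[i][t] + (calls(i, t) == NA_INTEGER ? 1 : 0);

  const int npairs = n * (n - 1) / 2;
  std::vector<std::vector<int>> miscum(npairs, std::vector<int>(L + 1, 0));
  {
    int p = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j, ++p)
        for (int t = 0; t < L; ++t) {
          int a = calls(i, t), b = calls(j, t);
          bool mis = (a == NA_INTEGER) || (b == NA_INTEGER) || (a != b);
          miscum[p][t + 1] = miscum[p][t] + (mis ? 1 : 0);
        }
  }

  std::vector<int> cls(n), cnt(n);
  for (int f = half; f < L - half; ++f) {
    const int s = f - half, e = f + half + 1; // [s, e)
    int k = 0;
    for (int i = 0; i < n; ++i) {
      cls[i] = -1;
      bool hasNA = nacum[i][e] - nacum[i][s] > 0;
      if (!hasNA) {
        for (int j = 0; j < i; ++j) {
          if (cls[j] < 0) continue; // j singleton-by-missing? cls[j] >= 0 always once set
          if (nacum[j][e] - nacum[j][s] > 0) continue;
          int p = j * n - j * (j + 1) / 2 + (i - j - 1); // pair index (j,i), j<i
          if (miscum[p][e] - miscum[p][s] == 0) { cls[i] = cls[j]; break; }
        }
      }
      if (cls[i] < 0) cls[i] = k++;
    }
    std::fill(cnt.begin(), cnt.begin() + k, 0);
    for (int i = 0; i < n; ++i) cnt[cls[i]]++;
    std::sort(cnt.begin(), cnt.begin() + k, std::greater<int>());
    double g;
    if (k <= 2) {
      g = 1.0;
    } else {
      // match base R arithmetic bit-for-bit: squares in double, the tail
      // summed in extended precision (as sum() does), then one final add
      double p12 = ((double)cnt[0] / n) + ((double)cnt[1] / n);
      long double tail = 0.0L;
      for (int c = 2; c < k; ++c) {
        double pc = (double)cnt[c] / n;
        tail += (double)(pc * pc);
      }
      g = p12 * p12 + (double)tail;
    }
    out[f] = g;
  }
  return out;
}

// H per focal SNP: mean over all sample pairs of the maximal identity-tract
// length (in SNPs) containing the focal SNP; 0 when the pair differs (or
// either is missing) at the focal SNP. Tracts truncate at chromosome ends.
// Per pair, run-length encoding of the match vector assigns each position
// its covering-run length in O(L).
// [[Rcpp::export(name = ".h_scan_core")]]
NumericVector h_scan_core(IntegerMatrix calls) {
  const int n = calls.nrow(), L = calls.ncol();
  NumericVector out(L, 0.0);
  if (n < 2) stop("H scan needs at least 2 samples");
  std::vector<double> acc(L, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int t = 0;
      while (t < L) {
        int a = calls(i, t), b = calls(j, t);
        bool match = (a != NA_INTEGER) && (b != NA_INTEGER) && (a == b);
        if (!match) { ++t; continue; }
        int start = t;
        while (t < L) {
          int aa = calls(i, t), bb = calls(j, t);
          if ((aa != NA_INTEGER) && (bb != NA_INTEGER) && (aa == bb)) ++t;
          else break;
        }
        double len = t - start;
        for (int u = start; u < t; ++u) acc[u] += len;
      }
    }
  }
  const double npairs = (double)n * (n - 1) / 2.0;
  for (int t = 0; t < L; ++t) out[t] = acc[t] / npairs;
  return out;
}
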