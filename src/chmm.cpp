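#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// State space: 2*G*K states. Index s in [0, GK) is the non-chimeric copy of
// (reference g = s / K, rate category k = s % K); s in [GK, 2GK) the chimeric
// copy of (s - GK). Emission codes (G x L integer matrix): 0 = query matches
// the reference nucleotide, 1 = mismatch (both plain nucleotides),
// 2 = uninformative (gap or N on either side; emits probability 1).
//
// Transition structure (per column):
//   self                          : 1 - psi - mu   (1 - psi when K == 1)
//   same reference & class, k'!=k : mu / (K - 1)
//   chimeric copy of ANOTHER ref  : psi / ((G - 1) K)
//   everything else               : 0
// With K == 1 the mu channel has no targets, so self absorbs it; rows of the
// implied dense transition matrix always sum to 1.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline void fill_emissions(const IntegerMatrix& codes,
                                  const NumericMatrix& rates,
                                  int t, int G, int K, std::vector<double>& e) {
  for (int g = 0; g < G; ++g) {
    int c = codes(g, t);
    for (int k = 0; k < K; ++k) {
      double m = rates(g, k);
      e[g * K + k] = (c == 0) ? 1.0 - m : ((c == 1) ? m / 3.0 : 1.0);
    }
  }
}

// [[Rcpp::export]]
List chmm_forward_cpp(IntegerMatrix codes, NumericMatrix rates,
                      double psi, double mu, bool retain) {
  const int G = codes.nrow(), L = codes.ncol(), K = rates.ncol();
  const int GK = G * K, n = 2 * GK;
  const double self_p = (K > 1) ? 1.0 - psi - mu : 1.0 - psi;
  const double mu_p = (K > 1) ? mu / (K - 1) : 0.0;
  const double cross_p = psi / ((double)(G - 1) * K);

  std::vector<double> aU(GK), aC(GK, 0.0), nU(GK), nC(GK), e(GK);
  std::vector<double> refU(G), refC(G);
  NumericVector scales(L);
  NumericMatrix alpha = retain ? NumericMatrix(n, L) : NumericMatrix(0, 0);
  double loglik = 0.0;

  fill_emissions(codes, rates, 0, G, K, e);
  const double init = 1.0 / GK;
  double s = 0.0;
  for (int i = 0; i < GK; ++i) { aU[i] = init * e[i]; s += aU[i]; }
  if (s <= 0.0) stop("zero-probability lattice column at position 1");
  for (int i = 0; i < GK; ++i) aU[i] /= s;
  scales[0] = s;
  loglik += std::log(s);
  if (retain) for (int i = 0; i < GK; ++i) { alpha(i, 0) = aU[i]; alpha(GK + i, 0) = 0.0; }

  for (int t = 1; t < L; ++t) {
    fill_emissions(codes, rates, t, G, K, e);
    double total = 0.0;
    for (int g = 0; g < G; ++g) {
      double su = 0.0, sc = 0.0;
      for (int k = 0; k < K; ++k) { su += aU[g * K + k]; sc += aC[g * K + k]; }
      refU[g] = su; refC[g] = sc; total += su + sc;
    }
    s = 0.0;
    for (int g = 0; g < G; ++g) {
      const double other = (total - refU[g] - refC[g]) * cross_p;
      for (int k = 0; k < K; ++k) {
        const int i = g * K + k;
        const double u = aU[i] * self_p + (refU[g] - aU[i]) * mu_p;
        const double c = aC[i] * self_p + (refC[g] - aC[i]) * mu_p + other;
        nU[i] = u * e[i];
        nC[i] = c * e[i];
        s += nU[i] + nC[i];
      }
    }
    if (s <= 0.0) stop("zero-probability lattice column at position %d", t + 1);
    for (int i = 0; i < GK; ++i) { aU[i] = nU[i] / s; aC[i] = nC[i] / s; }
    scales[t] = s;
    loglik += std::log(s);
    if (retain) for (int i = 0; i < GK; ++i) { alpha(i, t) = aU[i]; alpha(GK + i, t) = aC[i]; }
  }

  double post = 0.0;
  for (int i = 0; i < GK; ++i) post += aC[i];
  return List::create(_["log_likelihood"] = loglik,
                      _["chimera_posterior"] = post,
                      _["scales"] = scales,
                      _["alpha"] = retain ? (SEXP)alpha : R_NilValue);
}

// Scaled backward lattice using the forward pass's column scales, so that
// alpha_hat * beta_hat (elementwise) gives posterior state marginals and
// every column of that product sums to 1.
// [[Rcpp::export]]
NumericMatrix chmm_backward_cpp(IntegerMatrix codes, NumericMatrix rates,
                                double psi, double mu, NumericVector scales) {
  const int G = codes.nrow(), L = codes.ncol(), K = rates.ncol();
  const int GK = G * K, n = 2 * GK;
  const double self_p = (K > 1) ? 1.0 - psi - mu : 1.0 - psi;
  const double mu_p = (K > 1) ? mu / (K - 1) : 0.0;
  const double cross_p = psi / ((double)(G - 1) * K);

  NumericMatrix beta(n, L);
  std::vector<double> wU(GK), wC(GK), e(GK), refWU(G), refWC(G);
  for (int i = 0; i < n; ++i) beta(i, L - 1) = 1.0;

  for (int t = L - 2; t >= 0; --t) {
    fill_emissions(codes, rates, t + 1, G, K, e);
    double totalC = 0.0;
    for (int g = 0; g < G; ++g) {
      double su = 0.0, sc = 0.0;
      for (int k = 0; k < K; ++k) {
        const int i = g * K + k;
        wU[i] = e[i] * beta(i, t + 1);
        wC[i] = e[i] * beta(GK + i, t + 1);
        su += wU[i]; sc += wC[i];
      }
      refWU[g] = su; refWC[g] = sc; totalC += sc;
    }
    const double sc1 = scales[t + 1];
    for (int g = 0; g < G; ++g) {
      const double other = (totalC - refWC[g]) * cross_p;
      for (int k = 0; k < K; ++k) {
        const int i = g * K + k;
        beta(i, t) = (wU[i] * self_p + (refWU[g] - wU[i]) * mu_p + other) / sc1;
        beta(GK + i, t) = (wC[i] * self_p + (refWC[g] - wC[i]) * mu_p + other) / sc1;
      }
    }
  }
  return beta;
}

// Viterbi in log space. The cross-reference max over predecessors is served
// in O(1) per state from the global best / best-with-a-different-reference
// pair; the same-reference rate-switch max from per-(class, reference) top-2
// tables. Ties break toward the lowest predecessor state index.
// [[Rcpp::export]]
List chmm_viterbi_cpp(IntegerMatrix codes, NumericMatrix rates,
                      double psi, double mu) {
  const int G = codes.nrow(), L = codes.ncol(), K = rates.ncol();
  const int GK = G * K, n = 2 * GK;
  const double self_p = (K > 1) ? 1.0 - psi - mu : 1.0 - psi;
  const double mu_p = (K > 1) ? mu / (K - 1) : 0.0;
  const double cross_p = psi / ((double)(G - 1) * K);
  const double lself = std::log(self_p);
  const double lmu = (mu_p > 0.0) ? std::log(mu_p) : NEG_INF;
  const double lcross = (cross_p > 0.0) ? std::log(cross_p) : NEG_INF;

  std::vector<double> ld(n, NEG_INF), nld(n), e(GK);
  IntegerMatrix bp(n, L);
  const double linit = std::log(1.0 / GK);

  fill_emissions(codes, rates, 0, G, K, e);
  for (int i = 0; i < GK; ++i) ld[i] = linit + std::log(e[i]);

  std::vector<double> blk1v(2 * G), blk2v(2 * G);
  std::vector<int> blk1i(2 * G), blk2i(2 * G);

  for (int t = 1; t < L; ++t) {
    fill_emissions(codes, rates, t, G, K, e);

    // Global best and best-with-a-different-reference over all predecessors.
    double b1 = NEG_INF, b2 = NEG_INF;
    int i1 = -1, i2 = -1, r1 = -1;
    for (int i = 0; i < n; ++i) {
      if (ld[i] > b1) { b1 = ld[i]; i1 = i; }
    }
    if (i1 >= 0) r1 = (i1 % GK) / K;
    for (int i = 0; i < n; ++i) {
      if ((i % GK) / K != r1 && ld[i] > b2) { b2 = ld[i]; i2 = i; }
    }

    if (K > 1) {
      for (int b = 0; b < 2 * G; ++b) { blk1v[b] = blk2v[b] = NEG_INF; blk1i[b] = blk2i[b] = -1; }
      for (int i = 0; i < n; ++i) {
        const int blk = (i < GK ? 0 : G) + (i % GK) / K;
        if (ld[i] > blk1v[blk]) {
          blk2v[blk] = blk1v[blk]; blk2i[blk] = blk1i[blk];
          blk1v[blk] = ld[i]; blk1i[blk] = i;
        } else if (ld[i] > blk2v[blk]) {
          blk2v[blk] = ld[i]; blk2i[blk] = i;
        }
      }
    }

    for (int j = 0; j < n; ++j) {
      const int g = (j % GK) / K;
      const bool chim = j >= GK;
      double best = ld[j] + lself;
      int pred = j;
      if (K > 1 && lmu != NEG_INF) {
        const int blk = (chim ? G : 0) + g;
        double bv; int bi;
        if (blk1i[blk] == j) { bv = blk2v[blk]; bi = blk2i[blk]; }
        else { bv = blk1v[blk]; bi = blk1i[blk]; }
        if (bi >= 0) {
          const double cand = bv + lmu;
          if (cand > best || (cand == best && bi < pred)) { best = cand; pred = bi; }
        }
      }
      if (chim && lcross != NEG_INF) {
        double bv; int bi;
        if (r1 != g) { bv = b1; bi = i1; } else { bv = b2; bi = i2; }
        if (bi >= 0) {
          const double cand = bv + lcross;
          if (cand > best || (cand == best && bi < pred)) { best = cand; pred = bi; }
        }
      }
      nld[j] = best + std::log(e[g * K + (j % K)]);
      bp(j, t) = pred;
    }
    ld = nld;
  }

  double bestv = NEG_INF;
  int bests = 0;
  for (int i = 0; i < n; ++i) if (ld[i] > bestv) { bestv = ld[i]; bests = i; }

  IntegerVector path(L);
  int cur = bests;
  for (int t = L - 1; t >= 0; --t) {
    path[t] = cur + 1;  // 1-based for R
    if (t > 0) cur = bp(cur, t);
  }
  return List::create(_["path"] = path, _["log_prob"] = bestv);
}
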