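#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// k-nearest-neighbour positive-vote fraction, Euclidean distance, distance
// ties at the k-th rank broken by lower training-row index.

static double vote_fraction(const std::vector<double>& d2,
                            std::vector<int>& idx,
                            const IntegerVector& ytr, int k) {
  std::iota(idx.begin(), idx.end(), 0);
  std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                    [&d2](int a, int b) {
                      if (d2[a] != d2[b]) return d2[a] < d2[b];
                      return a < b;
                    });
  int pos = 0;
  for (int t = 0; t < k; ++t) pos += (ytr[idx[t]] == 1);
  return static_cast<double>(pos) / k;
}

// [[Rcpp::export]]
NumericVector knn_scores(NumericMatrix xtr, NumericMatrix xte,
                         IntegerVector ytr, int k) {
  const int ntr = xtr.nrow(), nte = xte.nrow(), p = xtr.ncol();
  if (xte.ncol() != p) stop("query/training feature count mismatch");
  if (ytr.size() != ntr) stop("label length mismatch");
  if (k < 1 || k > ntr) stop("k must be in 1..n_train");
  NumericVector out(nte);
  std::vector<double> d2(ntr);
  std::vector<int> idx(ntr);
  for (int q = 0; q < nte; ++q) {
    std::fill(d2.begin(), d2.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      const double xq = xte(q, j);
      for (int t = 0; t < ntr; ++t) {
        const double diff = xq - xtr(t, j);
        d2[t] += diff * diff;
      }
    }
    out[q] = vote_fraction(d2, idx, ytr, k);
  }
  return out;
}

// Incremental prefix sweep for incremental feature selection: features are
// added one at a time in column order, and for every prefix size the vote
// fraction of each query is recorded. Shares the distance accumulation
// across prefixes, so the whole sweep costs one pass over the features.
// [[Rcpp::export]]
NumericMatrix knn_prefix_scores(NumericMatrix xtr, NumericMatrix xte,
                                IntegerVector ytr, int k) {
  const int ntr = xtr.nrow(), nte = xte.nrow(), p = xtr.ncol();
  if (xte.ncol() != p) stop("query/training feature count mismatch");
  if (ytr.size() != ntr) stop("label length mismatch");
  if (k < 1 || k > ntr) stop("k must be in 1..n_train");
  NumericMatrix out(nte, p);
  std::vector<double> d2(ntr);
  std::vector<int> idx(ntr);
  for (int q = 0; q < nte; ++q) {
    std::fill(d2.begin(), d2.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      const double xq = xte(q, j);
      for (int t = 0; t < ntr; ++t) {
        const double diff = xq - xtr(t, j);
        d2[t] += diff * diff;
      }
      out(q, j) = vote_fraction(d2, idx, ytr, k);
    }
  }
  return out;
}
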