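// Exhaustive gene-subset search scored by two-class LDA + Mann-Whitney AUC.
// The hot loop evaluates every bitmask-encoded subset of the gene universe:
// ridge-stabilized Fisher discriminant on the pooled covariance, linear
// scores, midrank AUC. Deterministic: masks ascend, no RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double auc_midrank(const arma::vec& scores, const arma::ivec& y,
                          arma::uvec& ord) {
  const arma::uword n = scores.n_elem;
  ord = arma::sort_index(scores);
  double r1 = 0.0;
  double n1 = 0.0, n0 = 0.0;
  for (arma::uword i = 0; i < n; ++i) (y(i) == 1 ? n1 : n0) += 1.0;
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    const double v = scores(ord(i));
    while (j + 1 < n && scores(ord(j + 1)) == v) ++j;
    const double avg = 0.5 * (double(i + 1) + double(j + 1));
    for (arma::uword k = i; k <= j; ++k)
      if (y(ord(k)) == 1) r1 += avg;
    i = j + 1;
  }
  return (r1 - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

// [[Rcpp::export]]
IntegerVector cpp_popcount(IntegerVector masks) {
  IntegerVector out(masks.size());
  for (R_xlen_t i = 0; i < masks.size(); ++i) {
    unsigned int m = (unsigned int)masks[i];
    int c = 0;
    while (m) { m &= m - 1u; ++c; }
    out[i] = c;
  }
  return out;
}

// X: samples x genes (universe order), y: 0/1 ints.
// Returns per-evaluated-subset vectors (ascending mask order).
// [[Rcpp::export]]
List cpp_panel_search(const arma::mat& X, const arma::ivec& y,
                      int min_size, int max_size) {
  const int p = (int)X.n_cols;
  const arma::uword n = X.n_rows;
  if (p < 1 || p > 25) stop("universe size must be in [1, 25]");
  if (min_size < 1 || max_size > p || min_size > max_size)
    stop("invalid size bounds");

  // pooled covariance and mean difference over the full universe
  arma::uvec idx1 = arma::find(y == 1);
  arma::uvec idx0 = arma::find(y == 0);
  const double n1 = (double)idx1.n_elem, n0 = (double)idx0.n_elem;
  if (n1 < 2 || n0 < 2) stop("both classes need at least 2 samples");
  arma::mat X1 = X.rows(idx1), X0 = X.rows(idx0);
  arma::mat S = ((n1 - 1.0) * arma::cov(X1) + (n0 - 1.0) * arma::cov(X0)) /
                (n1 + n0 - 2.0);
  arma::rowvec dmu = arma::mean(X1, 0) - arma::mean(X0, 0);

  const unsigned int total = (1u << p) - 1u;
  std::vector<int> masks, sizes;
  std::vector<double> aucs;
  std::vector<int> skipped;
  masks.reserve(total); sizes.reserve(total);
  aucs.reserve(total); skipped.reserve(total);

  arma::uvec sub(p);
  arma::uvec ordbuf;
  arma::vec scores(n);

  for (unsigned int mask = 1; mask <= total; ++mask) {
    int k = 0;
    for (int g = 0; g < p; ++g)
      if (mask & (1u << g)) sub(k++) = (arma::uword)g;
    if (k < min_size || k > max_size) continue;
    arma::uvec subi = sub.head(k);
    arma::mat Ssub = S.submat(subi, subi);
    arma::vec d = dmu.elem(subi);
    const double tr = arma::trace(Ssub);
    double lambda_frac = 1e-6;
    arma::vec beta;
    bool ok = false;
    while (lambda_frac <= 0.1 + 1e-15) {
      arma::mat A = Ssub;
      A.diag() += lambda_frac * tr / k;
      ok = arma::solve(beta, A, d, arma::solve_opts::no_approx);
      if (ok && beta.is_finite()) break;
      ok = false;
      lambda_frac *= 10.0;
    }
    masks.push_back((int)mask);
    sizes.push_back(k);
    if (!ok || tr <= 0.0) {
      aucs.push_back(NA_REAL);
      skipped.push_back(1);
      continue;
    }
    scores = X.cols(subi) * beta;
    // orientation (PROG higher) does not change which subsets win: flipping
    // the sign maps AUC -> 1-AUC only when the fit itself points the wrong
    // way, and the oriented score is what the model reports.
    if (arma::mean(scores.elem(idx1)) < arma::mean(scores.elem(idx0)))
      scores = -scores;
    aucs.push_back(auc_midrank(scores, y, ordbuf));
    skipped.push_back(0);
  }

  return List::create(_["mask"] = wrap(masks), _["size"] = wrap(sizes),
                      _["auc"] = wrap(aucs), _["skipped"] = wrap(skipped));
}
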