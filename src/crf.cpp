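// Linear-chain CRF kernels: penalized negative log-likelihood with analytic
// gradient (forward-backward in log space) and Viterbi decoding. Parameters
// are laid out as state weights (n_feats x n_labels, feature-major) followed
// by transition weights (n_labels x n_labels, previous-major). Disallowed
// transitions / initial labels (used by the composite-label reduction of
// higher-order models) are masked out of both training and decoding.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double log_sum_exp(const std::vector<double>& v) {
  double mx = NEG_INF;
  for (double x : v) if (x > mx) mx = x;
  if (mx == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (double x : v) if (x != NEG_INF) s += std::exp(x - mx);
  return mx + std::log(s);
}

// emission scores for one sequence: T x L
static void emissions(const List& feats, const NumericVector& w,
                      int n_labels, std::vector<double>& em, int T) {
  for (int t = 0; t < T; ++t) {
    IntegerVector f = feats[t];
    for (int l = 0; l < n_labels; ++l) {
      double s = 0.0;
      for (int k = 0; k < f.size(); ++k)
        s += w[(f[k] - 1) * n_labels + l];
      em[t * n_labels + l] = s;
    }
  }
}

// [[Rcpp::export]]
List crf_nll_grad(NumericVector w, List seq_feats, List seq_labels,
                  int n_feats, int n_labels, LogicalMatrix trans_ok,
                  LogicalVector init_ok, double c2) {
  const int n_state = n_feats * n_labels;
  const int n_par = n_state + n_labels * n_labels;
  NumericVector grad(n_par);
  double nll = 0.0;
  const int S = seq_feats.size();

  for (int s = 0; s < S; ++s) {
    List feats = seq_feats[s];
    IntegerVector y = seq_labels[s];
    const int T = feats.size();
    if (T == 0) continue;
    std::vector<double> em((size_t)T * n_labels);
    emissions(feats, w, n_labels, em, T);

    // gold score and empirical counts
    double gold = 0.0;
    for (int t = 0; t < T; ++t) {
      int l = y[t] - 1;
      gold += em[t * n_labels + l];
      IntegerVector f = feats[t];
      for (int k = 0; k < f.size(); ++k)
        grad[(f[k] - 1) * n_labels + l] -= 1.0;
      if (t > 0) {
        int p = y[t - 1] - 1;
        gold += w[n_state + p * n_labels + l];
        grad[n_state + p * n_labels + l] -= 1.0;
      }
    }

    // forward
    std::vector<double> alpha((size_t)T * n_labels, NEG_INF);
    for (int l = 0; l < n_labels; ++l)
      if (init_ok[l]) alpha[l] = em[l];
    std::vector<double> acc(n_labels);
    for (int t = 1; t < T; ++t)
      for (int l = 0; l < n_labels; ++l) {
        acc.clear();
        for (int p = 0; p < n_labels; ++p)
          if (trans_ok(p, l) && alpha[(t - 1) * n_labels + p] != NEG_INF)
            acc.push_back(alpha[(t - 1) * n_labels + p] +
                          w[n_state + p * n_labels + l]);
        alpha[t * n_labels + l] =
          acc.empty() ? NEG_INF : log_sum_exp(acc) + em[t * n_labels + l];
      }
    std::vector<double> last(n_labels);
    for (int l = 0; l < n_labels; ++l) last[l] = alpha[(T - 1) * n_labels + l];
    double logZ = log_sum_exp(last);

    // backward
    std::vector<double> beta((size_t)T * n_labels, 0.0);
    for (int t = T - 2; t >= 0; --t)
      for (int p = 0; p < n_labels; ++p) {
        acc.clear();
        for (int l = 0; l < n_labels; ++l)
          if (trans_ok(p, l) && beta[(t + 1) * n_labels + l] != NEG_INF)
            acc.push_back(w[n_state + p * n_labels + l] +
                          em[(t + 1) * n_labels + l] +
                          beta[(t + 1) * n_labels + l]);
        beta[t * n_labels + p] = acc.empty() ? NEG_INF : log_sum_exp(acc);
      }

    // expected state counts
    for (int t = 0; t < T; ++t) {
      IntegerVector f = feats[t];
      for (int l = 0; l < n_labels; ++l) {
        double a = alpha[t * n_labels + l], b = beta[t * n_labels + l];
        if (a == NEG_INF || b == NEG_INF) continue;
        double pr = std::exp(a + b - logZ);
        if (pr == 0.0) continue;
        for (int k = 0; k < f.size(); ++k)
          grad[(f[k] - 1) * n_labels + l] += pr;
      }
    }
    // expected transition counts
    for (int t = 1; t < T; ++t)
      for (int p = 0; p < n_labels; ++p) {
        double a = alpha[(t - 1) * n_labels + p];
        if (a == NEG_INF) continue;
        for (int l = 0; l < n_labels; ++l) {
          if (!trans_ok(p, l)) continue;
          double b = beta[t * n_labels + l];
          if (b == NEG_INF) continue;
          double pr = std::exp(a + w[n_state + p * n_labels + l] +
                               em[t * n_labels + l] + b - logZ);
          if (pr > 0.0) grad[n_state + p * n_labels + l] += pr;
        }
      }

    nll += logZ - gold;
  }

  // L2 penalty (gaussian prior, precision c2)
  for (int j = 0; j < n_par; ++j) {
    nll += 0.5 * c2 * w[j] * w[j];
    grad[j] += c2 * w[j];
  }
  return List::create(Named("nll") = nll, Named("grad") = grad);
}

// [[Rcpp::export]]
List crf_viterbi(NumericVector w, List feats, int n_feats, int n_labels,
                 LogicalMatrix trans_ok, LogicalVector init_ok) {
  const int n_state = n_feats * n_labels;
  const int T = feats.size();
  IntegerVector path(T);
  if (T == 0) return List::create(Named("path") = path, Named("score") = 0.0);
  std::vector<double> em((size_t)T * n_labels);
  emissions(feats, w, n_labels, em, T);

  std::vector<double> delta((size_t)T * n_labels, NEG_INF);
  std::vector<int> back((size_t)T * n_labels, -1);
  for (int l = 0; l < n_labels; ++l)
    if (init_ok[l]) delta[l] = em[l];
  for (int t = 1; t < T; ++t)
    for (int l = 0; l < n_labels; ++l) {
      double best = NEG_INF; int arg = -1;
      for (int p = 0; p < n_labels; ++p) {
        if (!trans_ok(p, l) || delta[(t - 1) * n_labels + p] == NEG_INF)
          continue;
        double sc = delta[(t - 1) * n_labels + p] +
                    w[n_state + p * n_labels + l];
        if (sc > best) { best = sc; arg = p; }   // ties -> lowest label index
      }
      if (arg >= 0) {
        delta[t * n_labels + l] = best + em[t * n_labels + l];
        back[t * n_labels + l] = arg;
      }
    }
  double best = NEG_INF; int arg = 0;
  for (int l = 0; l < n_labels; ++l)
    if (delta[(T - 1) * n_labels + l] > best) {
      best = delta[(T - 1) * n_labels + l]; arg = l;
    }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = back[t * n_labels + arg];
    path[t - 1] = arg + 1;
  }
  return List::create(Named("path") = path, Named("score") = best);
}

// unnormalized log score of a fixed label path (shared with tests/oracles)
// [[Rcpp::export]]
double crf_path_score(NumericVector w, List feats, IntegerVector y,
                      int n_feats, int n_labels) {
  const int n_state = n_feats * n_labels;
  const int T = feats.size();
  double sc = 0.0;
  for (int t = 0; t < T; ++t) {
    IntegerVector f = feats[t];
    int l = y[t] - 1;
    for (int k = 0; k < f.size(); ++k)
      sc += w[(f[k] - 1) * n_labels + l];
    if (t > 0) sc += w[n_state + (y[t - 1] - 1) * n_labels + l];
  }
  return sc;
}
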