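#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward over concatenated subject segments.
// logdens: T x K log emission densities; starts: 0-based segment starts.
// The chain is re-initialised from `init` at every segment start, so no
// probability mass flows across subject boundaries.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logdens, NumericVector init, NumericMatrix trans,
            IntegerVector starts) {
  const int T = logdens.nrow(), K = logdens.ncol(), S = starts.size();
  NumericMatrix gamma(T, K);
  NumericMatrix xi(K, K);            // summed over t within segments
  NumericVector init_post(K);        // summed gamma at segment starts
  NumericMatrix alpha(T, K), beta(T, K), b(T, K);
  NumericVector m(T), c(T);
  double loglik = 0.0;

  for (int t = 0; t < T; ++t) {
    double mx = logdens(t, 0);
    for (int k = 1; k < K; ++k) if (logdens(t, k) > mx) mx = logdens(t, k);
    m[t] = mx;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logdens(t, k) - mx);
  }

  for (int s = 0; s < S; ++s) {
    const int t0 = starts[s];
    const int t1 = (s + 1 < S) ? starts[s + 1] : T;
    // forward
    double csum = 0.0;
    for (int k = 0; k < K; ++k) { alpha(t0, k) = init[k] * b(t0, k); csum += alpha(t0, k); }
    if (csum <= 0.0) stop("forward pass underflow at segment start %d", t0 + 1);
    c[t0] = csum;
    for (int k = 0; k < K; ++k) alpha(t0, k) /= csum;
    for (int t = t0 + 1; t < t1; ++t) {
      csum = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
        a *= b(t, k);
        alpha(t, k) = a;
        csum += a;
      }
      if (csum <= 0.0) stop("forward pass underflow at time %d", t + 1);
      c[t] = csum;
      for (int k = 0; k < K; ++k) alpha(t, k) /= csum;
    }
    // backward
    for (int k = 0; k < K; ++k) beta(t1 - 1, k) = 1.0;
    for (int t = t1 - 2; t >= t0; --t) {
      for (int k = 0; k < K; ++k) {
        double v = 0.0;
        for (int j = 0; j < K; ++j) v += trans(k, j) * b(t + 1, j) * beta(t + 1, j);
        beta(t, k) = v / c[t + 1];
      }
    }
    // gamma, xi, loglik
    for (int t = t0; t < t1; ++t) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
      for (int k = 0; k < K; ++k) gamma(t, k) /= g;
      loglik += std::log(c[t]) + m[t];
    }
    for (int k = 0; k < K; ++k) init_post[k] += gamma(t0, k);
    for (int t = t0; t < t1 - 1; ++t) {
      double z = 0.0;
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j)
          z += alpha(t, i) * trans(i, j) * b(t + 1, j) * beta(t + 1, j);
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j)
          xi(i, j) += alpha(t, i) * trans(i, j) * b(t + 1, j) * beta(t + 1, j) / z;
    }
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["init_post"] = init_post, _["loglik"] = loglik);
}

// Viterbi decoding in log space, segment-wise; ties broken toward the
// lowest state index. Returns 1-based states.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logdens, NumericVector loginit,
                          NumericMatrix logtrans, IntegerVector starts) {
  const int T = logdens.nrow(), K = logdens.ncol(), S = starts.size();
  IntegerVector path(T);
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int s = 0; s < S; ++s) {
    const int t0 = starts[s];
    const int t1 = (s + 1 < S) ? starts[s + 1] : T;
    for (int k = 0; k < K; ++k) delta(t0, k) = loginit[k] + logdens(t0, k);
    for (int t = t0 + 1; t < t1; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = delta(t - 1, 0) + logtrans(0, k);
        int arg = 0;
        for (int j = 1; j < K; ++j) {
          double v = delta(t - 1, j) + logtrans(j, k);
          if (v > best) { best = v; arg = j; }   // strict: keeps lowest index
        }
        delta(t, k) = best + logdens(t, k);
        psi(t, k) = arg;
      }
    }
    double best = delta(t1 - 1, 0);
    int arg = 0;
    for (int k = 1; k < K; ++k) if (delta(t1 - 1, k) > best) { best = delta(t1 - 1, k); arg = k; }
    path[t1 - 1] = arg;
    for (int t = t1 - 2; t >= t0; --t) path[t] = psi(t + 1, path[t + 1]);
  }
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}

// Temporal variability of windowed FC patterns: for each feature (a set of
// 1-based column indices into E, the n_windows x n_entries matrix of
// vectorized window FC), V = 1 - mean over distinct window pairs of the
// Pearson correlation between the two pattern vectors. NA when any pattern
// vector is constant (correlation undefined).
// [[Rcpp::export(name = ".pattern_variability_cpp")]]
NumericVector pattern_variability_cpp(NumericMatrix E, List idx) {
  const int n = E.nrow(), F = idx.size();
  NumericVector out(F);
  for (int f = 0; f < F; ++f) {
    IntegerVector cols = idx[f];
    const int d = cols.size();
    std::vector<double> Z(n * d);
    bool degenerate = false;
    for (int i = 0; i < n; ++i) {
      double mu = 0.0;
      for (int e = 0; e < d; ++e) mu += E(i, cols[e] - 1);
      mu /= d;
      double ss = 0.0;
      for (int e = 0; e < d; ++e) {
        double v = E(i, cols[e] - 1) - mu;
        Z[i * d + e] = v;
        ss += v * v;
      }
      if (ss <= 0.0) { degenerate = true; break; }
      double sd = std::sqrt(ss);
      for (int e = 0; e < d; ++e) Z[i * d + e] /= sd;
    }
    if (degenerate) { out[f] = NA_REAL; continue; }
    double acc = 0.0;
    int npair = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double r = 0.0;
        for (int e = 0; e < d; ++e) r += Z[i * d + e] * Z[j * d + e];
        acc += r;
        ++npair;
      }
    out[f] = 1.0 - acc / npair;
  }
  return out;
}

// All window-FC pattern rows for one window length: row w holds the
// vectorized strict upper triangle (column-major order, matching
// which(upper.tri)) of the Pearson correlation matrix of window w. Windows
// are anchored at t = 0; the trailing T mod l timepoints are ignored.
// [[Rcpp::export(name = ".window_fc_rows_cpp")]]
NumericMatrix window_fc_rows_cpp(NumericMatrix X, int l) {
  const int T = X.nrow(), N = X.ncol();
  const int n = T / l;
  const int P = N * (N - 1) / 2;
  NumericMatrix E(n, P);
  std::vector<double> sd(N), W(static_cast<size_t>(l) * N);
  for (int w = 0; w < n; ++w) {
    const int t0 = w * l;
    for (int c = 0; c < N; ++c) {
      double mu = 0.0;
      for (int t = 0; t < l; ++t) mu += X(t0 + t, c);
      mu /= l;
      double ss = 0.0;
      for (int t = 0; t < l; ++t) {
        double v = X(t0 + t, c) - mu;
        W[static_cast<size_t>(c) * l + t] = v;
        ss += v * v;
      }
      if (ss <= 0.0)
        stop("zero-variance channel %d within window %d (length %d)",
             c + 1, w + 1, l);
      sd[c] = std::sqrt(ss);
    }
    int p = 0;
    for (int j = 1; j < N; ++j)
      for (int i = 0; i < j; ++i) {
        const double *wi = &W[static_cast<size_t>(i) * l];
        const double *wj = &W[static_cast<size_t>(j) * l];
        double s = 0.0;
        for (int t = 0; t < l; ++t) s += wi[t] * wj[t];
        E(w, p++) = s / (sd[i] * sd[j]);
      }
  }
  return E;
}
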