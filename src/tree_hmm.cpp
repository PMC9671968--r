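// Scaled upward/downward recursions, Viterbi decoding and pairwise
// transition posteriors for hidden Markov models indexed by binary
// lineage trees. Cells are in breadth-first order (parents before
// daughters); indices are 0-based here, -1 marks "none".

#include <Rcpp.h>
using namespace Rcpp;

static const double MSD_EPS = 1e-323;

// [[Rcpp::export]]
NumericMatrix cpp_msd(IntegerVector parent, NumericVector pi,
                      NumericMatrix T) {
  int n = parent.size(), K = pi.size();
  NumericMatrix MSD(n, K);
  for (int k = 0; k < K; ++k) MSD(0, k) = pi[k];
  for (int i = 1; i < n; ++i) {
    int p = parent[i];
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += MSD(p, j) * T(j, k);
      MSD(i, k) = s;
    }
  }
  return MSD;
}

// [[Rcpp::export]]
List cpp_upward(IntegerVector parent, IntegerMatrix daughters,
                NumericMatrix logEL, NumericMatrix MSD, NumericMatrix T) {
  int n = parent.size(), K = MSD.ncol();
  NumericMatrix beta(n, K), beta_pc(n, K);
  NumericVector NF(n), shift(n);
  std::fill(beta_pc.begin(), beta_pc.end(), NA_REAL);
  for (int i = n - 1; i >= 0; --i) {
    double mx = logEL(i, 0);
    for (int k = 1; k < K; ++k) mx = std::max(mx, logEL(i, k));
    shift[i] = mx;
    double nf = 0.0;
    int d1 = daughters(i, 0), d2 = daughters(i, 1);
    for (int k = 0; k < K; ++k) {
      double v = std::exp(logEL(i, k) - mx) * MSD(i, k);
      if (d1 >= 0) v *= beta_pc(d1, k) * beta_pc(d2, k);
      beta(i, k) = v;
      nf += v;
    }
    if (!(nf > 0.0) || !R_finite(nf)) {
      stop("normalizing factor underflow at cell %d", i + 1);
    }
    NF[i] = nf;
    for (int k = 0; k < K; ++k) beta(i, k) /= nf;
    if (i > 0) {
      // beta_{p(i),i}(k) = sum_j T(k, j) * beta_i(j) / MSD(i, j)
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) {
          double msd = MSD(i, j) > MSD_EPS ? MSD(i, j) : MSD_EPS;
          s += T(k, j) * beta(i, j) / msd;
        }
        beta_pc(i, k) = s;
      }
    }
  }
  return List::create(_["beta"] = beta, _["NF"] = NF,
                      _["beta_pc"] = beta_pc, _["shift"] = shift);
}

// [[Rcpp::export]]
NumericMatrix cpp_downward(IntegerVector parent, NumericMatrix beta,
                           NumericMatrix beta_pc, NumericMatrix MSD,
                           NumericMatrix T) {
  int n = parent.size(), K = MSD.ncol();
  NumericMatrix gamma(n, K);
  for (int k = 0; k < K; ++k) gamma(0, k) = beta(0, k);
  std::vector<double> ratio(K);
  for (int i = 1; i < n; ++i) {
    int p = parent[i];
    for (int j = 0; j < K; ++j) {
      double bpc = beta_pc(i, j) > MSD_EPS ? beta_pc(i, j) : MSD_EPS;
      ratio[j] = gamma(p, j) / bpc;
    }
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += T(j, k) * ratio[j];
      double msd = MSD(i, k) > MSD_EPS ? MSD(i, k) : MSD_EPS;
      gamma(i, k) = beta(i, k) / msd * s;
    }
  }
  return gamma;
}

// pairwise transition posteriors: slice [,,i] is the (mother, cell i)
// K x K joint, NA for the root
// [[Rcpp::export]]
NumericVector cpp_xi(IntegerVector parent, NumericMatrix gamma,
                     NumericMatrix beta, NumericMatrix beta_pc,
                     NumericMatrix MSD, NumericMatrix T) {
  int n = parent.size(), K = MSD.ncol();
  NumericVector xi(K * K * n, NA_REAL);
  xi.attr("dim") = IntegerVector::create(K, K, n);
  for (int i = 1; i < n; ++i) {
    int p = parent[i];
    for (int a = 0; a < K; ++a) {
      double bpc = beta_pc(i, a) > MSD_EPS ? beta_pc(i, a) : MSD_EPS;
      double r = gamma(p, a) / bpc;
      for (int b = 0; b < K; ++b) {
        double msd = MSD(i, b) > MSD_EPS ? MSD(i, b) : MSD_EPS;
        xi[(size_t)i * K * K + b * K + a] =
          r * T(a, b) * beta(i, b) / msd;
      }
    }
  }
  return xi;
}

// [[Rcpp::export]]
List cpp_viterbi(IntegerVector parent, IntegerMatrix daughters,
                 NumericMatrix logEL, NumericVector pi, NumericMatrix T) {
  int n = parent.size(), K = pi.size();
  NumericMatrix delta(n, K);
  IntegerMatrix link(n, K);
  std::fill(link.begin(), link.end(), NA_INTEGER);
  NumericMatrix logT(K, K);
  for (int a = 0; a < K; ++a) {
    for (int b = 0; b < K; ++b) {
      logT(a, b) = std::log(std::max(T(a, b), MSD_EPS));
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    for (int k = 0; k < K; ++k) delta(i, k) = logEL(i, k);
    for (int s = 0; s < 2; ++s) {
      int v = daughters(i, s);
      if (v < 0) continue;
      for (int k = 0; k < K; ++k) {
        double best = R_NegInf;
        int arg = 0;
        for (int j = 0; j < K; ++j) {
          double cand = delta(v, j) + logT(k, j);
          if (cand > best) { best = cand; arg = j; }
        }
        delta(i, k) += best;
        link(v, k) = arg;
      }
    }
  }
  IntegerVector states(n);
  double best = R_NegInf;
  for (int k = 0; k < K; ++k) {
    double cand = delta(0, k) + std::log(std::max(pi[k], MSD_EPS));
    if (cand > best) { best = cand; states[0] = k; }
  }
  for (int i = 1; i < n; ++i) states[i] = link(i, states[parent[i]]);
  for (int i = 0; i < n; ++i) states[i] += 1;  // 1-based states
  return List::create(_["states"] = states, _["delta"] = delta);
}
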