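// Inner loops of the copy-number HMM: Viterbi decoding and the
// forward-backward recursions.  Emissions and the distance-dependent
// transition matrices are prepared in R and passed in as arrays.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// logem: T x S log emission matrix; ltrans: S x S x (T-1) cube of log
// transition matrices (step t holds the t -> t+1 matrix); logpi: length-S
// log initial distribution.  Returns the 1-based MAP state path.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(const arma::mat& logem, const arma::cube& ltrans,
                          const arma::vec& logpi) {
  const int T = logem.n_rows, S = logem.n_cols;
  arma::mat delta(T, S);
  arma::imat psi(T, S, arma::fill::zeros);
  delta.row(0) = logpi.t() + logem.row(0);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < S; ++j) {
      double best = -arma::datum::inf;
      int arg = 0;
      for (int i = 0; i < S; ++i) {
        double v = delta(t - 1, i) + ltrans(i, j, t - 1);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logem(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  int s = delta.row(T - 1).index_max();
  path[T - 1] = s + 1;
  for (int t = T - 1; t > 0; --t) {
    s = psi(t, s);
    path[t - 1] = s + 1;
  }
  return path;
}

// Scaled forward-backward.  Returns the log-likelihood, the posterior
// state occupancies gamma (T x S), and the expected transition counts
// weighted by invf (length T-1; pass 1/f(d_t) to recover base-rate
// counts for the distance-dependent M-step).
// [[Rcpp::export(name = ".forward_backward_cpp")]]
List forward_backward_cpp(const arma::mat& logem, const arma::cube& ltrans,
                          const arma::vec& logpi, const arma::vec& invf) {
  const int T = logem.n_rows, S = logem.n_cols;
  arma::mat em = arma::exp(logem - arma::repmat(arma::max(logem, 1), 1, S));
  arma::vec emshift = arma::max(logem, 1);
  arma::cube A = arma::exp(ltrans);
  arma::mat alpha(T, S), beta(T, S);
  arma::vec scale(T);

  alpha.row(0) = arma::exp(logpi.t()) % em.row(0);
  scale(0) = arma::accu(alpha.row(0));
  alpha.row(0) /= scale(0);
  for (int t = 1; t < T; ++t) {
    alpha.row(t) = (alpha.row(t - 1) * A.slice(t - 1)) % em.row(t);
    scale(t) = arma::accu(alpha.row(t));
    if (scale(t) <= 0) scale(t) = arma::datum::eps;
    alpha.row(t) /= scale(t);
  }
  beta.row(T - 1).ones();
  for (int t = T - 2; t >= 0; --t) {
    beta.row(t) = (beta.row(t + 1) % em.row(t + 1)) * A.slice(t).t();
    beta.row(t) /= scale(t + 1);
  }
  arma::mat gamma = alpha % beta;
  gamma.each_col() /= arma::sum(gamma, 1);

  arma::mat xiw(S, S, arma::fill::zeros);
  for (int t = 0; t < T - 1; ++t) {
    arma::mat xi = (alpha.row(t).t() * (beta.row(t + 1) % em.row(t + 1))) %
      A.slice(t) / scale(t + 1);
    xiw += invf(t) * xi;
  }
  double ll = arma::accu(arma::log(scale)) + arma::accu(emshift);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xiWeighted"] = xiw);
}
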