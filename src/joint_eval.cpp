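// Fast evaluation of the per-(neuron, cluster) joint log-density
//   log P_SC(y | X beta) - 0.5 * sum(prec * (beta - pmean)^2) + const
// with gradient and Hessian; the inner loop of the EM E-step.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List joint_eval_cpp(const arma::mat& X, const arma::vec& y,
                          const arma::vec& beta, const arma::vec& prec,
                          const arma::vec& pmean, double log_const,
                          double eta_max, bool derivs) {
  arma::vec eta = X * beta;
  arma::uvec over = arma::find(eta > eta_max);
  if (!over.is_empty()) eta.elem(over).fill(eta_max);
  arma::vec mu = arma::exp(eta);
  arma::vec d = beta - pmean;
  double value = arma::dot(y, eta) - arma::accu(mu) -
    0.5 * arma::dot(prec, d % d) + log_const;
  if (!derivs)
    return Rcpp::List::create(Rcpp::Named("value") = value);
  arma::vec grad = X.t() * (y - mu) - prec % d;
  arma::mat Xw = X.each_col() % arma::sqrt(mu);
  arma::mat H = -(Xw.t() * Xw);
  H.diag() -= prec;
  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("hess") = H);
}
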