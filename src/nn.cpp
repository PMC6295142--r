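#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Full-batch backpropagation for an all-sigmoid feed-forward regressor.
//
// X: n x p standardized inputs; y: n responses scaled into (0,1).
// W0: list of L weight matrices, layer l of size (p_l + 1) x p_{l+1}
//     with the bias in the last row. Loss E = 0.5 * sum((o - y)^2).
// Plain gradient descent with a bold-driver step: on an error increase the
// step is undone and the rate halved, on a decrease the rate grows 5%.
// Stops when the gradient norm drops below tol or max_epochs is reached.
// [[Rcpp::export]]
List nn_gd_train(const arma::mat& X, const arma::vec& y, List W0,
                 double lr, double tol, int max_epochs) {
  const int L = W0.size();
  std::vector<arma::mat> W(L), Wprev(L), G(L);
  for (int l = 0; l < L; ++l) W[l] = as<arma::mat>(W0[l]);

  std::vector<arma::mat> A(L + 1);
  double E_prev = std::numeric_limits<double>::infinity();
  double gnorm = NA_REAL;
  double rate = lr;
  bool diverged = false;
  int epoch = 0;

  for (epoch = 0; epoch < max_epochs; ++epoch) {
    // forward
    A[0] = X;
    for (int l = 0; l < L; ++l) {
      const arma::uword p = W[l].n_rows - 1;
      arma::mat Z = A[l] * W[l].rows(0, p - 1);
      Z.each_row() += W[l].row(p);
      A[l + 1] = 1.0 / (1.0 + arma::exp(-Z));
    }
    arma::vec o = A[L].col(0);
    arma::vec err = o - y;
    double E = 0.5 * arma::dot(err, err);
    if (!std::isfinite(E) || E > 1e10) { diverged = true; break; }

    if (E > E_prev && epoch > 0) {
      // bold driver: reject the last step, halve the rate
      W = Wprev;
      rate *= 0.5;
      if (rate < 1e-12) break;
      continue;
    }
    E_prev = E;
    rate *= 1.05;
    if (rate > 1e3 * lr) rate = 1e3 * lr;

    // backward
    arma::mat delta = err % o % (1.0 - o); // n x 1
    double g2 = 0.0;
    for (int l = L - 1; l >= 0; --l) {
      const arma::uword p = W[l].n_rows - 1;
      G[l].set_size(W[l].n_rows, W[l].n_cols);
      G[l].rows(0, p - 1) = A[l].t() * delta;
      G[l].row(p) = arma::sum(delta, 0);
      g2 += arma::accu(arma::square(G[l]));
      if (l > 0) {
        delta = (delta * W[l].rows(0, p - 1).t()) % A[l] % (1.0 - A[l]);
      }
    }
    gnorm = std::sqrt(g2);
    if (gnorm < tol) break;

    Wprev = W;
    for (int l = 0; l < L; ++l) W[l] -= rate * G[l];
  }

  List Wout(L);
  for (int l = 0; l < L; ++l) Wout[l] = W[l];
  return List::create(_["weights"] = Wout, _["epochs"] = epoch,
                      _["grad_norm"] = gnorm, _["error"] = E_prev,
                      _["diverged"] = diverged, _["final_rate"] = rate);
}
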