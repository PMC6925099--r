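// Mini-batch trainer for the fully connected retention-time regressor.
//
// Architecture: dense relu hidden layers, single linear output unit,
// mean-squared-error loss with an L2 weight penalty, Adam updates.
// All randomness (weight initialisation, per-epoch shuffling) happens on
// the R side and is passed in, so a fixed seed gives bit-identical fits.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// [[Rcpp::export(name = ".mlp_fit_cpp")]]
Rcpp::List mlp_fit_cpp(const arma::mat& X, const arma::vec& y,
                       Rcpp::List W0, Rcpp::List b0,
                       const arma::umat& order,
                       double l2, double lr, int batch,
                       double beta1, double beta2, double eps) {
  const int L = W0.size();
  std::vector<mat> W(L), mW(L), vW(L);
  std::vector<rowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(W0[l]);
    b[l] = Rcpp::as<rowvec>(b0[l]);
    mW[l] = zeros<mat>(W[l].n_rows, W[l].n_cols); vW[l] = mW[l];
    mb[l] = zeros<rowvec>(b[l].n_elem);           vb[l] = mb[l];
  }
  const int epochs = order.n_cols;
  const int n = X.n_rows;
  vec losses(epochs, fill::zeros);
  long t = 0;
  std::vector<mat> A(L + 1);
  for (int ep = 0; ep < epochs; ++ep) {
    double epoch_loss = 0; int n_batches = 0;
    for (int s = 0; s < n; s += batch) {
      const int e = std::min(s + batch, n) - 1;
      uvec idx = order(span(s, e), span(ep, ep)) - 1;  // 1-based from R
      const int m = idx.n_elem;
      A[0] = X.rows(idx);
      for (int l = 0; l < L; ++l) {
        mat Z = A[l] * W[l];
        Z.each_row() += b[l];
        A[l + 1] = (l < L - 1) ? clamp(Z, 0.0, datum::inf) : Z;
      }
      vec r = A[L].col(0) - y(idx);
      epoch_loss += dot(r, r) / m; ++n_batches;
      mat delta = (2.0 / m) * r;   // d(MSE)/d(output)
      ++t;
      const double c1 = 1.0 - std::pow(beta1, (double)t);
      const double c2 = 1.0 - std::pow(beta2, (double)t);
      for (int l = L - 1; l >= 0; --l) {
        mat gW = A[l].t() * delta + 2.0 * l2 * W[l];
        rowvec gb = sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= conv_to<mat>::from(A[l] > 0);  // relu gate
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * square(gW);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * square(gb);
        W[l] -= lr * (mW[l] / c1) / (sqrt(vW[l] / c2) + eps);
        b[l] -= lr * (mb[l] / c1) / (sqrt(vb[l] / c2) + eps);
      }
    }
    losses(ep) = epoch_loss / n_batches;
  }
  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) { Wout[l] = W[l]; bout[l] = b[l]; }
  return Rcpp::List::create(Rcpp::Named("W") = Wout,
                            Rcpp::Named("b") = bout,
                            Rcpp::Named("loss") = losses);
}

// [[Rcpp::export(name = ".mlp_predict_cpp")]]
arma::vec mlp_predict_cpp(const arma::mat& X, Rcpp::List Wl, Rcpp::List bl) {
  const int L = Wl.size();
  mat A = X;
  for (int l = 0; l < L; ++l) {
    mat Z = A * Rcpp::as<mat>(Wl[l]);
    Z.each_row() += Rcpp::as<rowvec>(bl[l]);
    A = (l < L - 1) ? clamp(Z, 0.0, datum::inf) : Z;
  }
  return A.col(0);
}
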