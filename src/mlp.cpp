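// Minibatch momentum-SGD trainer for the rectifier MLP.
// Uses R's RNG throughout (init, shuffling, dropout masks), so results are
// fully determined by set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                   int hidden_layers, int nodes, double dropout,
                   double momentum, int batch_size, int epochs,
                   double lr, double lr_decay) {
  RNGScope scope;
  const int n = X.n_rows, p = X.n_cols;
  const int L = hidden_layers + 1;
  const double keep = 1.0 - dropout;

  std::vector<int> sizes(L + 1);
  sizes[0] = p;
  for (int l = 1; l <= hidden_layers; ++l) sizes[l] = nodes;
  sizes[L] = 1;

  std::vector<arma::mat> W(L), vW(L);
  std::vector<arma::rowvec> b(L), vb(L);
  for (int l = 0; l < L; ++l) {
    const double r = std::sqrt(6.0 / sizes[l]);
    W[l].set_size(sizes[l], sizes[l + 1]);
    for (arma::uword j = 0; j < W[l].n_cols; ++j)      // column-major,
      for (arma::uword i = 0; i < W[l].n_rows; ++i)    // like R's matrix()
        W[l](i, j) = R::runif(-r, r);
    b[l].zeros(sizes[l + 1]);
    vW[l].zeros(sizes[l], sizes[l + 1]);
    vb[l].zeros(sizes[l + 1]);
  }

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  NumericVector loss_hist(epochs);
  std::vector<arma::mat> A(L + 1), mask(L), delta_store;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    double ep_loss = 0.0;
    const int nb = (n + batch_size - 1) / batch_size;
    for (int bi = 0; bi < nb; ++bi) {
      const int lo = bi * batch_size;
      const int hi = std::min(n, lo + batch_size) - 1;
      const int m = hi - lo + 1;
      arma::uvec rows(m);
      for (int i = 0; i < m; ++i) rows[i] = ord[lo + i];
      A[0] = X.rows(rows);
      arma::vec yb(m);
      for (int i = 0; i < m; ++i) yb[i] = y[ord[lo + i]];

      // forward with inverted dropout on hidden activations
      for (int l = 0; l < L; ++l) {
        arma::mat Z = A[l] * W[l];
        Z.each_row() += b[l];
        if (l < L - 1) {
          arma::mat H = arma::clamp(Z, 0.0, arma::datum::inf);
          if (dropout > 0) {
            arma::mat msk(H.n_rows, H.n_cols);
            for (arma::uword j = 0; j < msk.n_cols; ++j)
              for (arma::uword i = 0; i < msk.n_rows; ++i)
                msk(i, j) = (unif_rand() < keep) ? 1.0 : 0.0;
            H = (H % msk) / keep;
            mask[l] = msk;
          }
          A[l + 1] = H;
        } else {
          A[l + 1] = Z;
        }
      }
      arma::vec err = A[L].col(0) - yb;
      const double bloss = arma::dot(err, err) / m;
      if (!std::isfinite(bloss))
        stop("non-finite training loss at epoch %d, batch %d", ep + 1,
             bi + 1);
      ep_loss += bloss * m;

      // backward
      arma::mat delta = arma::mat(2.0 * err / m);
      for (int l = L - 1; l >= 0; --l) {
        arma::mat gW = A[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= arma::conv_to<arma::mat>::from(A[l] > 0);
          if (dropout > 0) delta = (delta % mask[l - 1]) / keep;
        }
        vW[l] = momentum * vW[l] - lr * gW;
        vb[l] = momentum * vb[l] - lr * gb;
        W[l] += vW[l];
        b[l] += vb[l];
      }
    }
    loss_hist[ep] = ep_loss / n;
    lr *= lr_decay;
  }

  List weights(L);
  for (int l = 0; l < L; ++l)
    weights[l] = List::create(Named("W") = wrap(W[l]),
                              Named("b") = NumericVector(b[l].begin(),
                                                         b[l].end()));
  return List::create(Named("weights") = weights,
                      Named("loss") = loss_hist);
}
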