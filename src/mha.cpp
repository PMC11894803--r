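// Batched multi-head self-attention primitives.
//
// Activations are laid out as (B*G) x E matrices with row index
// r = b*G + g (sample-major, gene/token-minor). Attention mixes tokens only
// within a sample, so the forward and backward passes loop over samples and
// heads with small dense products; everything else in the network is a
// plain matrix operation handled in R by BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Forward pass. Q, K, V: (B*G) x E. Returns the concatenated per-head
// context ((B*G) x E) and the softmax attention probabilities stacked as a
// ((B*H*G) x G) matrix for reuse in the backward pass.
// [[Rcpp::export(name = ".mha_forward_cpp")]]
List mha_forward_cpp(const arma::mat& Q, const arma::mat& K,
                     const arma::mat& V, int B, int G, int H) {
  const int E = Q.n_cols;
  const int dh = E / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat ctx(Q.n_rows, E, arma::fill::zeros);
  arma::mat P((arma::uword)B * H * G, G);
  for (int b = 0; b < B; ++b) {
    const arma::uword r0 = (arma::uword)b * G, r1 = r0 + G - 1;
    for (int h = 0; h < H; ++h) {
      const arma::uword c0 = (arma::uword)h * dh, c1 = c0 + dh - 1;
      arma::mat S = Q.submat(r0, c0, r1, c1) *
                    K.submat(r0, c0, r1, c1).t() * scale;
      S.each_col() -= arma::max(S, 1);          // stabilized row softmax
      arma::mat Pb = arma::exp(S);
      Pb.each_col() /= arma::sum(Pb, 1);
      const arma::uword p0 = ((arma::uword)b * H + h) * G;
      P.rows(p0, p0 + G - 1) = Pb;
      ctx.submat(r0, c0, r1, c1) = Pb * V.submat(r0, c0, r1, c1);
    }
  }
  return List::create(Named("ctx") = ctx, Named("P") = P);
}

// Backward pass: gradients of the loss w.r.t. Q, K, V given the gradient
// w.r.t. the context and the cached attention probabilities.
// [[Rcpp::export(name = ".mha_backward_cpp")]]
List mha_backward_cpp(const arma::mat& dCtx, const arma::mat& Q,
                      const arma::mat& K, const arma::mat& V,
                      const arma::mat& P, int B, int G, int H) {
  const int E = Q.n_cols;
  const int dh = E / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat dQ(arma::size(Q), arma::fill::zeros);
  arma::mat dK(arma::size(K), arma::fill::zeros);
  arma::mat dV(arma::size(V), arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::uword r0 = (arma::uword)b * G, r1 = r0 + G - 1;
    for (int h = 0; h < H; ++h) {
      const arma::uword c0 = (arma::uword)h * dh, c1 = c0 + dh - 1;
      const arma::uword p0 = ((arma::uword)b * H + h) * G;
      const arma::mat Pb = P.rows(p0, p0 + G - 1);
      const arma::mat dC = dCtx.submat(r0, c0, r1, c1);
      const arma::mat Vb = V.submat(r0, c0, r1, c1);
      dV.submat(r0, c0, r1, c1) = Pb.t() * dC;
      arma::mat dP = dC * Vb.t();
      // softmax backward: dS = P .* (dP - rowsum(dP .* P))
      arma::vec rs = arma::sum(dP % Pb, 1);
      arma::mat dS = Pb % (dP.each_col() - rs);
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1) * scale;
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1) * scale;
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}
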