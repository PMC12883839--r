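// Batched dot-product self-attention kernels for the ACmix block.
// Tensors are passed as arma::cube with dimensions (channels, L, batch):
// one (C x L) slice per sample. Multi-head attention splits the channel
// dimension into contiguous groups.
//
// Attention scores are held transposed (keys x queries) so that the
// softmax over key positions runs down contiguous columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Forward pass of the attention path. Returns the output cube and, when
// want_cache, the Q/K/V projections and per-head attention weights
// (stored keys x queries) needed by the backward pass.
// [[Rcpp::export]]
Rcpp::List acmix_att_forward_cpp(const arma::cube &X, const arma::mat &Wq,
                                 const arma::vec &bq, const arma::mat &Wk,
                                 const arma::vec &bk, const arma::mat &Wv,
                                 const arma::vec &bv, const arma::vec &pos,
                                 int n_heads, bool want_cache) {
  const uword C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const uword hs = C / n_heads;
  const double scale = 1.0 / std::sqrt((double)hs);
  cube out(C, L, B), Qc, Kc, Vc, Ac;
  if (want_cache) {
    Qc.set_size(C, L, B); Kc.set_size(C, L, B); Vc.set_size(C, L, B);
    Ac.set_size(L, L, B * n_heads);
  }
  for (uword b = 0; b < B; ++b) {
    const mat &Xb = X.slice(b);
    mat Q = Wq * Xb; Q.each_col() += bq;
    mat K = Wk * Xb; K.each_col() += bk;
    mat V = Wv * Xb; V.each_col() += bv;
    for (int h = 0; h < n_heads; ++h) {
      const uword r0 = h * hs, r1 = (h + 1) * hs - 1;
      // St(j, i) = score of key j for query i (+ positional term on keys)
      mat St = K.rows(r0, r1).t() * Q.rows(r0, r1) * scale;
      St.each_col() += pos;
      St.each_row() -= max(St, 0);
      St = exp(St);
      St.each_row() /= sum(St, 0);
      out.slice(b).rows(r0, r1) = V.rows(r0, r1) * St;
      if (want_cache) Ac.slice(b * n_heads + h) = St;
    }
    if (want_cache) {
      Qc.slice(b) = Q; Kc.slice(b) = K; Vc.slice(b) = V;
    }
  }
  if (want_cache)
    return Rcpp::List::create(Rcpp::Named("out") = out,
                              Rcpp::Named("Q") = Qc, Rcpp::Named("K") = Kc,
                              Rcpp::Named("V") = Vc, Rcpp::Named("A") = Ac);
  return Rcpp::List::create(Rcpp::Named("out") = out);
}

// Backward pass: gradients of the projections, positional table and input.
// [[Rcpp::export]]
Rcpp::List acmix_att_backward_cpp(const arma::cube &X, const arma::cube &dOut,
                                  const arma::cube &Q, const arma::cube &K,
                                  const arma::cube &V, const arma::cube &A,
                                  const arma::mat &Wq, const arma::mat &Wk,
                                  const arma::mat &Wv, int n_heads) {
  const uword C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const uword hs = C / n_heads;
  const double scale = 1.0 / std::sqrt((double)hs);
  mat dWq(C, C, fill::zeros), dWk(C, C, fill::zeros), dWv(C, C, fill::zeros);
  vec dbq(C, fill::zeros), dbk(C, fill::zeros), dbv(C, fill::zeros);
  vec dpos(L, fill::zeros);
  cube dX(C, L, B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    const mat &Xb = X.slice(b);
    const mat &dOb = dOut.slice(b);
    mat dQ(C, L, fill::zeros), dK(C, L, fill::zeros), dV(C, L, fill::zeros);
    for (int h = 0; h < n_heads; ++h) {
      const uword r0 = h * hs, r1 = (h + 1) * hs - 1;
      const mat &At = A.slice(b * n_heads + h);          // keys x queries
      const mat dOh = dOb.rows(r0, r1);                  // hs x L(queries)
      const mat Vh = V.slice(b).rows(r0, r1);
      dV.rows(r0, r1) = dOh * At.t();
      // dAt(j, i) = sum_c V(c, j) dOh(c, i)
      mat dAt = Vh.t() * dOh;                            // L x L
      rowvec rs = sum(dAt % At, 0);
      mat dSt = At % (dAt.each_row() - rs);
      dpos += sum(dSt, 1);
      dQ.rows(r0, r1) = K.slice(b).rows(r0, r1) * dSt * scale;
      dK.rows(r0, r1) = Q.slice(b).rows(r0, r1) * dSt.t() * scale;
    }
    dWq += dQ * Xb.t(); dbq += sum(dQ, 1);
    dWk += dK * Xb.t(); dbk += sum(dK, 1);
    dWv += dV * Xb.t(); dbv += sum(dV, 1);
    dX.slice(b) = Wq.t() * dQ + Wk.t() * dK + Wv.t() * dV;
  }
  return Rcpp::List::create(
      Rcpp::Named("dWq") = dWq, Rcpp::Named("dbq") = dbq,
      Rcpp::Named("dWk") = dWk, Rcpp::Named("dbk") = dbk,
      Rcpp::Named("dWv") = dWv, Rcpp::Named("dbv") = dbv,
      Rcpp::Named("dpos") = dpos, Rcpp::Named("dX") = dX);
}

// Depthwise 1-D convolution over arrays laid out (batch, channel, L),
// matching R's array storage (batch fastest). Same padding, odd kernel.
// [[Rcpp::export]]
Rcpp::NumericVector depthwise_forward_cpp(const Rcpp::NumericVector &X,
                                          const arma::mat &W,
                                          const arma::vec &bias,
                                          int B, int C, int L) {
  const int k = W.n_cols, pad = (k - 1) / 2;
  Rcpp::NumericVector Y(X.size());
  const double *x = X.begin();
  double *y = Y.begin();
  for (int c = 0; c < C; ++c) {
    const double bc = bias(c);
    for (int l = 0; l < L; ++l) {
      double *yp = y + (size_t)B * (c + (size_t)C * l);
      for (int b = 0; b < B; ++b) yp[b] = bc;
      for (int t = 0; t < k; ++t) {
        const int ls = l + t - pad;
        if (ls < 0 || ls >= L) continue;
        const double w = W(c, t);
        const double *xp = x + (size_t)B * (c + (size_t)C * ls);
        for (int b = 0; b < B; ++b) yp[b] += w * xp[b];
      }
    }
  }
  Y.attr("dim") = Rcpp::IntegerVector::create(B, C, L);
  return Y;
}

// [[Rcpp::export]]
Rcpp::List depthwise_backward_cpp(const Rcpp::NumericVector &X,
                                  const Rcpp::NumericVector &dY,
                                  const arma::mat &W, int B, int C, int L) {
  const int k = W.n_cols, pad = (k - 1) / 2;
  arma::mat dW(C, k, arma::fill::zeros);
  arma::vec db(C, arma::fill::zeros);
  Rcpp::NumericVector dX(X.size());
  const double *x = X.begin(), *dy = dY.begin();
  double *dx = dX.begin();
  for (int c = 0; c < C; ++c) {
    for (int l = 0; l < L; ++l) {
      const double *dyp = dy + (size_t)B * (c + (size_t)C * l);
      double acc = 0;
      for (int b = 0; b < B; ++b) acc += dyp[b];
      db(c) += acc;
      for (int t = 0; t < k; ++t) {
        const int ls = l + t - pad;
        if (ls < 0 || ls >= L) continue;
        const double w = W(c, t);
        const double *xp = x + (size_t)B * (c + (size_t)C * ls);
        double *dxp = dx + (size_t)B * (c + (size_t)C * ls);
        double accw = 0;
        for (int b = 0; b < B; ++b) {
          accw += dyp[b] * xp[b];
          dxp[b] += w * dyp[b];
        }
        dW(c, t) += accw;
      }
    }
  }
  dX.attr("dim") = Rcpp::IntegerVector::create(B, C, L);
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}
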