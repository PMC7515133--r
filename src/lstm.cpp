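// Batched LSTM forward/backward and softmax cross-entropy kernels.
// Sequences are stacked time-major: row block t (size B) of an (M*B) x *
// matrix holds timestep t for the whole minibatch. The recurrence works
// in-place on preallocated caches to keep memory traffic low.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double sigm1(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// inputs: (M*B) x 4H input contributions (W_x x_t); bias: length-4H vector
// added at every step; extra: B x 4H per-sequence contribution (W_z z) added
// at every step (pass 1 x 4H zeros to skip). Wh: H x 4H recurrent weights.
// Returns hidden/cell states for all steps (including the zero initial
// block) plus post-activation gate caches.
// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& inputs, const arma::mat& Wh,
                            const arma::vec& bias, const arma::mat& extra,
                            int B, int M) {
  const int H = Wh.n_rows;
  const bool has_extra = extra.n_rows == static_cast<unsigned>(B);
  mat Hs((M + 1) * B, H, fill::zeros);
  mat Cs((M + 1) * B, H, fill::zeros);
  mat Gates(M * B, 4 * H);
  mat TC(M * B, H);
  mat h(B, H, fill::zeros);
  for (int t = 0; t < M; ++t) {
    const int r0 = t * B;
    // G = inputs_t + bias [+ extra] + h * Wh, written into the Gates cache
    Gates.rows(r0, r0 + B - 1) = inputs.rows(r0, r0 + B - 1) + h * Wh;
    for (int j = 0; j < 4 * H; ++j) {
      double* gcol = Gates.colptr(j) + r0;
      const double bj = bias(j);
      if (has_extra) {
        const double* ecol = extra.colptr(j);
        for (int b = 0; b < B; ++b) gcol[b] += bj + ecol[b];
      } else {
        for (int b = 0; b < B; ++b) gcol[b] += bj;
      }
    }
    for (int j = 0; j < H; ++j) {
      double* gi = Gates.colptr(j) + r0;
      double* gf = Gates.colptr(H + j) + r0;
      double* go = Gates.colptr(2 * H + j) + r0;
      double* gg = Gates.colptr(3 * H + j) + r0;
      const double* cprev = Cs.colptr(j) + r0;        // block t = c_{t-1}
      double* cnew = Cs.colptr(j) + r0 + B;
      double* hnew = Hs.colptr(j) + r0 + B;
      double* tc = TC.colptr(j) + r0;
      double* hcol = h.colptr(j);
      for (int b = 0; b < B; ++b) {
        const double i_ = sigm1(gi[b]);
        const double f_ = sigm1(gf[b]);
        const double o_ = sigm1(go[b]);
        const double g_ = std::tanh(gg[b]);
        gi[b] = i_; gf[b] = f_; go[b] = o_; gg[b] = g_;
        const double c_ = f_ * cprev[b] + i_ * g_;
        const double tc_ = std::tanh(c_);
        cnew[b] = c_;
        tc[b] = tc_;
        const double h_ = o_ * tc_;
        hnew[b] = h_;
        hcol[b] = h_;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Hs") = Hs, Rcpp::Named("Cs") = Cs,
                            Rcpp::Named("Gates") = Gates,
                            Rcpp::Named("TC") = TC);
}

// dHs: (M*B) x H gradients arriving at each produced state h_t (zeros
// allowed); dh_last: extra gradient at the final hidden state.
// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& Hs, const arma::mat& Cs,
                             const arma::mat& Gates, const arma::mat& TC,
                             const arma::mat& Wh, const arma::mat& dHs,
                             const arma::mat& dh_last, int B, int M) {
  const int H = Wh.n_rows;
  mat dInputs(M * B, 4 * H);
  mat dWh(H, 4 * H, fill::zeros);
  mat dh = dh_last;
  mat dc(B, H, fill::zeros);
  for (int t = M - 1; t >= 0; --t) {
    const int r0 = t * B;
    for (int j = 0; j < H; ++j) {
      const double* gi = Gates.colptr(j) + r0;
      const double* gf = Gates.colptr(H + j) + r0;
      const double* go = Gates.colptr(2 * H + j) + r0;
      const double* gg = Gates.colptr(3 * H + j) + r0;
      const double* tc = TC.colptr(j) + r0;
      const double* cprev = Cs.colptr(j) + r0;
      const double* dhs = dHs.colptr(j) + r0;
      double* dhcol = dh.colptr(j);
      double* dccol = dc.colptr(j);
      double* dgi = dInputs.colptr(j) + r0;
      double* dgf = dInputs.colptr(H + j) + r0;
      double* dgo = dInputs.colptr(2 * H + j) + r0;
      double* dgg = dInputs.colptr(3 * H + j) + r0;
      for (int b = 0; b < B; ++b) {
        const double dh_ = dhcol[b] + dhs[b];
        const double tc_ = tc[b];
        double dc_ = dccol[b] + dh_ * go[b] * (1.0 - tc_ * tc_);
        const double do_ = dh_ * tc_;
        const double di = dc_ * gg[b];
        const double dg = dc_ * gi[b];
        const double df = dc_ * cprev[b];
        dgi[b] = di * gi[b] * (1.0 - gi[b]);
        dgf[b] = df * gf[b] * (1.0 - gf[b]);
        dgo[b] = do_ * go[b] * (1.0 - go[b]);
        dgg[b] = dg * (1.0 - gg[b] * gg[b]);
        dccol[b] = dc_ * gf[b];
      }
    }
    dWh += Hs.rows(r0, r0 + B - 1).t() * dInputs.rows(r0, r0 + B - 1);
    dh = dInputs.rows(r0, r0 + B - 1) * Wh.t();
  }
  return Rcpp::List::create(Rcpp::Named("dInputs") = dInputs,
                            Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("dh0") = dh);
}

// Softmax cross-entropy over rows; target is 1-based. Returns per-row nll
// and the gradient of sum(w * nll) w.r.t. the logits.
// [[Rcpp::export]]
Rcpp::List softmax_xent_cpp(const arma::mat& logits,
                            const arma::ivec& target, const arma::vec& w) {
  const int n = logits.n_rows;
  const vec mx = max(logits, 1);
  mat P = exp(logits.each_col() - mx);
  const vec Z = sum(P, 1);
  P.each_col() /= Z;
  vec nll(n);
  for (int i = 0; i < n; ++i) {
    const int j = target(i) - 1;
    nll(i) = std::log(Z(i)) + mx(i) - logits(i, j);
    P(i, j) -= 1.0;
  }
  P.each_col() %= w;
  return Rcpp::List::create(Rcpp::Named("nll") = nll,
                            Rcpp::Named("dlogits") = P);
}
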