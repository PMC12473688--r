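// LSTM forward/backward kernels and the fused Adam step for the sequence
// classifier.
//
// Batches are time-major: a batch of B sequences of length T is an
// (B*T) x D matrix whose rows (t*B) .. (t*B + B - 1) hold time step t.
// Inside the kernels the per-step activations live in cube slices
// (B x H x T), which are contiguous in memory; row blocks of the big
// column-major matrices are strided, so they are touched only once on the
// way in and once on the way out. Arithmetic runs in single precision —
// standard for network training, and it doubles the throughput of both
// the BLAS calls and the memory-bound elementwise recurrences; parameters
// and gradients cross the R boundary as doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline fmat sigm(const fmat& x) { return 1.0f / (1.0f + exp(-x)); }

// Scatter a (B*T) x K time-major matrix into a B x K x T cube.
static fcube to_cube(const fmat& M, const int B) {
  const int Tn = M.n_rows / B, K = M.n_cols;
  fcube out(B, K, Tn);
  for (int t = 0; t < Tn; ++t)
    out.slice(t) = M.rows(t * B, (t + 1) * B - 1);
  return out;
}

// Gather a B x K x T cube back into a (B*T) x K time-major matrix.
static fmat to_mat(const fcube& C) {
  const int B = C.n_rows, K = C.n_cols, Tn = C.n_slices;
  fmat out(B * Tn, K);
  for (int t = 0; t < Tn; ++t)
    out.rows(t * B, (t + 1) * B - 1) = C.slice(t);
  return out;
}

static fmat as_f(const arma::mat& M) { return conv_to<fmat>::from(M); }
static mat as_d(const fmat& M) { return conv_to<mat>::from(M); }

// [[Rcpp::export(name = ".lstm_fwd_cpp")]]
Rcpp::List lstm_fwd_cpp(const arma::mat& X, const arma::mat& W,
                        const arma::mat& U, const arma::vec& b, int B) {
  const int n = X.n_rows, Tn = n / B, H = W.n_cols / 4;
  const fmat Xf = as_f(X), Wf = as_f(W), Uf = as_f(U);
  const frowvec bf = conv_to<frowvec>::from(b);
  fmat XWm = Xf * Wf;
  XWm.each_row() += bf;
  const fcube XW = to_cube(XWm, B);
  fcube Gi(B, H, Tn), Gf(B, H, Tn), Gg(B, H, Tn), Go(B, H, Tn);
  fcube Cs(B, H, Tn), Tc(B, H, Tn), Hs(B, H, Tn);
  fmat h_prev(B, H, fill::zeros), c_prev(B, H, fill::zeros);
  for (int t = 0; t < Tn; ++t) {
    const fmat z = XW.slice(t) + h_prev * Uf;
    Gi.slice(t) = sigm(z.cols(0, H - 1));
    Gf.slice(t) = sigm(z.cols(H, 2 * H - 1));
    Gg.slice(t) = tanh(z.cols(2 * H, 3 * H - 1));
    Go.slice(t) = sigm(z.cols(3 * H, 4 * H - 1));
    Cs.slice(t) = Gf.slice(t) % c_prev + Gi.slice(t) % Gg.slice(t);
    Tc.slice(t) = tanh(Cs.slice(t));
    Hs.slice(t) = Go.slice(t) % Tc.slice(t);
    h_prev = Hs.slice(t); c_prev = Cs.slice(t);
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = as_d(to_mat(Hs)), Rcpp::Named("Gi") = Gi,
      Rcpp::Named("Gf") = Gf, Rcpp::Named("Gg") = Gg,
      Rcpp::Named("Go") = Go, Rcpp::Named("Cs") = Cs,
      Rcpp::Named("Tc") = Tc, Rcpp::Named("Hc") = Hs);
}

// [[Rcpp::export(name = ".lstm_bwd_cpp")]]
Rcpp::List lstm_bwd_cpp(const arma::mat& X, const arma::mat& W,
                        const arma::mat& U, const arma::fcube& Gi,
                        const arma::fcube& Gf, const arma::fcube& Gg,
                        const arma::fcube& Go, const arma::fcube& Cs,
                        const arma::fcube& Tc, const arma::fcube& Hc,
                        const arma::mat& dH, int B) {
  const int Tn = Gi.n_slices, H = W.n_cols / 4;
  const fmat Xf = as_f(X), Wf = as_f(W), Uf = as_f(U);
  const fcube dHc = to_cube(as_f(dH), B);
  fcube dZ(B, 4 * H, Tn);
  fmat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  const fmat Ut = Uf.t();
  for (int t = Tn - 1; t >= 0; --t) {
    const fmat& i = Gi.slice(t);
    const fmat& f = Gf.slice(t);
    const fmat& g = Gg.slice(t);
    const fmat& o = Go.slice(t);
    const fmat& tc = Tc.slice(t);
    fmat dh = dHc.slice(t) + dh_next;
    fmat dc = dc_next + dh % o % (1.0f - tc % tc);
    fmat dz(B, 4 * H);
    dz.cols(0, H - 1) = dc % g % i % (1.0f - i);
    if (t > 0) dz.cols(H, 2 * H - 1) = dc % Cs.slice(t - 1) % f % (1.0f - f);
    else dz.cols(H, 2 * H - 1).zeros();
    dz.cols(2 * H, 3 * H - 1) = dc % i % (1.0f - g % g);
    dz.cols(3 * H, 4 * H - 1) = dh % tc % o % (1.0f - o);
    dZ.slice(t) = dz;
    dh_next = dz * Ut;
    dc_next = dc % f;
  }
  // weight gradients and input gradient as single GEMMs over all steps
  const fmat dZm = to_mat(dZ);
  fcube Hprev(B, H, Tn, fill::zeros);
  for (int t = 1; t < Tn; ++t) Hprev.slice(t) = Hc.slice(t - 1);
  return Rcpp::List::create(
      Rcpp::Named("dW") = as_d(Xf.t() * dZm),
      Rcpp::Named("dU") = as_d(to_mat(Hprev).t() * dZm),
      Rcpp::Named("db") = as_d(sum(dZm, 0)),
      Rcpp::Named("dX") = as_d(dZm * Wf.t()));
}

// Fused Adam update over a flat list of parameter arrays. Returns fresh
// parameter arrays; the first/second-moment lists are updated in place
// (they are owned solely by the training loop).
// [[Rcpp::export(name = ".adam_step_cpp")]]
Rcpp::List adam_step_cpp(Rcpp::List params, Rcpp::List grads,
                         Rcpp::List m, Rcpp::List v,
                         int t, double lr, double beta1, double beta2,
                         double eps, double clipnorm) {
  const int K = params.size();
  double sq = 0.0;
  for (int k = 0; k < K; ++k) {
    Rcpp::NumericVector g(grads[k]);
    for (double x : g) sq += x * x;
  }
  const double gnorm = std::sqrt(sq);
  const double scale =
      (std::isfinite(gnorm) && gnorm > clipnorm) ? clipnorm / gnorm : 1.0;
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  Rcpp::List out(K);
  for (int k = 0; k < K; ++k) {
    Rcpp::NumericVector p(params[k]), g(grads[k]), mk(m[k]), vk(v[k]);
    const int n = p.size();
    Rcpp::NumericVector pn(Rcpp::clone(p));
    for (int j = 0; j < n; ++j) {
      const double gj = g[j] * scale;
      mk[j] = beta1 * mk[j] + (1.0 - beta1) * gj;
      vk[j] = beta2 * vk[j] + (1.0 - beta2) * gj * gj;
      pn[j] -= lr * (mk[j] / bc1) / (std::sqrt(vk[j] / bc2) + eps);
    }
    pn.attr("dim") = p.attr("dim");
    out[k] = pn;
  }
  out.names() = params.names();
  return out;
}
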