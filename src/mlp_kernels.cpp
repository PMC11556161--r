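// Fused multi-layer perceptron kernels: one C++ call evaluates a whole
// linear->SiLU->...->linear chain (optionally with a SiLU on the output) and
// one call backpropagates through it, so the R autodiff tape carries a single
// node per MLP instead of one per primitive op. Layer intermediates stay on
// the C++ side (external pointer) between the two calls.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct MlpCache {
  std::vector<mat> pre;   // pre-activations z_l
  std::vector<mat> acts;  // inputs to layer l
  std::vector<mat> W;     // weights (kept for the backward matmuls)
};

// layers: list of list(W, b); final_silu: apply SiLU after the last layer.
// [[Rcpp::export(name = ".cpp_mlp_forward")]]
Rcpp::List cpp_mlp_forward(const arma::mat& x, Rcpp::List layers,
                           bool final_silu) {
  int L = layers.size();
  Rcpp::XPtr<MlpCache> cache(new MlpCache(), true);
  cache->pre.resize(L);
  cache->acts.resize(L);
  cache->W.resize(L);
  mat cur = x;
  for (int l = 0; l < L; ++l) {
    Rcpp::List ly = layers[l];
    cache->W[l] = Rcpp::as<mat>(ly["W"]);
    rowvec b = Rcpp::as<rowvec>(ly["b"]);
    cache->acts[l] = cur;
    mat z = cur * cache->W[l];
    z.each_row() += b;
    if (l < L - 1 || final_silu) {
      cache->pre[l] = z;
      mat sig = 1.0 / (1.0 + exp(-z));
      cur = z % sig;
    } else {
      cur = std::move(z);  // linear output: no activation, no cache needed
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = cur,
                            Rcpp::Named("cache") = cache);
}

// Backward through the fused chain; g is the output gradient.
// [[Rcpp::export(name = ".cpp_mlp_backward")]]
Rcpp::List cpp_mlp_backward(const arma::mat& g, SEXP cache_sexp,
                            bool final_silu) {
  Rcpp::XPtr<MlpCache> cache(cache_sexp);
  int L = cache->W.size();
  Rcpp::List gW(L), gb(L);
  mat cur = g;
  for (int l = L - 1; l >= 0; --l) {
    if (l < L - 1 || final_silu) {
      const mat& z = cache->pre[l];
      mat sig = 1.0 / (1.0 + exp(-z));
      cur = cur % (sig + z % sig % (1.0 - sig));
    }
    gW[l] = cache->acts[l].t() * cur;
    gb[l] = sum(cur, 0);
    cur = cur * cache->W[l].t();
  }
  return Rcpp::List::create(Rcpp::Named("gx") = cur,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}
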