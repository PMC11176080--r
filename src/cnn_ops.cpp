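// Compiled kernels for the 1-D convolutional network.
//
// The full forward/backward pass over one minibatch runs in a single
// call (cnn_fused) with all activations kept on this side in single
// precision, the customary deep-learning precision; only parameters,
// inputs and gradients cross the interface as doubles.  Layer data is
// held in "stacked" form: a (length * batch) x channels matrix whose
// rows s*length .. (s+1)*length - 1 belong to sample s, so every
// convolution is one im2col plus one large GEMM.
//
// Standalone conv/pool kernels are exported as well for kernel-level
// tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col on a stacked activation matrix with zero ("same") padding;
// column block j holds the input shifted by j - pad within each sample
static void im2col_stacked(const fmat& A, int len, int batch, int k,
                           fmat& out) {
  const int cin = A.n_cols, pad = (k - 1) / 2;
  out.zeros(A.n_rows, k * cin);
  for (int s = 0; s < batch; ++s)
    for (int j = 0; j < k; ++j) {
      const int shift = j - pad;
      const int lo = std::max(0, -shift), hi = std::min(len, len - shift);
      if (lo >= hi) continue;
      out.submat(s * len + lo, j * cin, s * len + hi - 1,
                 (j + 1) * cin - 1) =
        A.rows(s * len + lo + shift, s * len + hi - 1 + shift);
    }
}

static void col2im_stacked(const fmat& dcols, int len, int batch, int k,
                           int cin, fmat& dA) {
  const int pad = (k - 1) / 2;
  dA.zeros(len * batch, cin);
  for (int s = 0; s < batch; ++s)
    for (int j = 0; j < k; ++j) {
      const int shift = j - pad;
      const int lo = std::max(0, -shift), hi = std::min(len, len - shift);
      if (lo >= hi) continue;
      dA.rows(s * len + lo + shift, s * len + hi - 1 + shift) +=
        dcols.submat(s * len + lo, j * cin, s * len + hi - 1,
                     (j + 1) * cin - 1);
    }
}

// max-pool size 2 (floor length) on stacked activations; argmax rows
// recorded for the backward scatter, ties to the earlier position
static void pool2_stacked(const fmat& R, int len, int batch, fmat& P,
                          umat& amax) {
  const int c = R.n_cols, out = len / 2;
  P.set_size(out * batch, c);
  amax.set_size(out * batch, c);
  for (int s = 0; s < batch; ++s)
    for (int j = 0; j < c; ++j)
      for (int i = 0; i < out; ++i) {
        const uword r0 = s * len + 2 * i;
        const float a = R(r0, j), b = R(r0 + 1, j);
        const uword ro = s * out + i;
        if (a >= b) { P(ro, j) = a; amax(ro, j) = r0; }
        else { P(ro, j) = b; amax(ro, j) = r0 + 1; }
      }
}

struct LayerCache {
  fmat cols;   // im2col of the layer input
  fmat R;      // post-ReLU, pre-pool activations (stacked)
  umat amax;   // pool argmax rows into R
  int len;     // input length of this layer
};

// [[Rcpp::export]]
Rcpp::List cnn_fused(Rcpp::List params, const arma::cube& X,
                     Rcpp::IntegerVector kernels,
                     Rcpp::Nullable<Rcpp::List> masks_,
                     Rcpp::Nullable<Rcpp::NumericVector> y_,
                     Rcpp::Nullable<Rcpp::NumericVector> dout_,
                     bool want_grads, bool input_grad) {
  const int len0 = X.n_rows, cin0 = X.n_cols, batch = X.n_slices;
  const int nconv = kernels.size();
  auto getm = [&](const std::string& nm) {
    return conv_to<fmat>::from(Rcpp::as<mat>(params[nm]));
  };
  auto getv = [&](const std::string& nm) {
    return conv_to<fvec>::from(Rcpp::as<vec>(params[nm]));
  };

  // entry: cube -> stacked
  fmat A(len0 * batch, cin0);
  for (int s = 0; s < batch; ++s)
    A.rows(s * len0, (s + 1) * len0 - 1) =
      conv_to<fmat>::from(X.slice(s));

  std::vector<LayerCache> cache(nconv);
  std::vector<fmat> Wc(nconv);
  int len = len0;
  for (int l = 0; l < nconv; ++l) {
    const int k = kernels[l];
    Wc[l] = getm("convW" + std::to_string(l + 1));
    fvec b = getv("convb" + std::to_string(l + 1));
    fmat cols;
    im2col_stacked(A, len, batch, k, cols);
    fmat Z = cols * Wc[l];
    Z.each_row() += b.t();
    Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    fmat P; umat amax;
    pool2_stacked(Z, len, batch, P, amax);
    if (want_grads) {
      cache[l].cols = std::move(cols);
      cache[l].R = std::move(Z);
      cache[l].amax = std::move(amax);
      cache[l].len = len;
    }
    A = std::move(P);
    len /= 2;
  }
  const int cfin = A.n_cols, flat = len * cfin;

  // flatten: H0(s, i + len*c) = A(s*len + i, c)
  fmat H0(batch, flat);
  for (int s = 0; s < batch; ++s)
    for (int c = 0; c < cfin; ++c)
      for (int i = 0; i < len; ++i)
        H0(s, i + len * c) = A(s * len + i, c);

  // dense layers (two hidden + linear output)
  fmat W1 = getm("denseW1"), W2 = getm("denseW2"), W3 = getm("denseW3");
  fvec b1 = getv("denseb1"), b2 = getv("denseb2"), b3 = getv("denseb3");
  fmat M1, M2;
  bool use_masks = masks_.isNotNull();
  if (use_masks) {
    Rcpp::List masks(masks_);
    M1 = conv_to<fmat>::from(Rcpp::as<mat>(masks[0]));
    M2 = conv_to<fmat>::from(Rcpp::as<mat>(masks[1]));
  }
  fmat R1 = H0 * W1; R1.each_row() += b1.t();
  R1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fmat H1 = use_masks ? fmat(R1 % M1) : R1;
  fmat R2 = H1 * W2; R2.each_row() += b2.t();
  R2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fmat H2 = use_masks ? fmat(R2 % M2) : R2;
  fvec pred = H2 * W3 + b3(0);

  Rcpp::NumericVector predR(pred.begin(), pred.end());
  double loss = NA_REAL;
  fvec dpred;
  if (y_.isNotNull()) {
    vec y = Rcpp::as<vec>(Rcpp::NumericVector(y_));
    fvec yf = conv_to<fvec>::from(y);
    loss = mean(square(conv_to<vec>::from(pred - yf)));
    dpred = 2.0f * (pred - yf) / (float)batch;
  }
  if (dout_.isNotNull())
    dpred = conv_to<fvec>::from(Rcpp::as<vec>(Rcpp::NumericVector(dout_)));
  if (!want_grads)
    return Rcpp::List::create(Rcpp::Named("pred") = predR,
                              Rcpp::Named("loss") = loss);

  Rcpp::List grads;
  // output layer
  fmat dW3 = H2.t() * dpred;
  float db3 = accu(dpred);
  fmat dH2 = dpred * W3.t();
  if (use_masks) dH2 %= M2;
  dH2.elem(find(R2 <= 0.0f)).zeros();
  fmat dW2 = H1.t() * dH2;
  frowvec db2 = sum(dH2, 0);
  fmat dH1 = dH2 * W2.t();
  if (use_masks) dH1 %= M1;
  dH1.elem(find(R1 <= 0.0f)).zeros();
  fmat dW1 = H0.t() * dH1;
  frowvec db1 = sum(dH1, 0);
  fmat dH0 = dH1 * W1.t();
  grads["denseW3"] = conv_to<mat>::from(dW3);
  grads["denseb3"] = Rcpp::NumericVector::create(db3);
  grads["denseW2"] = conv_to<mat>::from(dW2);
  grads["denseb2"] = conv_to<vec>::from(db2.t());
  grads["denseW1"] = conv_to<mat>::from(dW1);
  grads["denseb1"] = conv_to<vec>::from(db1.t());

  // unflatten
  fmat dP(len * batch, cfin);
  for (int s = 0; s < batch; ++s)
    for (int c = 0; c < cfin; ++c)
      for (int i = 0; i < len; ++i)
        dP(s * len + i, c) = dH0(s, i + len * c);

  for (int l = nconv - 1; l >= 0; --l) {
    const int k = kernels[l], inlen = cache[l].len;
    const int outlen = inlen / 2, cl = cache[l].R.n_cols;
    // pool backward: scatter into R-shaped matrix
    fmat dR(inlen * batch, cl, fill::zeros);
    for (int s = 0; s < batch; ++s)
      for (int j = 0; j < cl; ++j)
        for (int i = 0; i < outlen; ++i) {
          const uword ro = s * outlen + i;
          dR(cache[l].amax(ro, j), j) += dP(ro, j);
        }
    dR.elem(find(cache[l].R <= 0.0f)).zeros();
    fmat dWl = cache[l].cols.t() * dR;
    frowvec dbl = sum(dR, 0);
    grads["convW" + std::to_string(l + 1)] = conv_to<mat>::from(dWl);
    grads["convb" + std::to_string(l + 1)] = conv_to<vec>::from(dbl.t());
    if (l > 0 || input_grad) {
      fmat dcols = dR * Wc[l].t();
      const int cin = Wc[l].n_rows / k;
      fmat dA;
      col2im_stacked(dcols, inlen, batch, k, cin, dA);
      dP = std::move(dA);
    }
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("pred") = predR,
                                      Rcpp::Named("loss") = loss,
                                      Rcpp::Named("grads") = grads);
  if (input_grad) {
    cube dX(len0, cin0, batch);
    for (int s = 0; s < batch; ++s)
      dX.slice(s) = conv_to<mat>::from(
        fmat(dP.rows(s * len0, (s + 1) * len0 - 1)));
    out["dX"] = dX;
  }
  return out;
}

// ---- standalone kernels (cube interface), used for kernel-level tests ----

// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::mat& W,
                      const arma::vec& b, int k) {
  const int len = X.n_rows, cin = X.n_cols, batch = X.n_slices;
  fmat A(len * batch, cin);
  for (int s = 0; s < batch; ++s)
    A.rows(s * len, (s + 1) * len - 1) = conv_to<fmat>::from(X.slice(s));
  fmat cols;
  im2col_stacked(A, len, batch, k, cols);
  fmat Z = cols * conv_to<fmat>::from(W);
  Z.each_row() += conv_to<fvec>::from(b).t();
  cube Y(len, W.n_cols, batch);
  for (int s = 0; s < batch; ++s)
    Y.slice(s) = conv_to<mat>::from(fmat(Z.rows(s * len,
                                                (s + 1) * len - 1)));
  return Y;
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& X) {
  const int len = X.n_rows, c = X.n_cols, batch = X.n_slices;
  const int out = len / 2;
  cube Y(out, c, batch);
  ucube idx(out, c, batch);
  for (int s = 0; s < batch; ++s)
    for (int j = 0; j < c; ++j)
      for (int i = 0; i < out; ++i) {
        const double a = X(2 * i, j, s), b2 = X(2 * i + 1, j, s);
        if (a >= b2) { Y(i, j, s) = a; idx(i, j, s) = 2 * i; }
        else { Y(i, j, s) = b2; idx(i, j, s) = 2 * i + 1; }
      }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}
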