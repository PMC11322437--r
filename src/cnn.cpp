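// Patch-classifier CNN: 56x56x3 input -> conv(14x14, F1) -> batchnorm ->
// maxpool(2,2) -> ReLU -> conv(7x7, F2) -> batchnorm -> maxpool(2,2) -> ReLU
// -> fully-connected(2) -> softmax.  Trained by SGD with momentum on
// cross-entropy.  Implemented via im2col + BLAS gemm; all randomness
// (initial weights, shuffling) is injected from R so determinism is owned
// by R's RNG.
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

const double BN_EPS = 1e-5;

struct Geom {
  int in_h, in_w, in_c;   // input to conv
  int k;                  // kernel size
  int f;                  // filters
  int oh, ow;             // conv output spatial dims (valid padding)
  int ph, pw;             // pooled dims (2x2, stride 2, floor)
};

Geom make_geom(int in_h, int in_w, int in_c, int k, int f) {
  Geom g;
  g.in_h = in_h; g.in_w = in_w; g.in_c = in_c; g.k = k; g.f = f;
  g.oh = in_h - k + 1; g.ow = in_w - k + 1;
  g.ph = g.oh / 2; g.pw = g.ow / 2;
  return g;
}

// column p = r + oh*c holds the k x k x C patch at (r, c), flattened
// column-major (row fastest, then col, then channel).
void im2col(const double* x, const Geom& g, arma::mat& out) {
  const int kk = g.k * g.k;
  for (int c = 0; c < g.ow; ++c) {
    for (int r = 0; r < g.oh; ++r) {
      double* col = out.colptr(r + g.oh * c);
      for (int ch = 0; ch < g.in_c; ++ch) {
        const double* plane = x + static_cast<size_t>(ch) * g.in_h * g.in_w;
        for (int j = 0; j < g.k; ++j) {
          const double* src = plane + static_cast<size_t>(c + j) * g.in_h + r;
          std::copy(src, src + g.k, col + ch * kk + j * g.k);
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add columns back into the input gradient
void col2im(const arma::mat& cols, const Geom& g, double* dx) {
  const int kk = g.k * g.k;
  for (int c = 0; c < g.ow; ++c) {
    for (int r = 0; r < g.oh; ++r) {
      const double* col = cols.colptr(r + g.oh * c);
      for (int ch = 0; ch < g.in_c; ++ch) {
        double* plane = dx + static_cast<size_t>(ch) * g.in_h * g.in_w;
        for (int j = 0; j < g.k; ++j) {
          double* dst = plane + static_cast<size_t>(c + j) * g.in_h + r;
          const double* src = col + ch * kk + j * g.k;
          for (int i = 0; i < g.k; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// 2x2 max pool, stride 2; input (f, oh*ow), output (f, ph*pw); records argmax
void maxpool(const arma::mat& a, const Geom& g, arma::mat& out,
             arma::umat& amax) {
  for (int j = 0; j < g.pw; ++j) {
    for (int i = 0; i < g.ph; ++i) {
      const int q = i + g.ph * j;
      const int p00 = 2 * i + g.oh * (2 * j);
      const int cand[4] = {p00, p00 + 1, p00 + g.oh, p00 + g.oh + 1};
      for (int f = 0; f < g.f; ++f) {
        double best = a(f, cand[0]); int bi = cand[0];
        for (int t = 1; t < 4; ++t) {
          const double v = a(f, cand[t]);
          if (v > best) { best = v; bi = cand[t]; }
        }
        out(f, q) = best;
        amax(f, q) = static_cast<arma::uword>(bi);
      }
    }
  }
}

struct Params {
  arma::mat W1, W2, Wfc;
  arma::vec b1, g1, be1, rm1, rv1;
  arma::vec b2, g2, be2, rm2, rv2;
  arma::vec bfc;
};

Params read_params(const List& par) {
  Params p;
  p.W1 = as<arma::mat>(par["W1"]);   p.b1 = as<arma::vec>(par["b1"]);
  p.g1 = as<arma::vec>(par["gamma1"]); p.be1 = as<arma::vec>(par["beta1"]);
  p.rm1 = as<arma::vec>(par["rmean1"]); p.rv1 = as<arma::vec>(par["rvar1"]);
  p.W2 = as<arma::mat>(par["W2"]);   p.b2 = as<arma::vec>(par["b2"]);
  p.g2 = as<arma::vec>(par["gamma2"]); p.be2 = as<arma::vec>(par["beta2"]);
  p.rm2 = as<arma::vec>(par["rmean2"]); p.rv2 = as<arma::vec>(par["rvar2"]);
  p.Wfc = as<arma::mat>(par["Wfc"]); p.bfc = as<arma::vec>(par["bfc"]);
  return p;
}

List write_params(const Params& p) {
  return List::create(
    _["W1"] = p.W1, _["b1"] = p.b1, _["gamma1"] = p.g1, _["beta1"] = p.be1,
    _["rmean1"] = p.rm1, _["rvar1"] = p.rv1,
    _["W2"] = p.W2, _["b2"] = p.b2, _["gamma2"] = p.g2, _["beta2"] = p.be2,
    _["rmean2"] = p.rm2, _["rvar2"] = p.rv2,
    _["Wfc"] = p.Wfc, _["bfc"] = p.bfc);
}

// forward for a batch stored as cubes indexed [feature, position, sample];
// when `training`, batch statistics are used and caches are filled.
struct LayerCache {
  arma::cube a;      // conv pre-BN
  arma::cube xhat;   // BN normalized
  arma::cube h;      // post-ReLU pooled activations
  arma::ucube amax;  // pool argmax
  arma::vec mu, var; // batch stats actually used
};

void conv_block_forward(const std::vector<const double*>& xs,
                        const Geom& g, const arma::mat& W, const arma::vec& b,
                        const arma::vec& gamma, const arma::vec& beta,
                        arma::vec& rmean, arma::vec& rvar, bool training,
                        double bn_momentum, LayerCache& cache) {
  const int B = static_cast<int>(xs.size());
  const int P = g.oh * g.ow;
  const int Q = g.ph * g.pw;
  arma::mat cols(static_cast<arma::uword>(g.k) * g.k * g.in_c, P);
  cache.h.set_size(g.f, Q, B);
  if (!training) {
    // lean inference path: running statistics, no caches beyond h
    arma::vec inv_sd = 1.0 / arma::sqrt(rvar + BN_EPS);
    arma::mat a(g.f, P), pooled(g.f, Q);
    arma::umat amax(g.f, Q);
    for (int n = 0; n < B; ++n) {
      im2col(xs[n], g, cols);
      a = W * cols;
      a.each_col() += b - rmean;
      a.each_col() %= gamma % inv_sd;
      a.each_col() += beta;
      maxpool(a, g, pooled, amax);
      cache.h.slice(n) = arma::clamp(pooled, 0.0, arma::datum::inf);
    }
    return;
  }
  cache.a.set_size(g.f, P, B);
  for (int n = 0; n < B; ++n) {
    im2col(xs[n], g, cols);
    cache.a.slice(n) = W * cols;
    cache.a.slice(n).each_col() += b;
  }
  // batch norm per feature over (position, sample)
  const double N = static_cast<double>(P) * B;
  arma::vec mu(g.f, arma::fill::zeros), var(g.f, arma::fill::zeros);
  for (int n = 0; n < B; ++n) mu += arma::sum(cache.a.slice(n), 1);
  mu /= N;
  for (int n = 0; n < B; ++n) {
    arma::mat d = cache.a.slice(n);
    d.each_col() -= mu;
    var += arma::sum(arma::square(d), 1);
  }
  var /= N;
  rmean = (1.0 - bn_momentum) * rmean + bn_momentum * mu;
  rvar  = (1.0 - bn_momentum) * rvar  + bn_momentum * var;
  cache.mu = mu; cache.var = var;
  arma::vec inv_sd = 1.0 / arma::sqrt(var + BN_EPS);
  cache.xhat.set_size(g.f, P, B);
  cache.amax.set_size(g.f, Q, B);
  arma::mat pooled(g.f, Q);
  arma::umat amax(g.f, Q);
  for (int n = 0; n < B; ++n) {
    arma::mat xh = cache.a.slice(n);
    xh.each_col() -= mu;
    xh.each_col() %= inv_sd;
    cache.xhat.slice(n) = xh;
    xh.each_col() %= gamma;
    xh.each_col() += beta;
    maxpool(xh, g, pooled, amax);
    cache.h.slice(n) = arma::clamp(pooled, 0.0, arma::datum::inf);
    cache.amax.slice(n) = amax;
  }
}

// backward through ReLU -> pool -> BN -> conv for one block.
// din: gradient wrt cache.h (f, Q, B).  Returns gradient wrt block input
// planes in dxs (caller-allocated, zero-filled) unless dxs empty.
void conv_block_backward(const std::vector<const double*>& xs,
                         const Geom& g, const arma::mat& W,
                         const arma::vec& gamma, const LayerCache& cache,
                         const arma::cube& din,
                         arma::mat& dW, arma::vec& db, arma::vec& dgamma,
                         arma::vec& dbeta, std::vector<double*>* dxs) {
  const int B = static_cast<int>(xs.size());
  const int P = g.oh * g.ow;
  const int Q = g.ph * g.pw;
  const double N = static_cast<double>(P) * B;
  arma::vec inv_sd = 1.0 / arma::sqrt(cache.var + BN_EPS);

  // route gradients: ReLU mask then scatter to conv positions (pre-BN scale)
  arma::cube dy(g.f, P, B, arma::fill::zeros);  // grad wrt BN output
  for (int n = 0; n < B; ++n) {
    for (int q = 0; q < Q; ++q) {
      for (int f = 0; f < g.f; ++f) {
        if (cache.h(f, q, n) > 0.0) {
          dy(f, cache.amax(f, q, n), n) += din(f, q, n);
        }
      }
    }
  }
  // BN backward (per feature over position x sample)
  arma::vec sum_dy(g.f, arma::fill::zeros), sum_dyx(g.f, arma::fill::zeros);
  for (int n = 0; n < B; ++n) {
    sum_dy += arma::sum(dy.slice(n), 1);
    sum_dyx += arma::sum(dy.slice(n) % cache.xhat.slice(n), 1);
  }
  dgamma = sum_dyx;
  dbeta = sum_dy;
  arma::vec mean_dy = sum_dy / N, mean_dyx = sum_dyx / N;
  arma::mat cols(static_cast<arma::uword>(g.k) * g.k * g.in_c, P);
  dW.zeros(); db.zeros();
  for (int n = 0; n < B; ++n) {
    arma::mat da = dy.slice(n);
    da.each_col() %= gamma;
    da -= cache.xhat.slice(n).each_col() % (gamma % mean_dyx);
    da.each_col() -= gamma % mean_dy;
    da.each_col() %= inv_sd;
    // conv grads
    im2col(xs[n], g, cols);
    dW += da * cols.t();
    db += arma::sum(da, 1);
    if (dxs) {
      arma::mat dcols = W.t() * da;
      col2im(dcols, g, (*dxs)[n]);
    }
  }
}

void softmax_cols(arma::mat& z) {
  for (arma::uword j = 0; j < z.n_cols; ++j) {
    const double m = z.col(j).max();
    z.col(j) = arma::exp(z.col(j) - m);
    z.col(j) /= arma::accu(z.col(j));
  }
}

// full forward pass on raw (already normalized) patches laid out as a
// (in_h*in_w*c_data) x B matrix of input planes.  c_data may be smaller
// than the declared input channels: trailing channels are implicitly zero
// (the red-channel embedding), in which case only the leading columns of
// W1 contribute and the rest are skipped.
arma::mat forward_probs(const arma::mat& X, int in_h, int in_w, int k1,
                        int k2, Params& p, bool training, double bn_momentum,
                        LayerCache& c1, LayerCache& c2, arma::mat& feats) {
  const int B = static_cast<int>(X.n_cols);
  const int c_data = static_cast<int>(X.n_rows) / (in_h * in_w);
  Geom g1 = make_geom(in_h, in_w, c_data, k1, static_cast<int>(p.W1.n_rows));
  Geom g2 = make_geom(g1.ph, g1.pw, g1.f, k2, static_cast<int>(p.W2.n_rows));
  std::vector<const double*> xs1(B);
  for (int n = 0; n < B; ++n) xs1[n] = X.colptr(n);
  const arma::uword used1 = static_cast<arma::uword>(k1) * k1 * c_data;
  const arma::mat W1u = p.W1.head_cols(used1);
  conv_block_forward(xs1, g1, W1u, p.b1, p.g1, p.be1,
                     p.rm1, p.rv1, training, bn_momentum, c1);
  std::vector<const double*> xs2(B);
  for (int n = 0; n < B; ++n) xs2[n] = c1.h.slice(n).memptr();
  conv_block_forward(xs2, g2, p.W2, p.b2, p.g2, p.be2,
                     p.rm2, p.rv2, training, bn_momentum, c2);
  feats.set_size(static_cast<arma::uword>(g2.f) * g2.ph * g2.pw, B);
  for (int n = 0; n < B; ++n) {
    feats.col(n) = arma::vectorise(c2.h.slice(n));
  }
  arma::mat logits = p.Wfc * feats;
  logits.each_col() += p.bfc;
  softmax_cols(logits);
  return logits;
}

} // namespace

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
arma::mat cnn_forward_cpp(const arma::mat& X, int in_h, int in_w, int k1,
                          int k2, List par) {
  Params p = read_params(par);
  LayerCache c1, c2;
  arma::mat feats;
  return forward_probs(X, in_h, in_w, k1, k2, p, false, 0.0, c1, c2, feats);
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(const arma::mat& X, const arma::ivec& y, int in_h,
                   int in_w, int k1, int k2, List par,
                   const arma::imat& order, double lr, double momentum,
                   int batch_size, double bn_momentum) {
  Params p = read_params(par);
  const int epochs = static_cast<int>(order.n_cols);
  const int Ntr = static_cast<int>(order.n_rows);
  const int c_data = static_cast<int>(X.n_rows) / (in_h * in_w);
  Geom g1 = make_geom(in_h, in_w, c_data, k1, static_cast<int>(p.W1.n_rows));
  Geom g2 = make_geom(g1.ph, g1.pw, g1.f, k2, static_cast<int>(p.W2.n_rows));
  // only the weight columns fed by non-zero input channels are trained;
  // the remainder stay at their initial values (their inputs are zero)
  const arma::uword used1 = static_cast<arma::uword>(k1) * k1 * c_data;
  arma::mat W1_tail;
  if (used1 < p.W1.n_cols) W1_tail = p.W1.tail_cols(p.W1.n_cols - used1);
  const arma::uword full1 = p.W1.n_cols;
  p.W1 = p.W1.head_cols(used1);

  arma::mat vW1(arma::size(p.W1), arma::fill::zeros);
  arma::mat vW2(arma::size(p.W2), arma::fill::zeros);
  arma::mat vWfc(arma::size(p.Wfc), arma::fill::zeros);
  arma::vec vb1(arma::size(p.b1), arma::fill::zeros);
  arma::vec vb2(arma::size(p.b2), arma::fill::zeros);
  arma::vec vbfc(arma::size(p.bfc), arma::fill::zeros);
  arma::vec vg1(arma::size(p.g1), arma::fill::zeros);
  arma::vec vg2(arma::size(p.g2), arma::fill::zeros);
  arma::vec vbe1(arma::size(p.be1), arma::fill::zeros);
  arma::vec vbe2(arma::size(p.be2), arma::fill::zeros);

  arma::vec epoch_loss(epochs, arma::fill::zeros);
  arma::mat dW1(arma::size(p.W1)), dW2(arma::size(p.W2));
  arma::vec db1(arma::size(p.b1)), db2(arma::size(p.b2));
  arma::vec dg1(arma::size(p.g1)), dg2(arma::size(p.g2));
  arma::vec dbe1(arma::size(p.be1)), dbe2(arma::size(p.be2));

  LayerCache c1, c2;
  arma::mat feats;
  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0.0;
    int n_batches = 0;
    for (int start = 0; start < Ntr; start += batch_size) {
      const int B = std::min(batch_size, Ntr - start);
      arma::mat Xb(X.n_rows, B);
      arma::ivec yb(B);
      for (int n = 0; n < B; ++n) {
        const int idx = order(start + n, e) - 1;  // 1-based from R
        Xb.col(n) = X.col(idx);
        yb(n) = y(idx);
      }
      arma::mat probs = forward_probs(Xb, in_h, in_w, k1, k2, p, true,
                                      bn_momentum, c1, c2, feats);
      double loss = 0.0;
      arma::mat dlogits = probs;
      for (int n = 0; n < B; ++n) {
        loss -= std::log(std::max(probs(yb(n), n), 1e-300));
        dlogits(yb(n), n) -= 1.0;
      }
      loss /= B;
      dlogits /= B;
      loss_sum += loss; ++n_batches;

      arma::mat dWfc = dlogits * feats.t();
      arma::vec dbfc = arma::sum(dlogits, 1);
      arma::mat dfeats = p.Wfc.t() * dlogits;

      const int Q2 = g2.ph * g2.pw;
      arma::cube din2(g2.f, Q2, B);
      for (int n = 0; n < B; ++n) {
        din2.slice(n) = arma::reshape(dfeats.col(n), g2.f, Q2);
      }
      std::vector<const double*> xs2(B), xs1(B);
      for (int n = 0; n < B; ++n) xs2[n] = c1.h.slice(n).memptr();
      for (int n = 0; n < B; ++n) xs1[n] = Xb.colptr(n);

      // gradient wrt layer-1 pooled activations
      arma::cube dh1(g1.f, static_cast<arma::uword>(g1.ph) * g1.pw, B,
                     arma::fill::zeros);
      std::vector<double*> dxs2(B);
      for (int n = 0; n < B; ++n) dxs2[n] = dh1.slice(n).memptr();
      conv_block_backward(xs2, g2, p.W2, p.g2, c2, din2, dW2, db2, dg2,
                          dbe2, &dxs2);
      conv_block_backward(xs1, g1, p.W1, p.g1, c1, dh1, dW1, db1, dg1,
                          dbe1, nullptr);

      // SGD with momentum
      vW1 = momentum * vW1 - lr * dW1;   p.W1 += vW1;
      vb1 = momentum * vb1 - lr * db1;   p.b1 += vb1;
      vg1 = momentum * vg1 - lr * dg1;   p.g1 += vg1;
      vbe1 = momentum * vbe1 - lr * dbe1; p.be1 += vbe1;
      vW2 = momentum * vW2 - lr * dW2;   p.W2 += vW2;
      vb2 = momentum * vb2 - lr * db2;   p.b2 += vb2;
      vg2 = momentum * vg2 - lr * dg2;   p.g2 += vg2;
      vbe2 = momentum * vbe2 - lr * dbe2; p.be2 += vbe2;
      vWfc = momentum * vWfc - lr * dWfc; p.Wfc += vWfc;
      vbfc = momentum * vbfc - lr * dbfc; p.bfc += vbfc;
    }
    epoch_loss(e) = loss_sum / std::max(n_batches, 1);
  }
  if (used1 < full1) p.W1 = arma::join_rows(p.W1, W1_tail);
  return List::create(_["params"] = write_params(p),
                      _["epoch_loss"] = epoch_loss);
}

// Sliding-window detection helper: z-scores (clip at 0) the 56x56 patch
// centred (at patch index (28,28), 0-based) on each requested pixel and
// classifies it.  Channels 2-3 of the network input are zero by the
// red-channel embedding convention, so only the first-channel weights
// contribute.  Returns the neuron-class posterior per centre.
// [[Rcpp::export(name = ".cnn_classify_centers_cpp")]]
arma::vec cnn_classify_centers_cpp(const arma::mat& image,
                                   const arma::ivec& center_r,
                                   const arma::ivec& center_c,
                                   List par, int half_lo, int patch,
                                   int k1, int k2, int batch_size) {
  Params p = read_params(par);
  const int n = static_cast<int>(center_r.n_elem);
  const int pp = patch * patch;
  arma::vec post(n);
  for (int start = 0; start < n; start += batch_size) {
    const int B = std::min(batch_size, n - start);
    arma::mat X(static_cast<arma::uword>(pp), B);
    for (int t = 0; t < B; ++t) {
      const int r0 = center_r(start + t) - half_lo;  // 0-based top row
      const int c0 = center_c(start + t) - half_lo;
      arma::mat pat = image.submat(r0, c0, r0 + patch - 1, c0 + patch - 1);
      const double mu = arma::mean(arma::vectorise(pat));
      const double sd = arma::stddev(arma::vectorise(pat), 1);
      if (sd > 0.0) {
        pat = arma::clamp((pat - mu) / sd, 0.0, arma::datum::inf);
      } else {
        pat.zeros();
      }
      X.col(t) = arma::vectorise(pat);
    }
    LayerCache c1, c2;
    arma::mat feats;
    arma::mat probs = forward_probs(X, patch, patch, k1, k2, p, false, 0.0,
                                    c1, c2, feats);
    for (int t = 0; t < B; ++t) post(start + t) = probs(1, t);
  }
  return post;
}
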