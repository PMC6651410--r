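// Sequence-to-sequence LSTM for inclination-angle regression.
//
// Forward pass, backpropagation through time, and Adam updates for a stacked
// LSTM (sigmoid gates, tanh state activation) with a linear read-out layer.
// All stochastic choices (weight initialization, minibatch order) are made on
// the R side, so these routines are purely deterministic.
//
// Shapes: sequences are cube slices; X is (T x D x N), Y is (T x K x N).
// Per layer l: Wx[l] is (4H x D_l), Wh[l] is (4H x H), b[l] is (4H).
// Gate row blocks in order: input, forget, candidate, output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LstmParams {
  std::vector<mat> Wx, Wh;
  std::vector<vec> b;
  mat V;   // K x H
  vec c;   // K
};

LstmParams unpack(const Rcpp::List& w) {
  LstmParams p;
  Rcpp::List Wx = w["Wx"], Wh = w["Wh"], b = w["b"];
  for (int l = 0; l < Wx.size(); ++l) {
    p.Wx.push_back(Rcpp::as<mat>(Wx[l]));
    p.Wh.push_back(Rcpp::as<mat>(Wh[l]));
    p.b.push_back(Rcpp::as<vec>(b[l]));
  }
  p.V = Rcpp::as<mat>(w["V"]);
  p.c = Rcpp::as<vec>(w["c"]);
  return p;
}

Rcpp::List pack(const LstmParams& p) {
  Rcpp::List Wx, Wh, b;
  for (size_t l = 0; l < p.Wx.size(); ++l) {
    Wx.push_back(p.Wx[l]);
    Wh.push_back(p.Wh[l]);
    b.push_back(p.b[l]);
  }
  return Rcpp::List::create(Rcpp::Named("Wx") = Wx, Rcpp::Named("Wh") = Wh,
                            Rcpp::Named("b") = b, Rcpp::Named("V") = p.V,
                            Rcpp::Named("c") = p.c);
}

inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// cached forward pass for one minibatch
struct ForwardCache {
  // [layer][t] matrices of size H x B
  std::vector<std::vector<mat>> gi, gf, gg, go, cs, hs;
  std::vector<mat> yhat; // [t] K x B
};

// Xb: T x D x B cube. Returns cache; if light = true only hs/yhat are kept.
ForwardCache forward(const LstmParams& p, const cube& Xb, bool light) {
  const int L = p.Wx.size();
  const int T = Xb.n_rows;
  const int B = Xb.n_slices;
  const int H = p.Wh[0].n_cols;
  ForwardCache f;
  f.gi.resize(L); f.gf.resize(L); f.gg.resize(L); f.go.resize(L);
  f.cs.resize(L); f.hs.resize(L);
  std::vector<mat> h(L, mat(H, B, fill::zeros));
  std::vector<mat> c(L, mat(H, B, fill::zeros));
  f.yhat.resize(T);
  for (int t = 0; t < T; ++t) {
    // input at time t for layer 0: D x B
    mat x(Xb.n_cols, B);
    for (int s = 0; s < B; ++s) x.col(s) = Xb.slice(s).row(t).t();
    for (int l = 0; l < L; ++l) {
      const mat& inp = (l == 0) ? x : h[l - 1];
      mat A = p.Wx[l] * inp + p.Wh[l] * h[l] + repmat(p.b[l], 1, B);
      mat i = sigm(A.rows(0, H - 1));
      mat fg = sigm(A.rows(H, 2 * H - 1));
      mat g = tanh(A.rows(2 * H, 3 * H - 1));
      mat o = sigm(A.rows(3 * H, 4 * H - 1));
      c[l] = fg % c[l] + i % g;
      h[l] = o % tanh(c[l]);
      if (!light) {
        f.gi[l].push_back(i); f.gf[l].push_back(fg);
        f.gg[l].push_back(g); f.go[l].push_back(o);
        f.cs[l].push_back(c[l]);
      }
      f.hs[l].push_back(h[l]);
    }
    f.yhat[t] = p.V * h[L - 1] + repmat(p.c, 1, B);
  }
  return f;
}

// gather minibatch slices into a cube
cube gather(const cube& X, const uvec& idx) {
  cube out(X.n_rows, X.n_cols, idx.n_elem);
  for (uword s = 0; s < idx.n_elem; ++s) out.slice(s) = X.slice(idx[s]);
  return out;
}

double mse_on(const LstmParams& p, const cube& X, const cube& Y) {
  ForwardCache f = forward(p, X, true);
  const int T = X.n_rows, B = X.n_slices, K = Y.n_cols;
  double acc = 0.0;
  for (int t = 0; t < T; ++t) {
    mat yt(K, B);
    for (int s = 0; s < B; ++s) yt.col(s) = Y.slice(s).row(t).t();
    acc += accu(square(f.yhat[t] - yt));
  }
  return acc / (double(T) * B * K);
}


// loss and parameter gradients for one batch; gradients written into g
double backward(const LstmParams& p, const cube& Xb, const cube& Yb,
                double lambda, LstmParams& g) {
  const int L = p.Wx.size();
  const int T = Xb.n_rows;
  const int B = Xb.n_slices;
  const int K = Yb.n_cols;
  const int H = p.Wh[0].n_cols;
  ForwardCache f = forward(p, Xb, false);
  for (int l = 0; l < L; ++l) { g.Wx[l].zeros(); g.Wh[l].zeros(); g.b[l].zeros(); }
  g.V.zeros(); g.c.zeros();
  std::vector<mat> dh_next(L, mat(H, B, fill::zeros));
  std::vector<mat> dc_next(L, mat(H, B, fill::zeros));
  const double denom = double(T) * B * K;
  double loss = 0.0;
  for (int t = T - 1; t >= 0; --t) {
    mat yt(K, B), xt(Xb.n_cols, B);
    for (int s = 0; s < B; ++s) {
      yt.col(s) = Yb.slice(s).row(t).t();
      xt.col(s) = Xb.slice(s).row(t).t();
    }
    mat dy = 2.0 * (f.yhat[t] - yt) / denom;
    loss += accu(square(f.yhat[t] - yt));
    g.V += dy * f.hs[L - 1][t].t();
    g.c += sum(dy, 1);
    mat from_above = p.V.t() * dy; // H x B into top layer
    for (int l = L - 1; l >= 0; --l) {
      mat dh = from_above + dh_next[l];
      const mat& i = f.gi[l][t];
      const mat& fg = f.gf[l][t];
      const mat& gg = f.gg[l][t];
      const mat& o = f.go[l][t];
      const mat& ct = f.cs[l][t];
      mat tc = tanh(ct);
      mat dct = dh % o % (1.0 - square(tc)) + dc_next[l];
      mat cprev = (t > 0) ? f.cs[l][t - 1] : mat(H, B, fill::zeros);
      mat da_i = (dct % gg) % (i % (1.0 - i));
      mat da_f = (dct % cprev) % (fg % (1.0 - fg));
      mat da_g = (dct % i) % (1.0 - square(gg));
      mat da_o = (dh % tc) % (o % (1.0 - o));
      dc_next[l] = dct % fg;
      mat dA = join_cols(join_cols(da_i, da_f), join_cols(da_g, da_o));
      const mat& inp = (l == 0) ? xt : f.hs[l - 1][t];
      mat hprev = (t > 0) ? f.hs[l][t - 1] : mat(H, B, fill::zeros);
      g.Wx[l] += dA * inp.t();
      g.Wh[l] += dA * hprev.t();
      g.b[l] += sum(dA, 1);
      dh_next[l] = p.Wh[l].t() * dA;
      if (l > 0) from_above = p.Wx[l].t() * dA;
    }
  }
  loss /= denom;
  // L2 weight penalty (weights only, not biases)
  double pen = 0.0;
  for (int l = 0; l < L; ++l) {
    g.Wx[l] += 2.0 * lambda * p.Wx[l];
    g.Wh[l] += 2.0 * lambda * p.Wh[l];
    pen += accu(square(p.Wx[l])) + accu(square(p.Wh[l]));
  }
  g.V += 2.0 * lambda * p.V;
  pen += accu(square(p.V));
  loss += lambda * pen;
  return loss;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const arma::cube& X, const arma::cube& Y,
                          const Rcpp::List& w0, const arma::imat& order,
                          int batch, double lr, double lambda,
                          const arma::cube& Xval, const arma::cube& Yval,
                          double clipnorm) {
  LstmParams p = unpack(w0);
  const int L = p.Wx.size();
  const int T = X.n_rows;
  const int K = Y.n_cols;
  const int H = p.Wh[0].n_cols;
  const int epochs = order.n_rows;
  const int n = order.n_cols;

  // Adam state mirrors the parameter layout
  LstmParams m = p, v = p;
  for (int l = 0; l < L; ++l) {
    m.Wx[l].zeros(); m.Wh[l].zeros(); m.b[l].zeros();
    v.Wx[l].zeros(); v.Wh[l].zeros(); v.b[l].zeros();
  }
  m.V.zeros(); m.c.zeros(); v.V.zeros(); v.c.zeros();
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  vec train_loss(epochs, fill::zeros), val_mse(epochs, fill::zeros);

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch) {
      int stop = std::min(start + batch - 1, n - 1);
      uvec idx(stop - start + 1);
      for (int j = start; j <= stop; ++j)
        idx[j - start] = order(ep, j) - 1; // 1-based from R
      cube Xb = gather(X, idx), Yb = gather(Y, idx);
      const int B = Xb.n_slices;

      LstmParams g = p;
      double loss = backward(p, Xb, Yb, lambda, g);

      // global gradient-norm clipping
      double nrm2 = accu(square(g.V)) + accu(square(g.c));
      for (int l = 0; l < L; ++l)
        nrm2 += accu(square(g.Wx[l])) + accu(square(g.Wh[l])) +
                accu(square(g.b[l]));
      double scale = 1.0;
      double nrm = std::sqrt(nrm2);
      if (clipnorm > 0 && nrm > clipnorm) scale = clipnorm / nrm;

      // Adam
      ++step;
      const double bc1 = 1.0 - std::pow(b1, double(step));
      const double bc2 = 1.0 - std::pow(b2, double(step));
      auto adam = [&](mat& w, mat& mw, mat& vw, const mat& gw) {
        mat gs = gw * scale;
        mw = b1 * mw + (1.0 - b1) * gs;
        vw = b2 * vw + (1.0 - b2) * square(gs);
        w -= lr * (mw / bc1) / (sqrt(vw / bc2) + eps);
      };
      auto adamv = [&](vec& w, vec& mw, vec& vw, const vec& gw) {
        vec gs = gw * scale;
        mw = b1 * mw + (1.0 - b1) * gs;
        vw = b2 * vw + (1.0 - b2) * square(gs);
        w -= lr * (mw / bc1) / (sqrt(vw / bc2) + eps);
      };
      for (int l = 0; l < L; ++l) {
        adam(p.Wx[l], m.Wx[l], v.Wx[l], g.Wx[l]);
        adam(p.Wh[l], m.Wh[l], v.Wh[l], g.Wh[l]);
        adamv(p.b[l], m.b[l], v.b[l], g.b[l]);
      }
      adam(p.V, m.V, v.V, g.V);
      adamv(p.c, m.c, v.c, g.c);

      ep_loss += loss;
      ++n_batches;
    }
    train_loss[ep] = ep_loss / n_batches;
    val_mse[ep] = (Xval.n_slices > 0) ? mse_on(p, Xval, Yval) : datum::nan;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(Rcpp::Named("weights") = pack(p),
                            Rcpp::Named("train_loss") = train_loss,
                            Rcpp::Named("val_mse") = val_mse);
}

// [[Rcpp::export]]
arma::cube lstm_predict_cpp(const Rcpp::List& w, const arma::cube& X) {
  LstmParams p = unpack(w);
  ForwardCache f = forward(p, X, true);
  const int T = X.n_rows, B = X.n_slices, K = p.V.n_rows;
  cube out(T, K, B);
  for (int t = 0; t < T; ++t)
    for (int s = 0; s < B; ++s)
      out.slice(s).row(t) = f.yhat[t].col(s).t();
  return out;
}

// [[Rcpp::export]]
Rcpp::List lstm_grad_cpp(const Rcpp::List& w, const arma::cube& X,
                         const arma::cube& Y, double lambda) {
  LstmParams p = unpack(w);
  LstmParams g = p;
  double loss = backward(p, X, Y, lambda, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = pack(g));
}
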