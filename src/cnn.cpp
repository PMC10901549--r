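// 3D convolutional classifiers for X-Y-T photon-count stacks.
//
// Two small architectures (LeNet-style and ResNet-style) with hand-written
// forward/backward passes. Convolutions are 3x3x3, same-padded, implemented
// as im2col gathers followed by BLAS sgemm; pooling is 2x2x2 max; training
// is Adam on the softmax cross-entropy. Single precision throughout; all
// randomness (shuffling) comes from a seeded mt19937 so training is a pure
// function of (data, weights, seed).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace arma;

namespace {

struct Grid {
  int nx, ny, nt, D;
  Grid(int x, int y, int t) : nx(x), ny(y), nt(t), D(x * y * t) {}
};

// 27-neighbourhood index table for same-padded 3x3x3 conv: nbr(o, d) is the
// linear input index of offset o at output position d, or -1 outside.
struct ConvIdx {
  Mat<int> nbr;
  explicit ConvIdx(const Grid& g) : nbr(27, g.D) {
    for (int t = 0; t < g.nt; ++t)
      for (int y = 0; y < g.ny; ++y)
        for (int x = 0; x < g.nx; ++x) {
          int d = x + g.nx * (y + g.ny * t);
          int o = 0;
          for (int dt = -1; dt <= 1; ++dt)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx, ++o) {
                int xx = x + dx, yy = y + dy, tt = t + dt;
                nbr(o, d) =
                  (xx < 0 || yy < 0 || tt < 0 || xx >= g.nx || yy >= g.ny ||
                   tt >= g.nt)
                    ? -1
                    : xx + g.nx * (yy + g.ny * tt);
              }
        }
  }
};

// 2x2x2 max-pool index table (floor halving keeps all 8 children in range)
struct PoolIdx {
  Grid out;
  Mat<int> cand;  // 8 x Q
  explicit PoolIdx(const Grid& g)
      : out(g.nx / 2, g.ny / 2, g.nt / 2), cand(8, out.D) {
    for (int t = 0; t < out.nt; ++t)
      for (int y = 0; y < out.ny; ++y)
        for (int x = 0; x < out.nx; ++x) {
          int q = x + out.nx * (y + out.ny * t);
          int o = 0;
          for (int dt = 0; dt < 2; ++dt)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx, ++o)
                cand(o, q) =
                  (2 * x + dx) + g.nx * ((2 * y + dy) + g.ny * (2 * t + dt));
        }
  }
};

void im2col(const fmat& in, const Mat<int>& nbr, fmat& col) {
  const int C = in.n_rows, D = nbr.n_cols;
  if (C == 1) {
    const float* src = in.memptr();
    for (int d = 0; d < D; ++d) {
      float* dst = col.colptr(d);
      const int* nb = nbr.colptr(d);
      for (int o = 0; o < 27; ++o) dst[o] = nb[o] >= 0 ? src[nb[o]] : 0.f;
    }
    return;
  }
  for (int d = 0; d < D; ++d) {
    float* dst = col.colptr(d);
    const int* nb = nbr.colptr(d);
    for (int o = 0; o < 27; ++o) {
      int src = nb[o];
      if (src >= 0)
        std::memcpy(dst + o * C, in.colptr(src), C * sizeof(float));
      else
        std::memset(dst + o * C, 0, C * sizeof(float));
    }
  }
}

template <typename T>
inline void relu_(T& a) {
  float* p = a.memptr();
  const uword n = a.n_elem;
  for (uword i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
}

// zero entries of g where the forward activation a is zero (dead ReLU)
template <typename TA, typename TG>
inline void relu_mask(const TA& a, TG& g) {
  const float* pa = a.memptr();
  float* pg = g.memptr();
  const uword n = a.n_elem;
  for (uword i = 0; i < n; ++i)
    if (pa[i] == 0) pg[i] = 0;
}

void col2im(const fmat& dcol, const Mat<int>& nbr, fmat& din) {
  const int C = din.n_rows, D = nbr.n_cols;
  din.zeros();
  for (int d = 0; d < D; ++d) {
    const float* src = dcol.colptr(d);
    for (int o = 0; o < 27; ++o) {
      int dst = nbr(o, d);
      if (dst >= 0) {
        float* p = din.colptr(dst);
        const float* s = src + o * C;
        for (int c = 0; c < C; ++c) p[c] += s[c];
      }
    }
  }
}

void maxpool(const fmat& in, const PoolIdx& pi, fmat& out, Mat<int>& arg) {
  const int C = in.n_rows, Q = pi.out.D;
  out.set_size(C, Q);
  arg.set_size(C, Q);
  for (int q = 0; q < Q; ++q) {
    const int* cand = pi.cand.colptr(q);
    float* po = out.colptr(q);
    int* pa = arg.colptr(q);
    const float* p0 = in.colptr(cand[0]);
    for (int c = 0; c < C; ++c) { po[c] = p0[c]; pa[c] = cand[0]; }
    for (int o = 1; o < 8; ++o) {
      const float* p = in.colptr(cand[o]);
      for (int c = 0; c < C; ++c)
        if (p[c] > po[c]) { po[c] = p[c]; pa[c] = cand[o]; }
    }
  }
}

void maxpool_back(const fmat& dout, const Mat<int>& arg, fmat& din) {
  din.zeros();
  for (uword q = 0; q < dout.n_cols; ++q)
    for (uword c = 0; c < dout.n_rows; ++c)
      din(c, arg(c, q)) += dout(c, q);
}

struct Param {
  fmat W, g, m, v;
  explicit Param(const fmat& w) : W(w), g(size(w), fill::zeros),
                                  m(size(w), fill::zeros),
                                  v(size(w), fill::zeros) {}
};

struct Net {
  std::string arch;
  Grid g1;
  int K, c1, c2, pen;
  ConvIdx ci1;
  PoolIdx p1;
  Grid g2;
  ConvIdx ci2;
  PoolIdx p2;
  Grid g3;
  ConvIdx ci3;
  std::vector<Param> par;

  // per-sample activation buffers (reused)
  fmat col1, a1, pool1, col2, a2, pool2, colb, r1a, r1b, s1, colc, cold,
    r2a, r2b, s2;
  Mat<int> arg1, arg2;
  fvec flat, hid, logits, probs;

  Net(const std::string& arch_, int nx, int ny, int nt, int K_, int c1_,
      int c2_, int pen_, const Rcpp::List& weights)
      : arch(arch_), g1(nx, ny, nt), K(K_), c1(c1_), c2(c2_), pen(pen_),
        ci1(g1), p1(g1), g2(p1.out), ci2(g2), p2(g2), g3(p2.out), ci3(g3) {
    for (int i = 0; i < weights.size(); ++i) {
      Rcpp::NumericMatrix w = weights[i];
      fmat f(w.nrow(), w.ncol());
      for (int c = 0; c < w.ncol(); ++c)
        for (int r = 0; r < w.nrow(); ++r) f(r, c) = (float)w(r, c);
      par.emplace_back(f);
    }
    col1.set_size(27, g1.D);
  }

  int n_features() const { return pen; }

  // forward one sample (x: D1 vector); fills buffers, returns loss-ready probs
  void forward(const fvec& x) {
    fmat in(const_cast<float*>(x.memptr()), 1, g1.D, false, true);
    im2col(in, ci1.nbr, col1);
    a1 = par[0].W * col1;
    a1.each_col() += fvec(par[1].W.col(0));
    relu_(a1);
    maxpool(a1, p1, pool1, arg1);
    if (arch == "fli_lenet") {
      col2.set_size(27 * c1, g2.D);
      im2col(pool1, ci2.nbr, col2);
      a2 = par[2].W * col2;
      a2.each_col() += fvec(par[3].W.col(0));
      relu_(a2);
      maxpool(a2, p2, pool2, arg2);
      flat = vectorise(pool2);
      hid = par[4].W * flat + par[5].W.col(0);
      relu_(hid);
      logits = par[6].W * hid + par[7].W.col(0);
    } else {
      colb.set_size(27 * c1, g2.D);
      im2col(pool1, ci2.nbr, colb);
      r1a = par[2].W * colb;
      r1a.each_col() += fvec(par[3].W.col(0));
      relu_(r1a);
      colc.set_size(27 * c1, g2.D);
      im2col(r1a, ci2.nbr, colc);
      r1b = par[4].W * colc;
      r1b.each_col() += fvec(par[5].W.col(0));
      s1 = pool1 + r1b;
      relu_(s1);
      maxpool(s1, p2, pool2, arg2);
      cold.set_size(27 * c1, g3.D);
      im2col(pool2, ci3.nbr, cold);
      r2a = par[6].W * cold;
      r2a.each_col() += fvec(par[7].W.col(0));
      relu_(r2a);
      col2.set_size(27 * c1, g3.D);
      im2col(r2a, ci3.nbr, col2);
      r2b = par[8].W * col2;
      r2b.each_col() += fvec(par[9].W.col(0));
      s2 = pool2 + r2b;
      relu_(s2);
      // global average over X,Y per (channel, t)
      flat.set_size(c1 * g3.nt);
      const int plane = g3.nx * g3.ny;
      for (int t = 0; t < g3.nt; ++t) {
        fvec acc(c1, fill::zeros);
        for (int pxy = 0; pxy < plane; ++pxy)
          acc += s2.col(t * plane + pxy);
        flat.subvec(t * c1, (t + 1) * c1 - 1) = acc / (float)plane;
      }
      hid = par[10].W * flat + par[11].W.col(0);
      relu_(hid);
      logits = par[12].W * hid + par[13].W.col(0);
    }
    fvec z = logits - logits.max();
    probs = exp(z);
    probs /= accu(probs);
  }

  // backward one sample; accumulates into par[i].g
  void backward(const fvec& x, int y) {
    fvec dlog = probs;
    dlog(y) -= 1.f;
    if (arch == "fli_lenet") {
      par[6].g += dlog * hid.t();
      par[7].g.col(0) += dlog;
      fvec dhid = par[6].W.t() * dlog;
      for (int i = 0; i < pen; ++i) if (hid(i) <= 0) dhid(i) = 0;
      par[4].g += dhid * flat.t();
      par[5].g.col(0) += dhid;
      fvec dflat = par[4].W.t() * dhid;
      fmat dpool2(dflat.memptr(), c2, g3.D, false, true);
      fmat da2(c2, g2.D);
      maxpool_back(dpool2, arg2, da2);
      relu_mask(a2, da2);
      par[2].g += da2 * col2.t();
      par[3].g.col(0) += sum(da2, 1);
      fmat dcol2 = par[2].W.t() * da2;
      fmat dpool1(c1, g2.D);
      col2im(dcol2, ci2.nbr, dpool1);
      fmat da1(c1, g1.D);
      maxpool_back(dpool1, arg1, da1);
      relu_mask(a1, da1);
      par[0].g += da1 * col1.t();
      par[1].g.col(0) += sum(da1, 1);
    } else {
      par[12].g += dlog * hid.t();
      par[13].g.col(0) += dlog;
      fvec dhid = par[12].W.t() * dlog;
      relu_mask(hid, dhid);
      par[10].g += dhid * flat.t();
      par[11].g.col(0) += dhid;
      fvec dflat = par[10].W.t() * dhid;
      const int plane = g3.nx * g3.ny;
      fmat ds2(c1, g3.D);
      for (int t = 0; t < g3.nt; ++t) {
        fvec dv = dflat.subvec(t * c1, (t + 1) * c1 - 1) / (float)plane;
        for (int pxy = 0; pxy < plane; ++pxy)
          ds2.col(t * plane + pxy) = dv;
      }
      relu_mask(s2, ds2);
      // block 2: ds2 flows to r2b and (skip) to pool2
      par[8].g += ds2 * col2.t();
      par[9].g.col(0) += sum(ds2, 1);
      fmat dcol = par[8].W.t() * ds2;
      fmat dr2a(c1, g3.D);
      col2im(dcol, ci3.nbr, dr2a);
      relu_mask(r2a, dr2a);
      par[6].g += dr2a * cold.t();
      par[7].g.col(0) += sum(dr2a, 1);
      fmat dcol0 = par[6].W.t() * dr2a;
      fmat dpool2(c1, g3.D);
      col2im(dcol0, ci3.nbr, dpool2);
      dpool2 += ds2;  // identity skip
      fmat ds1(c1, g2.D);
      maxpool_back(dpool2, arg2, ds1);
      relu_mask(s1, ds1);
      // block 1
      par[4].g += ds1 * colc.t();
      par[5].g.col(0) += sum(ds1, 1);
      fmat dcolc = par[4].W.t() * ds1;
      fmat dr1a(c1, g2.D);
      col2im(dcolc, ci2.nbr, dr1a);
      relu_mask(r1a, dr1a);
      par[2].g += dr1a * colb.t();
      par[3].g.col(0) += sum(dr1a, 1);
      fmat dcolb = par[2].W.t() * dr1a;
      fmat dpool1(c1, g2.D);
      col2im(dcolb, ci2.nbr, dpool1);
      dpool1 += ds1;  // identity skip
      fmat da1(c1, g1.D);
      maxpool_back(dpool1, arg1, da1);
      relu_mask(a1, da1);
      par[0].g += da1 * col1.t();
      par[1].g.col(0) += sum(da1, 1);
    }
  }
};

Rcpp::List export_weights(const Net& net) {
  Rcpp::List out(net.par.size());
  for (size_t i = 0; i < net.par.size(); ++i) {
    const fmat& W = net.par[i].W;
    Rcpp::NumericMatrix w(W.n_rows, W.n_cols);
    for (uword c = 0; c < W.n_cols; ++c)
      for (uword r = 0; r < W.n_rows; ++r) w(r, c) = W(r, c);
    out[i] = w;
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train_cpp(std::string arch, int nx, int ny, int nt, int K,
                         int c1, int c2, int pen, Rcpp::List weights,
                         arma::mat Xtr, arma::ivec ytr, arma::mat Xva,
                         arma::ivec yva, int epochs, double lr, int batch,
                         int seed, double stop_val_loss, bool verbose) {
  Net net(arch, nx, ny, nt, K, c1, c2, pen, weights);
  const int ntr = Xtr.n_cols, nva = Xva.n_cols;
  fmat Xt = conv_to<fmat>::from(Xtr), Xv = conv_to<fmat>::from(Xva);
  std::mt19937 rng(seed);
  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;

  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long step = 0;
  std::vector<double> tr_loss, tr_acc, va_loss, va_acc;
  Rcpp::List best_weights = export_weights(net);
  double best_val = datum::inf;
  int ran_epochs = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double eloss = 0;
    int ecorrect = 0;
    for (int start = 0; start < ntr; start += batch) {
      int stop = std::min(start + batch, ntr);
      for (auto& p : net.par) p.g.zeros();
      for (int i = start; i < stop; ++i) {
        fvec x = Xt.col(order[i]);
        net.forward(x);
        int y = ytr(order[i]);
        eloss += -std::log(std::max(net.probs(y), 1e-12f));
        if (net.probs.index_max() == (uword)y) ++ecorrect;
        net.backward(x, y);
      }
      ++step;
      float bc = (float)(stop - start);
      float corr = std::sqrt(1.f - std::pow(b2, (float)step)) /
                   (1.f - std::pow(b1, (float)step));
      for (auto& p : net.par) {
        p.g /= bc;
        p.m = b1 * p.m + (1.f - b1) * p.g;
        p.v = b2 * p.v + (1.f - b2) * square(p.g);
        p.W -= (float)lr * corr * p.m / (sqrt(p.v) + eps);
      }
      Rcpp::checkUserInterrupt();
    }
    double vloss = 0;
    int vcorrect = 0;
    for (int i = 0; i < nva; ++i) {
      fvec x = Xv.col(i);
      net.forward(x);
      int y = yva(i);
      vloss += -std::log(std::max(net.probs(y), 1e-12f));
      if (net.probs.index_max() == (uword)y) ++vcorrect;
    }
    vloss = nva ? vloss / nva : NA_REAL;
    tr_loss.push_back(eloss / ntr);
    tr_acc.push_back((double)ecorrect / ntr);
    va_loss.push_back(vloss);
    va_acc.push_back(nva ? (double)vcorrect / nva : NA_REAL);
    ran_epochs = ep + 1;
    if (nva && vloss < best_val) {
      best_val = vloss;
      best_weights = export_weights(net);
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << " train_loss " << eloss / ntr
                  << " val_loss " << vloss << "\n";
    if (stop_val_loss > 0 && nva && vloss < stop_val_loss) break;
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = export_weights(net),
    Rcpp::Named("best_weights") = best_weights,
    Rcpp::Named("epochs_run") = ran_epochs,
    Rcpp::Named("trace") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = Rcpp::seq(1, ran_epochs),
      Rcpp::Named("train_loss") = tr_loss,
      Rcpp::Named("train_accuracy") = tr_acc,
      Rcpp::Named("val_loss") = va_loss,
      Rcpp::Named("val_accuracy") = va_acc));
}

// loss and accumulated parameter gradients over a batch, no update
// (used for finite-difference verification of the backward pass)
// [[Rcpp::export(name = ".cnn_grad")]]
Rcpp::List cnn_grad_cpp(std::string arch, int nx, int ny, int nt, int K,
                        int c1, int c2, int pen, Rcpp::List weights,
                        arma::mat X, arma::ivec y) {
  Net net(arch, nx, ny, nt, K, c1, c2, pen, weights);
  fmat Xf = conv_to<fmat>::from(X);
  for (auto& p : net.par) p.g.zeros();
  double loss = 0;
  for (uword i = 0; i < Xf.n_cols; ++i) {
    fvec x = Xf.col(i);
    net.forward(x);
    loss += -std::log(std::max(net.probs(y(i)), 1e-12f));
    net.backward(x, y(i));
  }
  Rcpp::List grads(net.par.size());
  for (size_t i = 0; i < net.par.size(); ++i) {
    const fmat& G = net.par[i].g;
    Rcpp::NumericMatrix g(G.n_rows, G.n_cols);
    for (uword cc = 0; cc < G.n_cols; ++cc)
      for (uword r = 0; r < G.n_rows; ++r) g(r, cc) = G(r, cc);
    grads[i] = g;
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}

// [[Rcpp::export(name = ".cnn_forward")]]
Rcpp::List cnn_forward_cpp(std::string arch, int nx, int ny, int nt, int K,
                           int c1, int c2, int pen, Rcpp::List weights,
                           arma::mat X) {
  Net net(arch, nx, ny, nt, K, c1, c2, pen, weights);
  const int n = X.n_cols;
  fmat Xf = conv_to<fmat>::from(X);
  mat probs(n, K);
  mat feats(n, net.n_features());
  for (int i = 0; i < n; ++i) {
    fvec x = Xf.col(i);
    net.forward(x);
    for (int k = 0; k < K; ++k) probs(i, k) = net.probs(k);
    const fvec& f = net.hid;
    for (int j = 0; j < (int)f.n_elem; ++j) feats(i, j) = f(j);
  }
  return Rcpp::List::create(Rcpp::Named("probs") = probs,
                            Rcpp::Named("features") = feats);
}
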