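// Small convolutional classifier for 32x32 pressure maps.
// Three 3x3 conv (same padding) + 2x2 max-pool blocks, a 256-unit fully
// connected layer, and a softmax head; trained with Adam on cross-entropy.
// Written against Armadillo so the per-block convolutions reduce to
// im2col + GEMM.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  std::vector<mat> Wc;      // (9*Cin) x F per conv block
  std::vector<rowvec> bc;
  mat Wf1; rowvec bf1;      // flat -> 256
  mat Wf2; rowvec bf2;      // 256 -> K
  std::vector<int> C;       // channels per stage: {1, F1, F2, F3}
  std::vector<int> H;       // spatial side per stage input: {32,16,8,4}
};

// out(w*H + r, c*9 + (dc+1)*3 + (dr+1)) = in(r+dr, w+dc, c), zero padded
void im2col3(const cube& in, mat& out) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  out.zeros(H * W, 9 * C);
  for (int c = 0; c < C; ++c) {
    const mat& s = in.slice(c);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int j = c * 9 + (dc + 1) * 3 + (dr + 1);
        double* col = out.colptr(j);
        for (int w = 0; w < W; ++w) {
          const int wc = w + dc;
          if (wc < 0 || wc >= W) continue;
          const double* sc = s.colptr(wc);
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          for (int r = r0; r < r1; ++r) col[w * H + r] = sc[r + dr];
        }
      }
    }
  }
}

// adjoint of im2col3
void col2im3(const mat& cols, cube& dIn) {
  const int H = dIn.n_rows, W = dIn.n_cols, C = dIn.n_slices;
  dIn.zeros();
  for (int c = 0; c < C; ++c) {
    mat& s = dIn.slice(c);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int j = c * 9 + (dc + 1) * 3 + (dr + 1);
        const double* col = cols.colptr(j);
        for (int w = 0; w < W; ++w) {
          const int wc = w + dc;
          if (wc < 0 || wc >= W) continue;
          double* sc = s.colptr(wc);
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          for (int r = r0; r < r1; ++r) sc[r + dr] += col[w * H + r];
        }
      }
    }
  }
}

cube mat2cube(const mat& m, int H, int W) {
  cube out(H, W, m.n_cols);
  for (uword f = 0; f < m.n_cols; ++f)
    out.slice(f) = reshape(m.col(f), H, W);
  return out;
}

mat cube2mat(const cube& c) {
  mat out(c.n_rows * c.n_cols, c.n_slices);
  for (uword f = 0; f < c.n_slices; ++f)
    out.col(f) = vectorise(c.slice(f));
  return out;
}

void maxpool2(const cube& in, cube& out, umat& arg) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  out.set_size(Ho, Wo, C);
  arg.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& s = in.slice(c);
    for (int w = 0; w < Wo; ++w) {
      for (int r = 0; r < Ho; ++r) {
        double best = -datum::inf; int bi = 0;
        for (int dc = 0; dc < 2; ++dc) {
          for (int dr = 0; dr < 2; ++dr) {
            const int rr = 2 * r + dr, cc = 2 * w + dc;
            const double v = s(rr, cc);
            if (v > best) { best = v; bi = cc * H + rr; }
          }
        }
        out(r, w, c) = best;
        arg(w * Ho + r, c) = bi;
      }
    }
  }
}

void unpool2(const cube& dOut, const umat& arg, cube& dIn) {
  const int Ho = dOut.n_rows, Wo = dOut.n_cols, C = dOut.n_slices;
  dIn.zeros();
  for (int c = 0; c < C; ++c) {
    const mat& d = dOut.slice(c);
    double* sl = dIn.slice_memptr(c);
    for (int w = 0; w < Wo; ++w)
      for (int r = 0; r < Ho; ++r)
        sl[arg(w * Ho + r, c)] += d(r, w);
  }
}

struct FwdCache {
  std::vector<mat> cols;     // im2col per conv block
  std::vector<cube> act;     // post-ReLU conv activations (mask source)
  std::vector<cube> pooled;
  std::vector<umat> arg;
  rowvec flat, z1, h1, p;
  double loss = 0.0;
  int pred = 0;
  FwdCache() : cols(3), act(3), pooled(3), arg(3) {}
};

void forward(const Net& net, const double* xptr, FwdCache& fc,
             bool store) {
  cube a(net.H[0], net.H[0], 1);
  std::memcpy(a.memptr(), xptr,
              sizeof(double) * net.H[0] * net.H[0]);
  for (int b = 0; b < 3; ++b) {
    mat cols;
    im2col3(a, cols);
    mat z = cols * net.Wc[b];
    z.each_row() += net.bc[b];
    z.transform([](double v) { return v > 0 ? v : 0.0; });
    cube act = mat2cube(z, a.n_rows, a.n_cols);
    cube pooled; umat arg;
    maxpool2(act, pooled, arg);
    if (store) { fc.cols[b] = std::move(cols); fc.act[b] = act;
                 fc.arg[b] = arg; fc.pooled[b] = pooled; }
    a = std::move(pooled);
  }
  fc.flat = vectorise(a).t();
  fc.z1 = fc.flat * net.Wf1 + net.bf1;
  fc.h1 = fc.z1;
  fc.h1.transform([](double v) { return v > 0 ? v : 0.0; });
  rowvec z2 = fc.h1 * net.Wf2 + net.bf2;
  z2 -= z2.max();
  rowvec e = exp(z2);
  fc.p = e / accu(e);
  fc.pred = (int)fc.p.index_max();
}

struct Grads {
  std::vector<mat> Wc; std::vector<rowvec> bc;
  mat Wf1; rowvec bf1; mat Wf2; rowvec bf2;
  void zero_like(const Net& n) {
    Wc.resize(3); bc.resize(3);
    for (int b = 0; b < 3; ++b) {
      Wc[b].zeros(n.Wc[b].n_rows, n.Wc[b].n_cols);
      bc[b].zeros(n.bc[b].n_elem);
    }
    Wf1.zeros(n.Wf1.n_rows, n.Wf1.n_cols); bf1.zeros(n.bf1.n_elem);
    Wf2.zeros(n.Wf2.n_rows, n.Wf2.n_cols); bf2.zeros(n.bf2.n_elem);
  }
};

void backward(const Net& net, const FwdCache& fc, int y, Grads& g) {
  rowvec dz2 = fc.p;
  dz2(y) -= 1.0;
  g.Wf2 += fc.h1.t() * dz2;
  g.bf2 += dz2;
  rowvec dh1 = dz2 * net.Wf2.t();
  rowvec dz1 = dh1;
  for (uword i = 0; i < dz1.n_elem; ++i) if (fc.z1(i) <= 0) dz1(i) = 0;
  g.Wf1 += fc.flat.t() * dz1;
  g.bf1 += dz1;
  rowvec dflat = dz1 * net.Wf1.t();

  const int H3 = net.H[2] / 2;  // spatial side after final pool
  cube dpool(H3, H3, net.C[3]);
  std::memcpy(dpool.memptr(), dflat.memptr(),
              sizeof(double) * dflat.n_elem);
  for (int b = 2; b >= 0; --b) {
    cube dact(fc.act[b].n_rows, fc.act[b].n_cols, fc.act[b].n_slices);
    unpool2(dpool, fc.arg[b], dact);
    // ReLU mask
    const double* a = fc.act[b].memptr();
    double* d = dact.memptr();
    for (uword i = 0; i < dact.n_elem; ++i) if (a[i] <= 0) d[i] = 0;
    mat dz = cube2mat(dact);
    g.Wc[b] += fc.cols[b].t() * dz;
    g.bc[b] += sum(dz, 0);
    if (b > 0) {
      mat dcols = dz * net.Wc[b].t();
      cube dIn(fc.pooled[b - 1].n_rows, fc.pooled[b - 1].n_cols,
               fc.pooled[b - 1].n_slices);
      col2im3(dcols, dIn);
      dpool = std::move(dIn);
    }
  }
}

struct Adam {
  std::vector<mat> mWc, vWc; std::vector<rowvec> mbc, vbc;
  mat mWf1, vWf1, mWf2, vWf2; rowvec mbf1, vbf1, mbf2, vbf2;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Net& n) {
    mWc.resize(3); vWc.resize(3); mbc.resize(3); vbc.resize(3);
    for (int b = 0; b < 3; ++b) {
      mWc[b].zeros(size(n.Wc[b])); vWc[b].zeros(size(n.Wc[b]));
      mbc[b].zeros(n.bc[b].n_elem); vbc[b].zeros(n.bc[b].n_elem);
    }
    mWf1.zeros(size(n.Wf1)); vWf1.zeros(size(n.Wf1));
    mWf2.zeros(size(n.Wf2)); vWf2.zeros(size(n.Wf2));
    mbf1.zeros(n.bf1.n_elem); vbf1.zeros(n.bf1.n_elem);
    mbf2.zeros(n.bf2.n_elem); vbf2.zeros(n.bf2.n_elem);
  }
  template <class M>
  void upd(M& w, const M& gr, M& m, M& v, double lr) {
    m = b1 * m + (1 - b1) * gr;
    v = b2 * v + (1 - b2) * (gr % gr);
    const double bc1 = 1 - std::pow(b1, (double)t);
    const double bc2 = 1 - std::pow(b2, (double)t);
    w -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
  }
  void step(Net& n, const Grads& g, double lr) {
    ++t;
    for (int b = 0; b < 3; ++b) {
      upd(n.Wc[b], g.Wc[b], mWc[b], vWc[b], lr);
      upd(n.bc[b], g.bc[b], mbc[b], vbc[b], lr);
    }
    upd(n.Wf1, g.Wf1, mWf1, vWf1, lr);
    upd(n.bf1, g.bf1, mbf1, vbf1, lr);
    upd(n.Wf2, g.Wf2, mWf2, vWf2, lr);
    upd(n.bf2, g.bf2, mbf2, vbf2, lr);
  }
};

Net init_net(const std::vector<int>& filters, int K, std::mt19937& gen) {
  Net n;
  n.C = {1, filters[0], filters[1], filters[2]};
  n.H = {32, 16, 8, 4};
  std::normal_distribution<double> nd(0.0, 1.0);
  auto fill = [&](mat& w, double sd) {
    for (uword i = 0; i < w.n_elem; ++i) w(i) = sd * nd(gen);
  };
  n.Wc.resize(3); n.bc.resize(3);
  for (int b = 0; b < 3; ++b) {
    const int fan_in = 9 * n.C[b];
    n.Wc[b].set_size(fan_in, n.C[b + 1]);
    fill(n.Wc[b], std::sqrt(2.0 / fan_in));
    n.bc[b].zeros(n.C[b + 1]);
  }
  const int flat = 4 * 4 * n.C[3];
  n.Wf1.set_size(flat, 256); fill(n.Wf1, std::sqrt(2.0 / flat));
  n.bf1.zeros(256);
  n.Wf2.set_size(256, K); fill(n.Wf2, std::sqrt(2.0 / 256));
  n.bf2.zeros(K);
  return n;
}

Rcpp::List net_to_list(const Net& n) {
  return Rcpp::List::create(
    Rcpp::Named("Wc1") = n.Wc[0], Rcpp::Named("bc1") = n.bc[0],
    Rcpp::Named("Wc2") = n.Wc[1], Rcpp::Named("bc2") = n.bc[1],
    Rcpp::Named("Wc3") = n.Wc[2], Rcpp::Named("bc3") = n.bc[2],
    Rcpp::Named("Wf1") = n.Wf1, Rcpp::Named("bf1") = n.bf1,
    Rcpp::Named("Wf2") = n.Wf2, Rcpp::Named("bf2") = n.bf2);
}

Net net_from_list(const Rcpp::List& w) {
  Net n;
  n.Wc = {Rcpp::as<mat>(w["Wc1"]), Rcpp::as<mat>(w["Wc2"]),
          Rcpp::as<mat>(w["Wc3"])};
  n.bc = {Rcpp::as<rowvec>(w["bc1"]), Rcpp::as<rowvec>(w["bc2"]),
          Rcpp::as<rowvec>(w["bc3"])};
  n.Wf1 = Rcpp::as<mat>(w["Wf1"]); n.bf1 = Rcpp::as<rowvec>(w["bf1"]);
  n.Wf2 = Rcpp::as<mat>(w["Wf2"]); n.bf2 = Rcpp::as<rowvec>(w["bf2"]);
  n.C = {1, (int)n.Wc[0].n_cols, (int)n.Wc[1].n_cols, (int)n.Wc[2].n_cols};
  n.H = {32, 16, 8, 4};
  return n;
}

double eval_set(const Net& net, const mat& X, const ivec& y,
                double& acc_out) {
  FwdCache fc;
  double loss = 0; int correct = 0;
  for (uword i = 0; i < X.n_rows; ++i) {
    rowvec x = X.row(i);
    forward(net, x.memptr(), fc, false);
    loss += -std::log(std::max(fc.p((uword)y(i)), 1e-12));
    if (fc.pred == y(i)) ++correct;
  }
  acc_out = X.n_rows ? (double)correct / X.n_rows : NA_REAL;
  return X.n_rows ? loss / X.n_rows : NA_REAL;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::mat& X, const arma::ivec& y,
                         const arma::mat& Xval, const arma::ivec& yval,
                         const std::vector<int>& filters, int K,
                         int epochs, int batch, double lr, int seed) {
  std::mt19937 gen((unsigned)seed);
  Net net = init_net(filters, K, gen);
  Adam adam; adam.init(net);
  Grads g; g.zero_like(net);
  FwdCache fc;

  const uword n = X.n_rows;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> tr_loss, tr_acc, va_loss, va_acc;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), gen);
    double loss_sum = 0; int correct = 0;
    for (uword start = 0; start < n; start += batch) {
      const uword stop = std::min<uword>(start + batch, n);
      g.zero_like(net);
      for (uword k = start; k < stop; ++k) {
        const uword i = idx[k];
        rowvec x = X.row(i);
        forward(net, x.memptr(), fc, true);
        loss_sum += -std::log(std::max(fc.p((uword)y(i)), 1e-12));
        if (fc.pred == y(i)) ++correct;
        backward(net, fc, (int)y(i), g);
      }
      const double nb = (double)(stop - start);
      for (int b = 0; b < 3; ++b) { g.Wc[b] /= nb; g.bc[b] /= nb; }
      g.Wf1 /= nb; g.bf1 /= nb; g.Wf2 /= nb; g.bf2 /= nb;
      adam.step(net, g, lr);
      Rcpp::checkUserInterrupt();
    }
    tr_loss.push_back(loss_sum / n);
    tr_acc.push_back((double)correct / n);
    if (Xval.n_rows > 0) {
      double va;
      va_loss.push_back(eval_set(net, Xval, yval, va));
      va_acc.push_back(va);
    } else {
      va_loss.push_back(NA_REAL);
      va_acc.push_back(NA_REAL);
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = net_to_list(net),
    Rcpp::Named("trace") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = epochs > 0 ?
        Rcpp::IntegerVector(Rcpp::seq_len(epochs)) : Rcpp::IntegerVector(0),
      Rcpp::Named("train_loss") = tr_loss,
      Rcpp::Named("train_accuracy") = tr_acc,
      Rcpp::Named("val_loss") = va_loss,
      Rcpp::Named("val_accuracy") = va_acc));
}

// output: "prob" (n x K softmax scores) or "embedding" (n x 256 post-ReLU
// penultimate activations)
// [[Rcpp::export]]
arma::mat cnn_forward_cpp(const Rcpp::List& weights, const arma::mat& X,
                          const std::string& output) {
  Net net = net_from_list(weights);
  FwdCache fc;
  const bool emb = output == "embedding";
  mat out(X.n_rows, emb ? 256 : net.Wf2.n_cols);
  for (uword i = 0; i < X.n_rows; ++i) {
    rowvec x = X.row(i);
    forward(net, x.memptr(), fc, false);
    out.row(i) = emb ? fc.h1 : fc.p;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_init_cpp(const std::vector<int>& filters, int K, int seed) {
  std::mt19937 gen((unsigned)seed);
  Net net = init_net(filters, K, gen);
  return net_to_list(net);
}
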