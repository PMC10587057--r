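// Minimal 3D convolutional network engine used by the autoencoder and the
// property surrogates. Feature maps are stored as (V x C) matrices with
// V = D^3 voxels, x fastest (column-major voxel index v = x + D*(y + D*z)).
// Convolutions are 3x3x3, 'same' zero padding, realised as im2col + GEMM.
// Single precision internally; all randomness comes from a seeded mt19937
// with an explicit Box-Muller / Fisher-Yates so runs are bit-reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using Rcpp::List;
using Rcpp::Named;
typedef arma::fmat FM;
typedef arma::fvec FV;
typedef arma::umat UM;

namespace {

struct Rng {
  std::mt19937 g;
  bool has;
  double cache;
  explicit Rng(uint32_t seed) : g(seed), has(false), cache(0.0) {}
  double unif() { return (static_cast<double>(g()) + 0.5) / 4294967296.0; }
  double norm() {
    if (has) { has = false; return cache; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), t = 2.0 * M_PI * u2;
    cache = r * std::sin(t); has = true;
    return r * std::cos(t);
  }
  int below(int n) { return static_cast<int>(g() % static_cast<uint32_t>(n)); }
  void shuffle(std::vector<int>& v) {
    for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
      int j = below(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

void fill_normal(FM& w, double sd, Rng& rng) {
  for (arma::uword i = 0; i < w.n_elem; ++i)
    w[i] = static_cast<float>(sd * rng.norm());
}

// X: (V x Cin) -> P: (V x 27*Cin); patch column o + 27*ci holds the input
// shifted by offset o (out-of-range = 0, i.e. zero padding).
void im2col(const FM& X, int D, FM& P) {
  const int Cin = static_cast<int>(X.n_cols);
  P.zeros(X.n_rows, 27 * Cin);
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
    const int x0 = std::max(0, -dx), x1 = D - 1 - std::max(0, dx);
    const int y0 = std::max(0, -dy), y1 = D - 1 - std::max(0, dy);
    const int z0 = std::max(0, -dz), z1 = D - 1 - std::max(0, dz);
    const int rl = x1 - x0 + 1;
    if (rl <= 0) continue;
    for (int ci = 0; ci < Cin; ++ci) {
      const float* src = X.colptr(ci);
      float* dst = P.colptr(o + 27 * ci);
      for (int z = z0; z <= z1; ++z)
        for (int y = y0; y <= y1; ++y) {
          const int dv = x0 + D * (y + D * z);
          const int sv = (x0 + dx) + D * ((y + dy) + D * (z + dz));
          std::memcpy(dst + dv, src + sv, rl * sizeof(float));
        }
    }
  }
}

// adjoint of im2col: scatter-add patch gradients back onto the input grid
void col2im(const FM& dP, int D, int Cin, FM& dX) {
  dX.zeros(dP.n_rows, Cin);
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
    const int x0 = std::max(0, -dx), x1 = D - 1 - std::max(0, dx);
    const int y0 = std::max(0, -dy), y1 = D - 1 - std::max(0, dy);
    const int z0 = std::max(0, -dz), z1 = D - 1 - std::max(0, dz);
    const int rl = x1 - x0 + 1;
    if (rl <= 0) continue;
    for (int ci = 0; ci < Cin; ++ci) {
      const float* src = dP.colptr(o + 27 * ci);
      float* dst = dX.colptr(ci);
      for (int z = z0; z <= z1; ++z)
        for (int y = y0; y <= y1; ++y) {
          const int dv = x0 + D * (y + D * z);
          const int sv = (x0 + dx) + D * ((y + dy) + D * (z + dz));
          for (int i = 0; i < rl; ++i) dst[sv + i] += src[dv + i];
        }
    }
  }
}

void elu_fwd(FM& A) {
  for (arma::uword i = 0; i < A.n_elem; ++i)
    if (A[i] < 0.f) A[i] = std::expm1(A[i]);
}

// uses post-activation values: d/dx elu(x) = 1 (x>0) else elu(x)+1
void elu_bwd(const FM& Y, FM& dA) {
  for (arma::uword i = 0; i < dA.n_elem; ++i)
    if (Y[i] <= 0.f) dA[i] *= Y[i] + 1.f;
}

void maxpool_fwd(const FM& X, int D, FM& Y, UM& I) {
  const int Do = D / 2, C = static_cast<int>(X.n_cols);
  Y.set_size(static_cast<arma::uword>(Do) * Do * Do, C);
  I.set_size(Y.n_rows, C);
  for (int c = 0; c < C; ++c) {
    const float* xp = X.colptr(c);
    for (int z = 0; z < Do; ++z)
      for (int y = 0; y < Do; ++y)
        for (int x = 0; x < Do; ++x) {
          const int vo = x + Do * (y + Do * z);
          float best = -std::numeric_limits<float>::infinity();
          arma::uword bi = 0;
          for (int cz = 0; cz < 2; ++cz)
            for (int cy = 0; cy < 2; ++cy)
              for (int cx = 0; cx < 2; ++cx) {
                const int vi = (2 * x + cx) + D * ((2 * y + cy) + D * (2 * z + cz));
                if (xp[vi] > best) { best = xp[vi]; bi = vi; }
              }
          Y(vo, c) = best;
          I(vo, c) = bi;
        }
  }
}

void maxpool_bwd(const FM& dY, const UM& I, int Vin, FM& dX) {
  const int C = static_cast<int>(dY.n_cols);
  dX.zeros(Vin, C);
  for (int c = 0; c < C; ++c)
    for (arma::uword vo = 0; vo < dY.n_rows; ++vo)
      dX(I(vo, c), c) += dY(vo, c);
}

void upsample_fwd(const FM& X, int Din, int f, FM& Y) {
  const int Do = Din * f, C = static_cast<int>(X.n_cols);
  Y.set_size(static_cast<arma::uword>(Do) * Do * Do, C);
  for (int c = 0; c < C; ++c) {
    const float* xp = X.colptr(c);
    float* yp = Y.colptr(c);
    for (int z = 0; z < Do; ++z)
      for (int y = 0; y < Do; ++y)
        for (int x = 0; x < Do; ++x)
          yp[x + Do * (y + Do * z)] =
            xp[(x / f) + Din * ((y / f) + Din * (z / f))];
  }
}

void upsample_bwd(const FM& dY, int Din, int f, FM& dX) {
  const int Do = Din * f, C = static_cast<int>(dY.n_cols);
  dX.zeros(static_cast<arma::uword>(Din) * Din * Din, C);
  for (int c = 0; c < C; ++c) {
    const float* yp = dY.colptr(c);
    float* xp = dX.colptr(c);
    for (int z = 0; z < Do; ++z)
      for (int y = 0; y < Do; ++y)
        for (int x = 0; x < Do; ++x)
          xp[(x / f) + Din * ((y / f) + Din * (z / f))] +=
            yp[x + Do * (y + Do * z)];
  }
}

struct Adam {
  std::vector<FM> m, v;
  double lr, b1, b2, eps;
  int t;
  Adam() : lr(1e-3), b1(0.9), b2(0.999), eps(1e-8), t(0) {}
  void init(const std::vector<FM*>& ps) {
    m.clear(); v.clear();
    for (size_t i = 0; i < ps.size(); ++i) {
      m.push_back(arma::zeros<FM>(ps[i]->n_rows, ps[i]->n_cols));
      v.push_back(arma::zeros<FM>(ps[i]->n_rows, ps[i]->n_cols));
    }
  }
  void step(std::vector<FM*>& ps, std::vector<FM>& gs) {
    ++t;
    const float c1 = 1.f - std::pow(static_cast<float>(b1), t);
    const float c2 = 1.f - std::pow(static_cast<float>(b2), t);
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = static_cast<float>(b1) * m[i] + (1.f - static_cast<float>(b1)) * gs[i];
      v[i] = static_cast<float>(b2) * v[i] + (1.f - static_cast<float>(b2)) * (gs[i] % gs[i]);
      *ps[i] -= static_cast<float>(lr) * (m[i] / c1) /
                (arma::sqrt(v[i] / c2) + static_cast<float>(eps));
    }
  }
};

// ---------------------------------------------------------------------------
// 3D-CNN regressor: conv stages (3x3x3, ELU, max-pool 2) with the configured
// filter counts, then flatten and a dense ELU stack with a single linear
// output.
// ---------------------------------------------------------------------------
struct CNN {
  int D0;
  std::vector<int> filters, dense;
  std::vector<int> Ds;  // input resolution per conv stage
  int Dlast, flat;
  std::vector<FM> Wc, bc, Wd, bd;
  // caches
  std::vector<FM> P, A, M;
  std::vector<UM> I;
  std::vector<FV> H;
  FV flatv;

  void build(int D0_, const std::vector<int>& f, const std::vector<int>& d) {
    D0 = D0_; filters = f; dense = d;
    Ds.clear();
    int D = D0;
    for (size_t s = 0; s < filters.size(); ++s) { Ds.push_back(D); D /= 2; }
    Dlast = D;
    flat = D * D * D * filters.back();
    P.resize(filters.size()); A.resize(filters.size());
    M.resize(filters.size()); I.resize(filters.size());
    H.resize(dense.size());
  }

  void init_params(Rng& rng) {
    Wc.clear(); bc.clear(); Wd.clear(); bd.clear();
    int cin = 1;
    for (size_t s = 0; s < filters.size(); ++s) {
      FM w(27 * cin, filters[s]);
      fill_normal(w, std::sqrt(2.0 / (27.0 * cin)), rng);
      Wc.push_back(w);
      bc.push_back(arma::zeros<FM>(1, filters[s]));
      cin = filters[s];
    }
    int in = flat;
    for (size_t j = 0; j < dense.size(); ++j) {
      FM w(dense[j], in);
      fill_normal(w, std::sqrt(2.0 / in), rng);
      Wd.push_back(w);
      bd.push_back(arma::zeros<FM>(dense[j], 1));
      in = dense[j];
    }
    FM w(1, in);
    fill_normal(w, std::sqrt(1.0 / in), rng);
    Wd.push_back(w);
    bd.push_back(arma::zeros<FM>(1, 1));
  }

  std::vector<FM*> params() {
    std::vector<FM*> ps;
    for (size_t s = 0; s < Wc.size(); ++s) { ps.push_back(&Wc[s]); ps.push_back(&bc[s]); }
    for (size_t j = 0; j < Wd.size(); ++j) { ps.push_back(&Wd[j]); ps.push_back(&bd[j]); }
    return ps;
  }

  float forward(const FM& x) {
    const FM* cur = &x;
    for (size_t s = 0; s < filters.size(); ++s) {
      im2col(*cur, Ds[s], P[s]);
      A[s] = P[s] * Wc[s];
      A[s].each_row() += bc[s].row(0);
      elu_fwd(A[s]);
      maxpool_fwd(A[s], Ds[s], M[s], I[s]);
      cur = &M[s];
    }
    flatv = arma::vectorise(M.back());
    const FV* h = &flatv;
    for (size_t j = 0; j < dense.size(); ++j) {
      H[j] = Wd[j] * (*h) + bd[j];
      FM tmp(H[j].memptr(), H[j].n_elem, 1, false, true);
      elu_fwd(tmp);
      h = &H[j];
    }
    return arma::dot(Wd.back().row(0), *h) + bd.back()(0, 0);
  }

  // accumulate parameter gradients for one sample; dout = dLoss/dpred
  void backward(float dout, std::vector<FM>& g) {
    const size_t nc = filters.size(), nd = dense.size();
    // dense chain
    FV dh = arma::conv_to<FV>::from(Wd.back().row(0).t()) * dout;
    g[2 * nc + 2 * nd] += dout * H.back().t();          // Wd last
    g[2 * nc + 2 * nd + 1](0, 0) += dout;               // bd last
    for (int j = static_cast<int>(nd) - 1; j >= 0; --j) {
      FM dhm(dh.memptr(), dh.n_elem, 1, false, true);
      FM hm(H[j].memptr(), H[j].n_elem, 1, false, true);
      elu_bwd(hm, dhm);
      const FV& below = (j == 0) ? flatv : H[j - 1];
      g[2 * nc + 2 * j] += dh * below.t();
      g[2 * nc + 2 * j + 1] += dh;
      dh = Wd[j].t() * dh;
    }
    FM dM(dh.memptr(), M.back().n_rows, M.back().n_cols);
    for (int s = static_cast<int>(nc) - 1; s >= 0; --s) {
      FM dA;
      maxpool_bwd(dM, I[s], Ds[s] * Ds[s] * Ds[s], dA);
      elu_bwd(A[s], dA);
      g[2 * s] += P[s].t() * dA;
      g[2 * s + 1] += arma::sum(dA, 0);
      if (s > 0) {
        FM dP = dA * Wc[s].t();
        col2im(dP, Ds[s], filters[s - 1], dM);
      }
    }
  }

  List export_weights() const {
    List w;
    for (size_t s = 0; s < Wc.size(); ++s) {
      w.push_back(Rcpp::wrap(arma::conv_to<arma::mat>::from(Wc[s])));
      w.push_back(Rcpp::wrap(arma::conv_to<arma::mat>::from(bc[s])));
    }
    for (size_t j = 0; j < Wd.size(); ++j) {
      w.push_back(Rcpp::wrap(arma::conv_to<arma::mat>::from(Wd[j])));
      w.push_back(Rcpp::wrap(arma::conv_to<arma::mat>::from(bd[j])));
    }
    return w;
  }

  void import_weights(const List& w) {
    Wc.clear(); bc.clear(); Wd.clear(); bd.clear();
    int k = 0;
    for (size_t s = 0; s < filters.size(); ++s) {
      Wc.push_back(arma::conv_to<FM>::from(Rcpp::as<arma::mat>(w[k++])));
      bc.push_back(arma::conv_to<FM>::from(Rcpp::as<arma::mat>(w[k++])));
    }
    for (size_t j = 0; j < dense.size() + 1; ++j) {
      Wd.push_back(arma::conv_to<FM>::from(Rcpp::as<arma::mat>(w[k++])));
      bd.push_back(arma::conv_to<FM>::from(Rcpp::as<arma::mat>(w[k++])));
    }
  }
};

double mse_over(CNN& net, const FM& X, const arma::vec& y) {
  double s = 0.0;
  FM x(X.n_rows, 1);
  for (arma::uword i = 0; i < X.n_cols; ++i) {
    x.col(0) = X.col(i);
    double e = net.forward(x) - y(i);
    s += e * e;
  }
  return s / X.n_cols;
}

}  // namespace

// [[Rcpp::export]]
List cpp_cnn_train(const arma::mat& Xtr, const arma::vec& ytr,
                   const arma::mat& Xval, const arma::vec& yval,
                   int D, std::vector<int> filters, std::vector<int> dense,
                   int epochs, int batch, double lr, int seed, int patience,
                   double lr_decay) {
  FM Xt = arma::conv_to<FM>::from(Xtr);
  FM Xv = arma::conv_to<FM>::from(Xval);
  const int n = static_cast<int>(Xt.n_cols);
  Rng rng(static_cast<uint32_t>(seed));
  CNN net;
  net.build(D, filters, dense);
  net.init_params(rng);
  std::vector<FM*> ps = net.params();
  Adam opt;
  opt.lr = lr;
  opt.init(ps);
  std::vector<FM> g(ps.size());
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> tr_hist, val_hist;
  double best_val = std::numeric_limits<double>::infinity();
  List best_w = net.export_weights();
  int best_epoch = 0, since_best = 0;
  FM x(Xt.n_rows, 1);
  for (int ep = 0; ep < epochs; ++ep) {
    opt.lr = lr * std::pow(lr_decay, ep);
    rng.shuffle(order);
    double tr_loss = 0.0;
    for (int b0 = 0; b0 < n; b0 += batch) {
      const int bs = std::min(batch, n - b0);
      for (size_t i = 0; i < ps.size(); ++i)
        g[i] = arma::zeros<FM>(ps[i]->n_rows, ps[i]->n_cols);
      for (int bi = 0; bi < bs; ++bi) {
        const int i = order[b0 + bi];
        x.col(0) = Xt.col(i);
        const float pred = net.forward(x);
        const float err = pred - static_cast<float>(ytr(i));
        tr_loss += static_cast<double>(err) * err;
        net.backward(2.f * err / bs, g);
      }
      opt.step(ps, g);
    }
    tr_hist.push_back(tr_loss / n);
    const bool has_val = Xv.n_cols > 0;
    const double vl = has_val ? mse_over(net, Xv, yval) : tr_loss / n;
    val_hist.push_back(vl);
    if (vl < best_val) {
      best_val = vl;
      best_w = net.export_weights();
      best_epoch = ep + 1;
      since_best = 0;
    } else if (++since_best >= patience) {
      break;
    }
    if (!std::isfinite(vl) || !std::isfinite(tr_hist.back()))
      Rcpp::stop("training diverged (non-finite loss at epoch %d)", ep + 1);
  }
  return List::create(Named("weights") = best_w,
                      Named("train_mse") = tr_hist,
                      Named("val_mse") = val_hist,
                      Named("best_epoch") = best_epoch,
                      Named("best_val_mse") = best_val);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_cnn_predict(const List& weights, const arma::mat& X,
                                    int D, std::vector<int> filters,
                                    std::vector<int> dense) {
  CNN net;
  net.build(D, filters, dense);
  net.import_weights(weights);
  FM Xf = arma::conv_to<FM>::from(X);
  Rcpp::NumericVector out(Xf.n_cols);
  FM x(Xf.n_rows, 1);
  for (arma::uword i = 0; i < Xf.n_cols; ++i) {
    x.col(0) = Xf.col(i);
    out[i] = net.forward(x);
  }
  return out;
}

// Gradient-weighted activation data for regression activation maps: returns
// the post-ELU activations of the last conv stage and d(pred)/d(activations).
// [[Rcpp::export]]
List cpp_cnn_ram(const List& weights, const arma::mat& xin, int D,
                 std::vector<int> filters, std::vector<int> dense) {
  CNN net;
  net.build(D, filters, dense);
  net.import_weights(weights);
  FM x = arma::conv_to<FM>::from(xin);
  const float pred = net.forward(x);
  const size_t nd = net.dense.size();
  FV dh = arma::conv_to<FV>::from(net.Wd.back().row(0).t());
  for (int j = static_cast<int>(nd) - 1; j >= 0; --j) {
    FM dhm(dh.memptr(), dh.n_elem, 1, false, true);
    FM hm(net.H[j].memptr(), net.H[j].n_elem, 1, false, true);
    elu_bwd(hm, dhm);
    dh = net.Wd[j].t() * dh;
  }
  const size_t s = net.filters.size() - 1;
  FM dM(dh.memptr(), net.M[s].n_rows, net.M[s].n_cols);
  FM dA;
  maxpool_bwd(dM, net.I[s], net.Ds[s] * net.Ds[s] * net.Ds[s], dA);
  return List::create(
      Named("activations") = Rcpp::wrap(arma::conv_to<arma::mat>::from(net.A[s])),
      Named("gradients") = Rcpp::wrap(arma::conv_to<arma::mat>::from(dA)),
      Named("resolution") = net.Ds[s],
      Named("prediction") = pred);
}

// ---------------------------------------------------------------------------
// 3D convolutional autoencoder on 12^3 porosity arrays.
// Encoder: conv(f1) ELU pool -> conv(f2) ELU pool -> conv(f3) ELU
//          -> conv(latent) -> global average pool.
// Decoder: broadcast latent to 3^3 -> conv(f3) ELU -> up x2 -> conv(f2) ELU
//          -> up x2 -> conv(1) linear.
// ---------------------------------------------------------------------------
namespace {

struct CAE {
  int L;
  std::vector<int> f;  // encoder filter counts (3 stages)
  FM We1, be1, We2, be2, We3, be3, Wz, bz;
  FM Wd1, bd1, Wd2, bd2, Wd3, bd3;
  // caches
  FM P1, A1, M1, P2, A2, M2, P3, A3, Pz, Az;
  UM I1, I2;
  FV z;
  FM Zu, Pd1, B1, U1, Pd2, B2, U2, Pd3, Xhat;

  void init_params(Rng& rng) {
    We1.set_size(27, f[0]);       fill_normal(We1, std::sqrt(2.0 / 27), rng);
    be1 = arma::zeros<FM>(1, f[0]);
    We2.set_size(27 * f[0], f[1]); fill_normal(We2, std::sqrt(2.0 / (27.0 * f[0])), rng);
    be2 = arma::zeros<FM>(1, f[1]);
    We3.set_size(27 * f[1], f[2]); fill_normal(We3, std::sqrt(2.0 / (27.0 * f[1])), rng);
    be3 = arma::zeros<FM>(1, f[2]);
    Wz.set_size(27 * f[2], L);     fill_normal(Wz, std::sqrt(1.0 / (27.0 * f[2])), rng);
    bz = arma::zeros<FM>(1, L);
    Wd1.set_size(27 * L, f[2]);    fill_normal(Wd1, std::sqrt(2.0 / (27.0 * L)), rng);
    bd1 = arma::zeros<FM>(1, f[2]);
    Wd2.set_size(27 * f[2], f[1]); fill_normal(Wd2, std::sqrt(2.0 / (27.0 * f[2])), rng);
    bd2 = arma::zeros<FM>(1, f[1]);
    Wd3.set_size(27 * f[1], 1);    fill_normal(Wd3, std::sqrt(1.0 / (27.0 * f[1])), rng);
    bd3 = arma::zeros<FM>(1, 1);
  }

  std::vector<FM*> params() {
    FM* raw[] = {&We1, &be1, &We2, &be2, &We3, &be3, &Wz, &bz,
                 &Wd1, &bd1, &Wd2, &bd2, &Wd3, &bd3};
    return std::vector<FM*>(raw, raw + 14);
  }

  void encode(const FM& x) {
    im2col(x, 12, P1);
    A1 = P1 * We1; A1.each_row() += be1.row(0); elu_fwd(A1);
    maxpool_fwd(A1, 12, M1, I1);
    im2col(M1, 6, P2);
    A2 = P2 * We2; A2.each_row() += be2.row(0); elu_fwd(A2);
    maxpool_fwd(A2, 6, M2, I2);
    im2col(M2, 3, P3);
    A3 = P3 * We3; A3.each_row() += be3.row(0); elu_fwd(A3);
    im2col(A3, 3, Pz);
    Az = Pz * Wz; Az.each_row() += bz.row(0);
    z = arma::conv_to<FV>::from(arma::mean(Az, 0).t());
  }

  void decode() {
    Zu.set_size(27, L);
    for (int v = 0; v < 27; ++v) Zu.row(v) = z.t();
    im2col(Zu, 3, Pd1);
    B1 = Pd1 * Wd1; B1.each_row() += bd1.row(0); elu_fwd(B1);
    upsample_fwd(B1, 3, 2, U1);
    im2col(U1, 6, Pd2);
    B2 = Pd2 * Wd2; B2.each_row() += bd2.row(0); elu_fwd(B2);
    upsample_fwd(B2, 6, 2, U2);
    im2col(U2, 12, Pd3);
    Xhat = Pd3 * Wd3; Xhat.each_row() += bd3.row(0);
  }

  // dXhat: (1728 x 1) loss gradient; accumulates into g (order of params())
  void backward(const FM& dXhat, std::vector<FM>& g) {
    // decoder
    g[12] += Pd3.t() * dXhat;
    g[13] += arma::sum(dXhat, 0);
    FM dU2;
    col2im(dXhat * Wd3.t(), 12, f[1], dU2);
    FM dB2;
    upsample_bwd(dU2, 6, 2, dB2);
    elu_bwd(B2, dB2);
    g[10] += Pd2.t() * dB2;
    g[11] += arma::sum(dB2, 0);
    FM dU1;
    col2im(dB2 * Wd2.t(), 6, f[2], dU1);
    FM dB1;
    upsample_bwd(dU1, 3, 2, dB1);
    elu_bwd(B1, dB1);
    g[8] += Pd1.t() * dB1;
    g[9] += arma::sum(dB1, 0);
    FM dZu;
    col2im(dB1 * Wd1.t(), 3, L, dZu);
    FV dz = arma::conv_to<FV>::from(arma::sum(dZu, 0).t());
    // latent conv + gap
    FM dAz(27, L);
    for (int v = 0; v < 27; ++v) dAz.row(v) = dz.t() / 27.f;
    g[6] += Pz.t() * dAz;
    g[7] += arma::sum(dAz, 0);
    FM dA3;
    col2im(dAz * Wz.t(), 3, f[2], dA3);
    elu_bwd(A3, dA3);
    g[4] += P3.t() * dA3;
    g[5] += arma::sum(dA3, 0);
    FM dM2;
    col2im(dA3 * We3.t(), 3, f[1], dM2);
    FM dA2;
    maxpool_bwd(dM2, I2, 216, dA2);
    elu_bwd(A2, dA2);
    g[2] += P2.t() * dA2;
    g[3] += arma::sum(dA2, 0);
    FM dM1;
    col2im(dA2 * We2.t(), 6, f[0], dM1);
    FM dA1;
    maxpool_bwd(dM1, I1, 1728, dA1);
    elu_bwd(A1, dA1);
    g[0] += P1.t() * dA1;
    g[1] += arma::sum(dA1, 0);
  }

  List export_weights() {
    std::vector<FM*> ps = params();
    List w;
    for (size_t i = 0; i < ps.size(); ++i)
      w.push_back(Rcpp::wrap(arma::conv_to<arma::mat>::from(*ps[i])));
    return w;
  }

  void import_weights(const List& w) {
    std::vector<FM*> ps = params();
    for (size_t i = 0; i < ps.size(); ++i)
      *ps[i] = arma::conv_to<FM>::from(Rcpp::as<arma::mat>(w[i]));
  }
};

double cae_mse_over(CAE& net, const FM& X) {
  double s = 0.0;
  FM x(1728, 1);
  for (arma::uword i = 0; i < X.n_cols; ++i) {
    x.col(0) = X.col(i);
    net.encode(x);
    net.decode();
    s += arma::accu(arma::square(net.Xhat.col(0) - x.col(0))) / 1728.0;
  }
  return s / X.n_cols;
}

}  // namespace

// [[Rcpp::export]]
List cpp_cae_train(const arma::mat& Xtr, const arma::mat& Xval, int latent_dim,
                   std::vector<int> filters, int epochs, int batch, double lr,
                   int seed, int patience, double lr_decay) {
  if (Xtr.n_rows != 1728) Rcpp::stop("autoencoder input must be 12^3 arrays");
  FM Xt = arma::conv_to<FM>::from(Xtr);
  FM Xv = arma::conv_to<FM>::from(Xval);
  const int n = static_cast<int>(Xt.n_cols);
  Rng rng(static_cast<uint32_t>(seed));
  CAE net;
  net.L = latent_dim;
  net.f = filters;
  // weights are initialised before importing since param shapes derive from f
  net.init_params(rng);
  std::vector<FM*> ps = net.params();
  Adam opt;
  opt.lr = lr;
  opt.init(ps);
  std::vector<FM> g(ps.size());
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> tr_hist, val_hist;
  double best_val = std::numeric_limits<double>::infinity();
  List best_w = net.export_weights();
  int best_epoch = 0, since_best = 0;
  FM x(1728, 1);
  for (int ep = 0; ep < epochs; ++ep) {
    opt.lr = lr * std::pow(lr_decay, ep);
    rng.shuffle(order);
    double tr_loss = 0.0;
    for (int b0 = 0; b0 < n; b0 += batch) {
      const int bs = std::min(batch, n - b0);
      for (size_t i = 0; i < ps.size(); ++i)
        g[i] = arma::zeros<FM>(ps[i]->n_rows, ps[i]->n_cols);
      for (int bi = 0; bi < bs; ++bi) {
        const int i = order[b0 + bi];
        x.col(0) = Xt.col(i);
        net.encode(x);
        net.decode();
        FM dX = net.Xhat - x;
        tr_loss += arma::accu(arma::square(dX)) / 1728.0;
        dX *= 2.f / (1728.f * bs);
        net.backward(dX, g);
      }
      opt.step(ps, g);
    }
    tr_hist.push_back(tr_loss / n);
    const bool has_val = Xv.n_cols > 0;
    const double vl = has_val ? cae_mse_over(net, Xv) : tr_loss / n;
    val_hist.push_back(vl);
    if (vl < best_val) {
      best_val = vl;
      best_w = net.export_weights();
      best_epoch = ep + 1;
      since_best = 0;
    } else if (++since_best >= patience) {
      break;
    }
    if (!std::isfinite(vl) || !std::isfinite(tr_hist.back()))
      Rcpp::stop("autoencoder training diverged (non-finite loss at epoch %d)", ep + 1);
  }
  return List::create(Named("weights") = best_w,
                      Named("train_mse") = tr_hist,
                      Named("val_mse") = val_hist,
                      Named("best_epoch") = best_epoch,
                      Named("best_val_mse") = best_val);
}

// [[Rcpp::export]]
arma::mat cpp_cae_encode(const List& weights, const arma::mat& X,
                         int latent_dim, std::vector<int> filters) {
  CAE net;
  net.L = latent_dim;
  net.f = filters;
  net.import_weights(weights);
  FM Xf = arma::conv_to<FM>::from(X);
  arma::mat Z(latent_dim, Xf.n_cols);
  FM x(1728, 1);
  for (arma::uword i = 0; i < Xf.n_cols; ++i) {
    x.col(0) = Xf.col(i);
    net.encode(x);
    Z.col(i) = arma::conv_to<arma::vec>::from(net.z);
  }
  return Z;
}

// [[Rcpp::export]]
arma::mat cpp_cae_decode(const List& weights, const arma::mat& Z,
                         int latent_dim, std::vector<int> filters) {
  CAE net;
  net.L = latent_dim;
  net.f = filters;
  net.import_weights(weights);
  arma::mat X(1728, Z.n_cols);
  for (arma::uword i = 0; i < Z.n_cols; ++i) {
    net.z = arma::conv_to<FV>::from(Z.col(i));
    net.decode();
    X.col(i) = arma::conv_to<arma::vec>::from(net.Xhat.col(0));
  }
  return X;
}
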