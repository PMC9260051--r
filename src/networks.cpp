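// Neural-network machinery for the fingerprint generator network (FGN),
// the image reconstruction network (IRN, a convolutional u-net with
// batch norm, leaky-ReLU and dropout), the parameter estimation network
// (PEN), and the self-supervised parallel training loop of the DIP
// reconstruction. Written directly on BLAS via Armadillo: convolutions
// are gemm on gathered neighborhoods, and both optimizers are Adam.
// All randomness flows from one mt19937_64 stream per call, so runs are
// bitwise reproducible given the seed.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <chrono>
using namespace arma;

namespace {

constexpr double LEAKY = 0.1;
constexpr double BN_EPS = 1e-5;
constexpr double BN_MOM = 0.1;

struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t s) : g(s) {}
  double unif() { return std::uniform_real_distribution<double>(0., 1.)(g); }
  double normal() { return std::normal_distribution<double>(0., 1.)(g); }
  int below(int n) { return (int)(g() % (uint64_t)n); }
};

fmat randn_mat(Rng& r, int n, int m, double sd) {
  fmat out(n, m);
  for (uword j = 0; j < out.n_cols; ++j)
    for (uword i = 0; i < out.n_rows; ++i)
      out(i, j) = (float)(sd * r.normal());
  return out;
}

// sample m distinct indices from 0..n-1 (partial Fisher-Yates)
uvec sample_wor(Rng& r, int n, int m) {
  static thread_local std::vector<int> pool;
  pool.resize(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  uvec out(m);
  for (int i = 0; i < m; ++i) {
    int j = i + r.below(n - i);
    std::swap(pool[i], pool[j]);
    out(i) = pool[i];
  }
  return out;
}

struct Param {
  fmat w, g, m, v;
  void init(const fmat& w0) {
    w = w0;
    g = m = v = zeros<fmat>(w.n_rows, w.n_cols);
  }
  void step(float lr, long t) {
    const float bc1 = 1.0f - std::pow(0.9f, (float)t);
    const float bc2 = 1.0f - std::pow(0.999f, (float)t);
    float* wp = w.memptr();
    const float* gp = g.memptr();
    float* mp = m.memptr();
    float* vp = v.memptr();
    for (uword i = 0; i < w.n_elem; ++i) {
      mp[i] = 0.9f * mp[i] + 0.1f * gp[i];
      vp[i] = 0.999f * vp[i] + 0.001f * gp[i] * gp[i];
      wp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + 1e-8f);
    }
  }
};

// ---------------------------------------------------------------- dense
struct Dense {
  Param W, b;
  fmat Xin;
  void init(Rng& r, int nin, int nout, float sd) {
    W.init(randn_mat(r, nin, nout, sd));
    b.init(zeros<fmat>(1, nout));
  }
  fmat forward(const fmat& X, bool save) {
    if (save) Xin = X;
    fmat Y = X * W.w;
    Y.each_row() += b.w.row(0);
    return Y;
  }
  fmat backward(const fmat& dY) {
    W.g = Xin.t() * dY;
    b.g = sum(dY, 0);
    return dY * W.w.t();
  }
};

struct LeakyCache {
  fmat mask;
  fmat forward(const fmat& X, bool save) {
    fmat Y = X;
    if (save) mask.set_size(X.n_rows, X.n_cols);
    for (uword i = 0; i < Y.n_elem; ++i) {
      const bool pos = Y(i) > 0;
      if (save) mask(i) = pos ? 1.0 : LEAKY;
      if (!pos) Y(i) *= LEAKY;
    }
    return Y;
  }
  fmat backward(const fmat& dY) { return dY % mask; }
};

// frozen fully-connected net (the pre-trained FGN inside the DIP loop)
struct FrozenMLP {
  std::vector<fmat> W;
  std::vector<frowvec> b;
  std::vector<fmat> cache_mask, cache_in;
  fmat forward(const fmat& X, bool save) {
    if (save) {
      cache_mask.assign(W.size() - 1, fmat());
      cache_in.assign(W.size(), fmat());
    }
    fmat H = X;
    for (size_t l = 0; l < W.size(); ++l) {
      if (save) cache_in[l] = H;
      H = H * W[l];
      H.each_row() += b[l];
      if (l + 1 < W.size()) {
        if (save) cache_mask[l].set_size(H.n_rows, H.n_cols);
        for (uword i = 0; i < H.n_elem; ++i) {
          const bool pos = H(i) > 0;
          if (save) cache_mask[l](i) = pos ? 1.0 : LEAKY;
          if (!pos) H(i) *= LEAKY;
        }
      }
    }
    return H;
  }
  fmat input_grad(const fmat& dOut) const {
    fmat d = dOut;
    for (int l = (int)W.size() - 1; l >= 0; --l) {
      d = d * W[l].t();
      if (l > 0) d %= cache_mask[l - 1];
    }
    return d;
  }
};

FrozenMLP load_frozen(const Rcpp::List& weights) {
  FrozenMLP f;
  const int n_layers = (weights.size()) / 2;
  for (int l = 0; l < n_layers; ++l) {
    f.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(weights[2 * l])));
    fmat bb = conv_to<fmat>::from(Rcpp::as<mat>(weights[2 * l + 1]));
    f.b.push_back(bb.row(0));
  }
  return f;
}

// ------------------------------------------------------------ conv bits
imat make_nbr(int h, int w, int stride) {
  const int ho = h / stride, wo = w / stride;
  imat nb(ho * wo, 9);
  int col = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++col) {
      for (int x0 = 0; x0 < wo; ++x0) {
        for (int y0 = 0; y0 < ho; ++y0) {
          const int y = y0 * stride + dy, x = x0 * stride + dx;
          nb(y0 + x0 * ho, col) =
              (y >= 0 && y < h && x >= 0 && x < w) ? y + x * h : -1;
        }
      }
    }
  }
  return nb;
}

// gather one 3x3 offset of the input feature map (zero padded)
void shift_gather(const fmat& X, const imat& nbr, int j, fmat& out) {
  const int no = nbr.n_rows, cin = X.n_cols;
  out.set_size(no, cin);
  const sword* src_idx = nbr.colptr(j);
  for (int c = 0; c < cin; ++c) {
    float* dst = out.colptr(c);
    const float* src = X.colptr(c);
    for (int i = 0; i < no; ++i) {
      const sword s = src_idx[i];
      dst[i] = (s >= 0) ? src[s] : 0.0f;
    }
  }
}

// 3x3 convolution evaluated as nine shifted gemms; the weight matrix is
// stored (9*cin) x cout with offset-major blocks
struct Conv3 {
  Param W, b;
  const imat* nbr = nullptr;
  int cin = 0, cout = 0, npix_in = 0;
  fmat Xin;
  void init(Rng& r, int cin_, int cout_) {
    cin = cin_; cout = cout_;
    W.init(randn_mat(r, 9 * cin, cout, std::sqrt(2.0 / (9.0 * cin))));
    b.init(zeros<fmat>(1, cout));
  }
  fmat forward(const fmat& X, bool save) {
    if (save) Xin = X;
    const int no = nbr->n_rows;
    fmat Y(no, cout);
    Y.each_row() = b.w.row(0);
    fmat xs;
    for (int j = 0; j < 9; ++j) {
      shift_gather(X, *nbr, j, xs);
      Y += xs * W.w.rows(j * cin, (j + 1) * cin - 1);
    }
    return Y;
  }
  fmat backward(const fmat& dY) {
    b.g = sum(dY, 0);
    fmat dX(npix_in, cin, fill::zeros);
    fmat xs;
    for (int j = 0; j < 9; ++j) {
      shift_gather(Xin, *nbr, j, xs);
      W.g.rows(j * cin, (j + 1) * cin - 1) = xs.t() * dY;
      // adjoint of the gather: scatter-add the shifted gradient
      fmat g = dY * W.w.rows(j * cin, (j + 1) * cin - 1).t();
      const sword* src_idx = nbr->colptr(j);
      for (int c = 0; c < cin; ++c) {
        const float* src = g.colptr(c);
        float* dst = dX.colptr(c);
        for (int i = 0; i < (int)nbr->n_rows; ++i) {
          const sword s2 = src_idx[i];
          if (s2 >= 0) dst[s2] += src[i];
        }
      }
    }
    return dX;
  }
};

struct BatchNorm {
  Param ga, be;
  frowvec rm, rv, invstd;
  fmat xhat;
  void init(int c) {
    ga.init(ones<fmat>(1, c));
    be.init(zeros<fmat>(1, c));
    rm = zeros<frowvec>(c);
    rv = ones<frowvec>(c);
  }
  fmat forward(const fmat& X, bool train) {
    if (train) {
      const frowvec mu = mean(X, 0);
      xhat = X;
      xhat.each_row() -= mu;
      const frowvec var = mean(square(xhat), 0);
      invstd = 1.0 / sqrt(var + BN_EPS);
      xhat.each_row() %= invstd;
      rm = (1 - BN_MOM) * rm + BN_MOM * mu;
      rv = (1 - BN_MOM) * rv + BN_MOM * var;
      fmat Y = xhat;
      Y.each_row() %= ga.w.row(0);
      Y.each_row() += be.w.row(0);
      return Y;
    }
    fmat Y = X;
    Y.each_row() -= rm;
    Y.each_row() /= sqrt(rv + BN_EPS);
    Y.each_row() %= ga.w.row(0);
    Y.each_row() += be.w.row(0);
    return Y;
  }
  fmat backward(const fmat& dY) {
    const float N = (float)dY.n_rows;
    ga.g = sum(dY % xhat, 0);
    be.g = sum(dY, 0);
    fmat dxh = dY;
    dxh.each_row() %= ga.w.row(0);
    const frowvec s1 = sum(dxh, 0);
    const frowvec s2 = sum(dxh % xhat, 0);
    fmat dX = N * dxh;
    dX.each_row() -= s1;
    fmat tmp = xhat;
    tmp.each_row() %= s2;
    dX -= tmp;
    dX.each_row() %= (invstd / N);
    return dX;
  }
};

struct ActDrop {                 // leaky ReLU then (optional) dropout
  fmat mask;
  fmat forward(const fmat& X, bool train, float drop, Rng& rng) {
    fmat Y(X.n_rows, X.n_cols);
    mask.set_size(X.n_rows, X.n_cols);
    const float keep = 1.0 - drop;
    for (uword i = 0; i < X.n_elem; ++i) {
      float m = X(i) > 0 ? 1.0 : LEAKY;
      if (train && drop > 0) m *= (rng.unif() < keep) ? (1.0 / keep) : 0.0;
      mask(i) = m;
      Y(i) = X(i) * m;
    }
    return Y;
  }
  fmat backward(const fmat& dY) { return dY % mask; }
};

struct Block {             // [conv -> batch norm -> leaky ReLU -> dropout] x2
  Conv3 convA, convB;
  BatchNorm bnA, bnB;
  ActDrop actA, actB;
  bool two = true;         // the finest decoder level runs a single conv
  fmat forward(const fmat& X, bool train, float drop, Rng& rng) {
    fmat h = actA.forward(bnA.forward(convA.forward(X, train), train), train,
                         drop, rng);
    if (!two) return h;
    return actB.forward(bnB.forward(convB.forward(h, train), train), train,
                        drop, rng);
  }
  fmat backward(const fmat& dY) {
    fmat d = two ? convB.backward(bnB.backward(actB.backward(dY))) : dY;
    return convA.backward(bnA.backward(actA.backward(d)));
  }
  void collect(std::vector<Param*>& ps) {
    ps.push_back(&convA.W); ps.push_back(&convA.b);
    ps.push_back(&bnA.ga); ps.push_back(&bnA.be);
    if (!two) return;
    ps.push_back(&convB.W); ps.push_back(&convB.b);
    ps.push_back(&bnB.ga); ps.push_back(&bnB.be);
  }
};

// ----------------------------------------------------------------- unet
struct Unet {
  int ny, nx, d, k, L;
  ivec ch;
  static constexpr int SKIP_CH = 4;
  std::vector<imat> nbr_down;     // stride-2 tables, input res of level l
  std::vector<imat> nbr_dec;      // stride-1 tables at decoder output res
  std::vector<uvec> up_idx;       // nearest-neighbor upsampling gather
  std::vector<Block> enc, dec;
  std::vector<Dense> sproj;       // 1x1 skip projections (4 channels)
  std::vector<LeakyCache> sact;
  Dense fin;
  std::vector<fmat> skip;          // cached projected skip activations
  float drop = 0.0;

  void build(Rng& r, int ny_, int nx_, int d_, int k_, const ivec& ch_) {
    ny = ny_; nx = nx_; d = d_; k = k_; ch = ch_; L = ch.n_elem;
    enc.resize(L); dec.resize(L);
    sproj.resize(L); sact.resize(L);
    nbr_down.resize(L); nbr_dec.resize(L + 1); up_idx.resize(L);
    int h = ny, w = nx;
    nbr_dec[0] = make_nbr(h, w, 1);
    for (int l = 0; l < L; ++l) {
      if (h % 2 || w % 2) Rcpp::stop("image size not divisible by 2^depth");
      nbr_down[l] = make_nbr(h, w, 2);
      nbr_dec[l + 1] = make_nbr(h / 2, w / 2, 1);
      const int cin = (l == 0) ? d : (int)ch(l - 1);
      // encoder: stride-2 conv then stride-1 conv at the lower resolution
      enc[l].convA.init(r, cin, ch(l));
      enc[l].convA.nbr = &nbr_down[l];
      enc[l].convA.npix_in = h * w;
      enc[l].bnA.init(ch(l));
      enc[l].convB.init(r, ch(l), ch(l));
      enc[l].convB.nbr = &nbr_dec[l + 1];
      enc[l].convB.npix_in = (h / 2) * (w / 2);
      enc[l].bnB.init(ch(l));
      sproj[l].init(r, cin, SKIP_CH, std::sqrt(2.0 / cin));
      // decoder at this level outputs resolution (h, w), two convs
      const int below_c = (l == L - 1) ? (int)ch(L - 1) : dec_out(l + 1);
      dec[l].convA.init(r, below_c + SKIP_CH, dec_out(l));
      dec[l].convA.nbr = &nbr_dec[l];
      dec[l].convA.npix_in = h * w;
      dec[l].bnA.init(dec_out(l));
      dec[l].convB.init(r, dec_out(l), dec_out(l));
      dec[l].convB.nbr = &nbr_dec[l];
      dec[l].convB.npix_in = h * w;
      dec[l].bnB.init(dec_out(l));
      // the finest levels carry most of the cost; a single conv there
      // (two convs at the cheap coarse levels) keeps the run tractable
      if (l <= 1) dec[l].two = false;
      if (l == 0) enc[l].two = false;
      // upsample from (h/2, w/2) to (h, w)
      uvec ui(h * w);
      for (int x = 0; x < w; ++x)
        for (int y = 0; y < h; ++y)
          ui(y + x * h) = (uword)((y / 2) + (x / 2) * (h / 2));
      up_idx[l] = ui;
      h /= 2; w /= 2;
    }
    fin.init(r, dec_out(0), 2 * k, std::sqrt(1.0 / dec_out(0)));
  }
  int dec_out(int l) const { return (int)ch(l > 0 ? l - 1 : 0); }

  fmat forward(const fmat& z, bool train, Rng& rng) {
    skip.assign(L, fmat());
    fmat h = z;
    for (int l = 0; l < L; ++l) {
      skip[l] = sact[l].forward(sproj[l].forward(h, train), train);
      h = enc[l].forward(h, train, drop, rng);
    }
    for (int l = L - 1; l >= 0; --l) {
      h = h.rows(up_idx[l]);                       // nearest-neighbor up
      h = join_rows(h, skip[l]);
      h = dec[l].forward(h, train, drop, rng);
    }
    return fin.forward(h, train);
  }

  fmat backward(const fmat& dOut) {
    fmat dh = fin.backward(dOut);
    std::vector<fmat> dskip(L);
    for (int l = 0; l <= L - 1; ++l) {
      dh = dec[l].backward(dh);
      const int below_c = (l == L - 1) ? (int)ch(L - 1) : dec_out(l + 1);
      fmat dbelow = dh.cols(0, below_c - 1);
      dskip[l] = dh.cols(below_c, dh.n_cols - 1);
      // adjoint of nearest-neighbor upsampling: sum the 2x2 children
      const int npix_dn = dbelow.n_rows / 4;
      fmat acc(npix_dn, dbelow.n_cols, fill::zeros);
      const uvec& ui = up_idx[l];
      for (uword c = 0; c < dbelow.n_cols; ++c) {
        float* dst = acc.colptr(c);
        const float* src = dbelow.colptr(c);
        for (uword i = 0; i < ui.n_elem; ++i) dst[ui(i)] += src[i];
      }
      dh = acc;
    }
    for (int l = L - 1; l >= 0; --l) {
      dh = enc[l].backward(dh);
      dh += sproj[l].backward(sact[l].backward(dskip[l]));
    }
    return dh;                                     // gradient w.r.t. z
  }

  void collect(std::vector<Param*>& ps) {
    for (int l = 0; l < L; ++l) {
      enc[l].collect(ps);
      dec[l].collect(ps);
      ps.push_back(&sproj[l].W); ps.push_back(&sproj[l].b);
    }
    ps.push_back(&fin.W); ps.push_back(&fin.b);
  }
};

// ------------------------------------------------------- centered FFT2
cx_fmat ctr_fft2f(const cx_fmat& img) {
  const int ny = img.n_rows, nx = img.n_cols;
  cx_fmat tmp = img;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if ((y + x) & 1) tmp(y, x) = -tmp(y, x);
  tmp = fft2(tmp);
  const float sc = 1.0f / std::sqrt((float)img.n_elem);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      tmp(y, x) *= ((y + x) & 1) ? -sc : sc;
  return tmp;
}
cx_fmat ctr_ifft2f(const cx_fmat& ksp) {
  const int ny = ksp.n_rows, nx = ksp.n_cols;
  cx_fmat tmp = ksp;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if ((y + x) & 1) tmp(y, x) = -tmp(y, x);
  tmp = ifft2(tmp);
  const float sc = std::sqrt((float)ksp.n_elem);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      tmp(y, x) *= ((y + x) & 1) ? -sc : sc;
  return tmp;
}

vec checkerboard(int ny, int nx) {
  vec cb(ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      cb(y + x * ny) = ((y + x) & 1) ? -1.0 : 1.0;
  return cb;
}
// centered orthonormal FFT via the checkerboard identity (even sizes)
cx_mat ctr_fft2(const cx_mat& img) {
  const int ny = img.n_rows, nx = img.n_cols;
  cx_mat tmp = img;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if ((y + x) & 1) tmp(y, x) = -tmp(y, x);
  tmp = fft2(tmp);
  const double sc = 1.0 / std::sqrt((double)img.n_elem);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      tmp(y, x) *= ((y + x) & 1) ? -sc : sc;
  return tmp;
}
cx_mat ctr_ifft2(const cx_mat& ksp) {
  const int ny = ksp.n_rows, nx = ksp.n_cols;
  cx_mat tmp = ksp;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if ((y + x) & 1) tmp(y, x) = -tmp(y, x);
  tmp = ifft2(tmp);
  const double sc = std::sqrt((double)ksp.n_elem);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      tmp(y, x) *= ((y + x) & 1) ? -sc : sc;
  return tmp;
}

cx_mat interleaved_to_cx(const mat& O, int k) {
  cx_mat out(O.n_rows, k);
  for (int j = 0; j < k; ++j)
    out.col(j) = cx_vec(O.col(2 * j), O.col(2 * j + 1));
  return out;
}

// -------------------------------------------------------------- the PEN
struct Pen {
  Dense d1, d2, d3;
  LeakyCache a1, a2;
  float t1_lo = 50, t1_hi = 3000, t2_lo = 5, t2_hi = 1000;
  fmat s_cache;                                     // sigmoids for backward
  void init(Rng& r, int k) {
    d1.init(r, 2 * k, 300, std::sqrt(2.0 / (2.0 * k)));
    d2.init(r, 300, 300, std::sqrt(2.0 / 300.0));
    d3.init(r, 300, 4, std::sqrt(1.0 / 300.0));
  }
  // returns columns: t1, t2, m0re, m0im
  fmat forward(const fmat& X, bool save) {
    fmat U = d3.forward(a2.forward(d2.forward(
        a1.forward(d1.forward(X, save), save), save), save), save);
    fmat out(U.n_rows, 4);
    if (save) s_cache.set_size(U.n_rows, 2);
    for (uword i = 0; i < U.n_rows; ++i) {
      const float s1 = 1.0 / (1.0 + std::exp(-(double)U(i, 0)));
      const float s2 = 1.0 / (1.0 + std::exp(-(double)U(i, 1)));
      if (save) { s_cache(i, 0) = s1; s_cache(i, 1) = s2; }
      out(i, 0) = t1_lo + (t1_hi - t1_lo) * s1;
      out(i, 1) = t2_lo + (t2_hi - t2_lo) * s2;
      out(i, 2) = U(i, 2);
      out(i, 3) = U(i, 3);
    }
    return out;
  }
  void backward(const fmat& dMaps) {
    fmat dU = dMaps;
    for (uword i = 0; i < dU.n_rows; ++i) {
      dU(i, 0) *= (t1_hi - t1_lo) * s_cache(i, 0) * (1 - s_cache(i, 0));
      dU(i, 1) *= (t2_hi - t2_lo) * s_cache(i, 1) * (1 - s_cache(i, 1));
    }
    d1.backward(a1.backward(d2.backward(a2.backward(d3.backward(dU)))));
  }
  void collect(std::vector<Param*>& ps) {
    ps.push_back(&d1.W); ps.push_back(&d1.b);
    ps.push_back(&d2.W); ps.push_back(&d2.b);
    ps.push_back(&d3.W); ps.push_back(&d3.b);
  }
};

struct Loss1Work {
  double loss = 0;
  mat dO;
};

struct Loss1WorkF {
  double loss = 0;
  fmat dO;
};

// single-precision variant used inside the training loop
Loss1WorkF loss1_and_grad_f(const fmat& O, const cx_fmat& y, const umat& P,
                            const fvec& W, const cx_fmat& S,
                            const cx_fmat& V, const uvec& frames, int ny,
                            int nx, int k, bool want_grad) {
  typedef std::complex<float> cxf;
  const int C = S.n_cols;
  const int HW = ny * nx;
  const int B = frames.n_elem;
  cx_fmat xk(O.n_rows, k);
  for (int j = 0; j < k; ++j)
    xk.col(j) = cx_fvec(O.col(2 * j), O.col(2 * j + 1));
  cx_fmat FB(HW * C, k);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      cx_fmat img(HW, 1);
      img.col(0) = S.col(c) % xk.col(j);
      img.reshape(ny, nx);
      cx_fmat f = ctr_fft2f(img);
      f.reshape(HW, 1);
      FB.submat(c * HW, j, (c + 1) * HW - 1, j) = f;
    }
  }
  double count = 0;
  for (int b = 0; b < B; ++b) count += (double)accu(P.col(frames(b))) * C;
  Loss1WorkF out;
  cx_fmat gFB;
  if (want_grad) gFB = zeros<cx_fmat>(HW * C, k);
  const float gscale = (float)(2.0 / count);
  for (int b = 0; b < B; ++b) {
    const uword i = frames(b);
    const uword* pc = P.colptr(i);
    const float* wp = W.memptr();
    cx_frowvec vrow = V.row(i);
    cx_frowvec vconj = conj(vrow);
    for (int c = 0; c < C; ++c) {
      const cxf* ycol = y.colptr(i * C + c);
      for (int px = 0; px < HW; ++px) {
        if (!pc[px]) continue;
        const float wpx = wp[px];
        const uword row = (uword)c * HW + px;
        cxf yh(0, 0);
        const cxf* fb = FB.memptr() + row;
        for (int j = 0; j < k; ++j) yh += fb[(uword)j * HW * C] * vconj(j);
        const cxf r = yh * wpx - ycol[px];
        out.loss += (double)std::norm(r);
        if (want_grad) {
          const cxf g = gscale * r * wpx;
          cxf* gp = gFB.memptr() + row;
          for (int j = 0; j < k; ++j) gp[(uword)j * HW * C] += g * vrow(j);
        }
      }
    }
  }
  out.loss /= count;
  if (want_grad) {
    out.dO.set_size(HW, 2 * k);
    for (int j = 0; j < k; ++j) {
      cx_fvec gx(HW, fill::zeros);
      for (int c = 0; c < C; ++c) {
        cx_fmat gk(HW, 1);
        gk.col(0) = gFB.submat(c * HW, j, (c + 1) * HW - 1, j);
        gk.reshape(ny, nx);
        cx_fmat gi = ctr_ifft2f(gk);
        gi.reshape(HW, 1);
        gx += conj(S.col(c)) % gi.col(0);
      }
      out.dO.col(2 * j) = real(gx);
      out.dO.col(2 * j + 1) = imag(gx);
    }
  }
  return out;
}

// loss 1 (k-space data consistency on a frame minibatch) and its
// gradient with respect to the interleaved network output
Loss1Work loss1_and_grad(const mat& O, const cx_mat& y, const umat& P,
                         const vec& W, const cx_mat& S, const cx_mat& V,
                         const uvec& frames, int ny, int nx, int k,
                         bool want_grad) {
  const int C = S.n_cols;
  const int HW = ny * nx;
  const int B = frames.n_elem;
  cx_mat xk = interleaved_to_cx(O, k);
  // stacked coil k-space of the basis images: rows are (coil, pixel)
  cx_mat FB(HW * C, k);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      cx_mat img(HW, 1);
      img.col(0) = S.col(c) % xk.col(j);
      img.reshape(ny, nx);
      cx_mat f = ctr_fft2(img);
      f.reshape(HW, 1);
      FB.submat(c * HW, j, (c + 1) * HW - 1, j) = f;
    }
  }
  double count = 0;
  for (int b = 0; b < B; ++b) count += (double)accu(P.col(frames(b))) * C;
  Loss1Work out;
  cx_mat gFB;
  if (want_grad) gFB = zeros<cx_mat>(HW * C, k);
  const double gscale = 2.0 / count;
  // the model and the residual are only needed on each frame's sampled
  // cells (~matrix/2 per interleaf), not on the full grid
  for (int b = 0; b < B; ++b) {
    const uword i = frames(b);
    const uword* pc = P.colptr(i);
    const double* wp = W.memptr();
    cx_rowvec vrow = V.row(i);                  // V(i, .)
    cx_rowvec vconj = conj(vrow);
    for (int c = 0; c < C; ++c) {
      const cx_double* ycol = y.colptr(i * C + c);
      for (int px = 0; px < HW; ++px) {
        if (!pc[px]) continue;
        const double wpx = wp[px];
        const uword row = (uword)c * HW + px;
        cx_double yh(0, 0);
        const cx_double* fb = FB.memptr() + row;
        for (int j = 0; j < k; ++j) yh += fb[(uword)j * HW * C] * vconj(j);
        const cx_double r = yh * wpx - ycol[px];
        out.loss += std::norm(r);
        if (want_grad) {
          const cx_double g = gscale * r * wpx;
          cx_double* gp = gFB.memptr() + row;
          for (int j = 0; j < k; ++j) gp[(uword)j * HW * C] += g * vrow(j);
        }
      }
    }
  }
  out.loss /= count;
  if (want_grad) {
    out.dO.set_size(HW, 2 * k);
    for (int j = 0; j < k; ++j) {
      cx_vec gx(HW, fill::zeros);
      for (int c = 0; c < C; ++c) {
        cx_mat gk(HW, 1);
        gk.col(0) = gFB.submat(c * HW, j, (c + 1) * HW - 1, j);
        gk.reshape(ny, nx);
        cx_mat gi = ctr_ifft2(gk);
        gi.reshape(HW, 1);
        gx += conj(S.col(c)) % gi.col(0);
      }
      out.dO.col(2 * j) = real(gx);
      out.dO.col(2 * j + 1) = imag(gx);
    }
  }
  return out;
}

}  // namespace

// ------------------------------------------------------------ exported

// Train a fully-connected regression network (leaky-ReLU hidden layers,
// linear output, MSE loss, Adam) and return the best-validation weights.
// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(const arma::mat& X, const arma::mat& Y,
                         const arma::ivec& hidden, int epochs, int batch,
                         double lr, int seed, double val_frac,
                         int patience) {
  const int N = X.n_rows;
  Rng rng((uint64_t)seed * 2654435761u + 17u);
  uvec perm = sample_wor(rng, N, N);
  const int n_val = std::max(1, (int)std::round(val_frac * N));
  const int n_tr = N - n_val;
  const fmat Xf = conv_to<fmat>::from(X), Yf = conv_to<fmat>::from(Y);
  const fmat Xtr = Xf.rows(perm.head(n_tr)), Ytr = Yf.rows(perm.head(n_tr));
  const fmat Xva = Xf.rows(perm.tail(n_val)), Yva = Yf.rows(perm.tail(n_val));

  std::vector<int> dims;
  dims.push_back(X.n_cols);
  for (uword i = 0; i < hidden.n_elem; ++i) dims.push_back((int)hidden(i));
  dims.push_back(Y.n_cols);
  const int nl = (int)dims.size() - 1;
  std::vector<Dense> layers(nl);
  std::vector<LeakyCache> acts(nl - 1);
  for (int l = 0; l < nl; ++l) {
    const double sd = (l == nl - 1) ? std::sqrt(1.0 / dims[l])
                                    : std::sqrt(2.0 / dims[l]);
    layers[l].init(rng, dims[l], dims[l + 1], sd);
  }
  std::vector<Param*> ps;
  for (int l = 0; l < nl; ++l) { ps.push_back(&layers[l].W); ps.push_back(&layers[l].b); }

  auto fwd = [&](const fmat& Xb, bool save) {
    fmat H = Xb;
    for (int l = 0; l < nl; ++l) {
      H = layers[l].forward(H, save);
      if (l < nl - 1) H = acts[l].forward(H, save);
    }
    return H;
  };

  vec tr_loss(epochs, fill::zeros), va_loss(epochs, fill::zeros);
  double best_val = datum::inf;
  int best_epoch = -1, stall = 0;
  std::vector<fmat> best_w(2 * nl);
  long t_adam = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    // step decay: x0.3 at 50% and 80% of the epoch budget
    double lr_ep = lr;
    if (ep >= (int)(0.8 * epochs)) lr_ep = lr * 0.09;
    else if (ep >= (int)(0.5 * epochs)) lr_ep = lr * 0.3;
    uvec order = sample_wor(rng, n_tr, n_tr);
    double acc_loss = 0;
    long n_seen = 0;
    for (int lo = 0; lo < n_tr; lo += batch) {
      const int hi = std::min(lo + batch, n_tr) - 1;
      const uvec idx = order.subvec(lo, hi);
      const fmat Xb = Xtr.rows(idx), Yb = Ytr.rows(idx);
      fmat Pr = fwd(Xb, true);
      fmat R = Pr - Yb;
      acc_loss += (double)accu(square(R));
      n_seen += R.n_elem;
      fmat d = (2.0f / (float)R.n_elem) * R;
      for (int l = nl - 1; l >= 0; --l) {
        d = layers[l].backward(d);
        if (l > 0) d = acts[l - 1].backward(d);
      }
      ++t_adam;
      for (Param* p : ps) p->step(lr_ep, t_adam);
    }
    tr_loss(ep) = acc_loss / (double)n_seen;
    const fmat Pv = fwd(Xva, false);
    va_loss(ep) = (double)accu(square(Pv - Yva)) / (double)Pv.n_elem;
    if (va_loss(ep) < best_val) {
      best_val = va_loss(ep);
      best_epoch = ep;
      stall = 0;
      for (int l = 0; l < nl; ++l) {
        best_w[2 * l] = layers[l].W.w;
        best_w[2 * l + 1] = layers[l].b.w;
      }
    } else if (++stall > patience) {
      tr_loss = tr_loss.head(ep + 1);
      va_loss = va_loss.head(ep + 1);
      break;
    }
  }
  Rcpp::List w(2 * nl);
  for (int l = 0; l < 2 * nl; ++l)
    w[l] = conv_to<mat>::from(best_w[l]);
  return Rcpp::List::create(
      Rcpp::Named("weights") = w, Rcpp::Named("train_loss") = tr_loss,
      Rcpp::Named("val_loss") = va_loss,
      Rcpp::Named("best_val") = best_val,
      Rcpp::Named("best_epoch") = best_epoch + 1);
}

// forward pass through weights produced by mlp_train_cpp
// [[Rcpp::export]]
arma::mat mlp_forward_cpp(Rcpp::List weights, const arma::mat& X) {
  FrozenMLP f = load_frozen(weights);
  return conv_to<mat>::from(f.forward(conv_to<fmat>::from(X), false));
}

// Self-supervised DIP-MRF training: the IRN maps a fixed random tensor z
// to spatial basis images; loss 1 enforces masked k-space consistency on
// a frame minibatch and updates the IRN; loss 2 fits the PEN (through the
// frozen FGN) to the detached basis images and updates the PEN. Two
// independent Adam optimizers run in parallel each iteration.
// [[Rcpp::export]]
Rcpp::List dip_train_cpp(const arma::cx_mat& y, const arma::umat& P,
                         const arma::vec& W, const arma::cx_mat& S,
                         const arma::cx_mat& V, const arma::vec& bscale,
                         Rcpp::List fgn_weights,
                         const arma::rowvec& rr_norm, int ny, int nx,
                         int d, const arma::ivec& channels, int n_iters,
                         double lr, int batch_frames, int vox_batch,
                         double dropout, int seed, int record_every,
                         const arma::vec& t1_true,
                         const arma::vec& t2_true,
                         const arma::uvec& fg_idx, bool compute_trace) {
  const int t = P.n_cols, C = S.n_cols, k = V.n_cols, HW = ny * nx;
  if ((int)y.n_rows != HW || (int)y.n_cols != t * C)
    Rcpp::stop("k-space data must be HW x (frames * coils)");
  const cx_fmat yf = conv_to<cx_fmat>::from(y);
  const cx_fmat Sf = conv_to<cx_fmat>::from(S);
  const cx_fmat Vf = conv_to<cx_fmat>::from(V);
  const fvec Wf = conv_to<fvec>::from(W);
  Rng rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);

  // fixed random input tensor, uniform in [-0.1, 0.1]
  fmat z(HW, d);
  for (uword i = 0; i < z.n_elem; ++i) z(i) = 0.2 * rng.unif() - 0.1;

  Unet irn;
  irn.build(rng, ny, nx, d, k, channels);
  irn.drop = dropout;
  Pen pen;
  pen.init(rng, k);
  FrozenMLP fgn = load_frozen(fgn_weights);
  std::vector<Param*> irn_ps, pen_ps;
  irn.collect(irn_ps);
  pen.collect(pen_ps);

  vec loss1_trace(n_iters), loss2_trace(n_iters);
  std::vector<double> tr_iter, tr_t1, tr_t2;
  double sc = 0.0;
  long t1_adam = 0, t2_adam = 0;
  const int nb = std::min(batch_frames, t);
  const int nv = std::min(vox_batch, HW);

  auto apply_bscale = [&](fmat& O) {
    for (int j = 0; j < k; ++j) {
      O.col(2 * j) *= (float)bscale(j);
      O.col(2 * j + 1) *= (float)bscale(j);
    }
  };
  auto eval_maps = [&](fmat& maps, cx_mat& xk_out) {
    Rng dummy(0);
    fmat O = irn.forward(z, false, dummy);
    apply_bscale(O);
    xk_out = interleaved_to_cx(conv_to<mat>::from(O), k);
    if (sc <= 0) sc = std::max((double)abs(O).max(), 1e-12);
    maps = pen.forward(O / (float)sc, false);
  };

  double tm_fwd = 0, tm_l1 = 0, tm_bwd = 0, tm_adam = 0, tm_l2 = 0;
  auto now = []() { return std::chrono::steady_clock::now(); };
  auto el = [](std::chrono::steady_clock::time_point a,
               std::chrono::steady_clock::time_point b) {
    return std::chrono::duration<double>(b - a).count();
  };
  for (int it = 0; it < n_iters; ++it) {
    // step decay keeps early exploration fast and settles the dropout
    // noise at the end: x0.3 at 60% and x0.1 at 85% of the run
    double lr_it = lr;
    if (it >= (int)(0.85 * n_iters)) lr_it = lr * 0.1;
    else if (it >= (int)(0.6 * n_iters)) lr_it = lr * 0.3;
    // ---- loss 1: update the image reconstruction network
    auto c0 = now();
    fmat O = irn.forward(z, true, rng);
    apply_bscale(O);                 // precondition: channel j carries the
                                     // dictionary's relative singular value
    auto c1 = now(); tm_fwd += el(c0, c1);
    uvec frames = sample_wor(rng, t, nb);
    Loss1WorkF l1 = loss1_and_grad_f(O, yf, P, Wf, Sf, Vf,
                                     frames, ny, nx, k, true);
    auto c2 = now(); tm_l1 += el(c1, c2);
    if (!std::isfinite(l1.loss))
      Rcpp::stop("loss 1 became non-finite at iteration %d", it + 1);
    apply_bscale(l1.dO);
    irn.backward(l1.dO);
    auto c3 = now(); tm_bwd += el(c2, c3);
    ++t1_adam;
    for (Param* p : irn_ps) p->step(lr_it, t1_adam);
    auto c4 = now(); tm_adam += el(c3, c4);
    loss1_trace(it) = l1.loss;

    // ---- loss 2: update the parameter estimation network
    // running-max input scale: grows during the early iterations while the
    // basis images approach the data scale, then is effectively constant
    sc = std::max(sc, std::max((double)abs(O).max(), 1e-12));
    uvec vox = sample_wor(rng, HW, nv);
    fmat Xin(nv, 2 * k);
    for (int j = 0; j < 2 * k; ++j)
      for (int i = 0; i < nv; ++i) Xin(i, j) = O(vox(i), j) / (float)sc;
    fmat maps = pen.forward(Xin, true);
    fmat Fin(nv, 2 + rr_norm.n_elem);
    Fin.col(0) = maps.col(0) / 3000.0f;
    Fin.col(1) = maps.col(1) / 3000.0f;
    for (uword j = 0; j < rr_norm.n_elem; ++j)
      Fin.col(2 + j).fill((float)rr_norm(j));
    fmat F = fgn.forward(Fin, true);
    const int tt = F.n_cols / 2;
    cx_mat fp(nv, tt);
    for (int j = 0; j < tt; ++j)
      fp.col(j) = cx_vec(conv_to<vec>::from(F.col(2 * j)),
                         conv_to<vec>::from(F.col(2 * j + 1)));
    cx_vec M0 = cx_vec(conv_to<vec>::from(maps.col(2)),
                       conv_to<vec>::from(maps.col(3)));
    cx_mat zfp = fp.each_col() % M0;
    cx_mat ck = zfp * V;                      // nv x k
    cx_mat xk_sub(nv, k);
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < nv; ++i)
        xk_sub(i, j) = cx_double(O(vox(i), 2 * j), O(vox(i), 2 * j + 1)) / sc;
    cx_mat e = xk_sub - ck;
    const double nrm = (double)(nv * k);
    const double l2 = accu(square(abs(e))) / nrm;
    if (!std::isfinite(l2))
      Rcpp::stop("loss 2 became non-finite at iteration %d", it + 1);
    cx_mat g_ck = (-2.0 / nrm) * e;
    cx_mat g_z = g_ck * V.t();                // nv x t
    cx_vec g_M0 = sum(g_z % conj(fp), 1);
    cx_mat g_fp = g_z.each_col() % conj(M0);
    fmat gF(nv, 2 * tt);
    for (int j = 0; j < tt; ++j) {
      gF.col(2 * j) = conv_to<fvec>::from(real(g_fp.col(j)));
      gF.col(2 * j + 1) = conv_to<fvec>::from(imag(g_fp.col(j)));
    }
    fmat g_in = fgn.input_grad(gF);
    fmat dMaps(nv, 4);
    dMaps.col(0) = g_in.col(0) / 3000.0f;
    dMaps.col(1) = g_in.col(1) / 3000.0f;
    dMaps.col(2) = conv_to<fvec>::from(real(g_M0));
    dMaps.col(3) = conv_to<fvec>::from(imag(g_M0));
    pen.backward(dMaps);
    ++t2_adam;
    for (Param* p : pen_ps) p->step(lr_it, t2_adam);
    loss2_trace(it) = l2;
    tm_l2 += el(c4, now());

    if (compute_trace && ((it + 1) % record_every == 0 || it == 0)) {
      fmat maps_all; cx_mat xk_e;
      eval_maps(maps_all, xk_e);
      double n1 = 0, d1 = 0, n2 = 0, d2 = 0;
      for (uword ii = 0; ii < fg_idx.n_elem; ++ii) {
        const uword vvi = fg_idx(ii);
        n1 += std::pow(maps_all(vvi, 0) - t1_true(vvi), 2);
        d1 += std::pow(t1_true(vvi), 2);
        n2 += std::pow(maps_all(vvi, 1) - t2_true(vvi), 2);
        d2 += std::pow(t2_true(vvi), 2);
      }
      tr_iter.push_back(it + 1);
      tr_t1.push_back(100.0 * std::sqrt(n1 / d1));
      tr_t2.push_back(100.0 * std::sqrt(n2 / d2));
    }
    if ((it + 1) % 500 == 0) Rcpp::checkUserInterrupt();
  }

  if (std::getenv("CMRF_DIP_TIMING"))
    Rprintf("dip timing (s): fwd %.2f loss1 %.2f bwd %.2f adam %.2f loss2 %.2f\n",
            tm_fwd, tm_l1, tm_bwd, tm_adam, tm_l2);
  fmat maps_all; cx_mat xk_out;
  eval_maps(maps_all, xk_out);
  return Rcpp::List::create(
      Rcpp::Named("t1") = conv_to<vec>::from(maps_all.col(0)),
      Rcpp::Named("t2") = conv_to<vec>::from(maps_all.col(1)),
      Rcpp::Named("m0_re") = conv_to<vec>::from(maps_all.col(2)) * sc,
      Rcpp::Named("m0_im") = conv_to<vec>::from(maps_all.col(3)) * sc,
      Rcpp::Named("x_k") = xk_out,
      Rcpp::Named("z") = conv_to<mat>::from(z),
      Rcpp::Named("loss1") = loss1_trace, Rcpp::Named("loss2") = loss2_trace,
      Rcpp::Named("scale") = sc,
      Rcpp::Named("trace_iter") = tr_iter,
      Rcpp::Named("trace_t1_nrmse") = tr_t1,
      Rcpp::Named("trace_t2_nrmse") = tr_t2);
}

// centered orthonormal FFT used inside the training loop (for tests)
// [[Rcpp::export]]
arma::cx_mat ctr_fft2_cpp(const arma::cx_mat& img) { return ctr_fft2(img); }

// [[Rcpp::export]]
arma::cx_mat ctr_ifft2_cpp(const arma::cx_mat& ksp) { return ctr_ifft2(ksp); }

// expose one 3x3 convolution for numerical verification from R
// [[Rcpp::export]]
Rcpp::List conv3_test_cpp(int seed, int h, int w, int cin, int cout,
                          int stride) {
  Rng rng((uint64_t)seed);
  imat nbr = make_nbr(h, w, stride);
  Conv3 conv;
  conv.init(rng, cin, cout);
  conv.nbr = &nbr;
  conv.npix_in = h * w;
  fmat X = randn_mat(rng, h * w, cin, 1.0);
  fmat Y = conv.forward(X, true);
  fmat dY = randn_mat(rng, Y.n_rows, cout, 1.0);
  fmat dX = conv.backward(dY);
  return Rcpp::List::create(
      Rcpp::Named("X") = conv_to<mat>::from(X),
      Rcpp::Named("W") = conv_to<mat>::from(conv.W.w),
      Rcpp::Named("b") = conv_to<mat>::from(conv.b.w),
      Rcpp::Named("Y") = conv_to<mat>::from(Y),
      Rcpp::Named("dY") = conv_to<mat>::from(dY),
      Rcpp::Named("dX") = conv_to<mat>::from(dX),
      Rcpp::Named("dW") = conv_to<mat>::from(conv.W.g),
      Rcpp::Named("nbr") = nbr);
}

// Finite-difference check of the IRN/loss-1 gradient path on a tiny
// random problem; returns the worst relative error over probed weights.
// [[Rcpp::export]]
double unet_gradcheck_cpp(int seed, int ny, int nx, int d, int k,
                          const arma::ivec& channels, int n_coils,
                          int t, int n_probe, double h) {
  Rng rng((uint64_t)seed + 99u);
  const int HW = ny * nx;
  fmat z = randn_mat(rng, HW, d, 1.0);
  cx_mat y(HW, t * n_coils), S(HW, n_coils), V(t, k);
  for (uword i = 0; i < y.n_elem; ++i) y(i) = cx_double(rng.normal(), rng.normal());
  for (uword i = 0; i < S.n_elem; ++i) S(i) = cx_double(rng.normal(), rng.normal());
  for (uword i = 0; i < V.n_elem; ++i) V(i) = cx_double(rng.normal(), rng.normal());
  umat P(HW, t);
  for (uword i = 0; i < P.n_elem; ++i) P(i) = rng.unif() < 0.6 ? 1 : 0;
  vec W(HW);
  for (int i = 0; i < HW; ++i) W(i) = 0.5 + rng.unif();
  uvec frames(t);
  for (int i = 0; i < t; ++i) frames(i) = i;

  Unet net;
  net.build(rng, ny, nx, d, k, channels);
  net.drop = 0.0;
  std::vector<Param*> ps;
  net.collect(ps);

  // analytic gradient (dropout off, but training-mode batch norm)
  Rng r2(7);
  fmat O = net.forward(z, true, r2);
  Loss1Work l1 = loss1_and_grad(conv_to<mat>::from(O), y, P, W, S, V,
                                frames, ny, nx, k, true);
  net.backward(conv_to<fmat>::from(l1.dO));
  std::vector<fmat> grads;
  for (Param* p : ps) grads.push_back(p->g);
  double gmax = 0;
  for (auto& g : grads) gmax = std::max(gmax, (double)abs(g).max());

  double worst = 0;
  for (int probe = 0; probe < n_probe; ++probe) {
    const int pi = rng.below((int)ps.size());
    // conv biases feed straight into batch norm, so their true gradient is
    // identically zero; skip blocks whose gradient is pure round-off
    if ((double)abs(grads[pi]).max() < 1e-4 * gmax) continue;
    Param* p = ps[pi];
    const uword ei = (uword)rng.below((int)p->w.n_elem);
    const float w0 = p->w(ei);
    p->w(ei) = w0 + (float)h;
    Rng ra(7);
    double fp_ = loss1_and_grad(conv_to<mat>::from(net.forward(z, true, ra)),
                                y, P, W, S, V, frames, ny, nx, k, false).loss;
    p->w(ei) = w0 - (float)h;
    Rng rb(7);
    double fm_ = loss1_and_grad(conv_to<mat>::from(net.forward(z, true, rb)),
                                y, P, W, S, V, frames, ny, nx, k, false).loss;
    p->w(ei) = w0;
    const double fd = (fp_ - fm_) / (2 * h);
    const double an = grads[pi](ei);
    // compare at the scale of the parameter block's gradient so probes with
    // near-zero gradients are not dominated by finite-difference noise
    const double gscale = (double)abs(grads[pi]).max();
    const double rel = std::abs(fd - an) /
        std::max(0.01 * gscale, std::abs(fd) + std::abs(an));
    if (rel > 0.1 && std::getenv("CMRF_GC_DEBUG"))
      Rprintf("probe p=%d e=%d fd=%.4g an=%.4g gscale=%.4g\n",
              pi, (int)ei, fd, an, gscale);
    worst = std::max(worst, rel);
  }
  return worst;
}
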