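// Single-precision CNN for pseudo-landmark regression, trained on CPU.
//
// Layer grammar: `blocks` convolution blocks (each `convs_per_block` 3x3
// same-padded convolutions with ReLU, channels doubling per block from
// `base_channels`), each block closed by a 2x2 pooling (max or average,
// floor semantics on odd sizes); then `fc_layers` dense layers (ReLU +
// dropout on hidden layers, linear output). Loss is the mean squared error
// over all outputs; optimization is Adam (or SGD with Nesterov momentum)
// under a staged learning-rate schedule. Everything is single-threaded and
// bit-reproducible for a fixed seed.
//
// Activation layout is channels-first: an activation is an arma::fmat with
// C rows and B*H*W columns, column index = b*H*W + x*H + y; a column is one
// pixel's channel vector. Convolutions are cache-tiled im2col + sgemm: the
// column buffer only ever holds a tile of whole x-columns, so it stays in
// cache and the zero-padding edges are written explicitly instead of
// zeroing the whole buffer (the machine this targets is memory-bandwidth
// starved, not FLOP starved). The backward pass recomputes the im2col tiles
// rather than keeping them. Patches arrive as column-major 48 x 92
// matrices, i.e. pixel (x, y) at linear index x*H + y, matching this
// layout with C = 1.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
#include <random>
#include <vector>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Arch {
  int blocks, convs_per_block, base_channels, fc_layers, fc_hidden;
  int in_h, in_w, out_dim;
  bool max_pool;
  double dropout;
};

static Arch parse_arch(const List& a) {
  Arch r;
  r.blocks = as<int>(a["blocks"]);
  r.convs_per_block = as<int>(a["convs_per_block"]);
  r.base_channels = as<int>(a["base_channels"]);
  r.fc_layers = as<int>(a["fc_layers"]);
  r.fc_hidden = as<int>(a["fc_hidden"]);
  r.in_h = as<int>(a["in_h"]);
  r.in_w = as<int>(a["in_w"]);
  r.out_dim = as<int>(a["out_dim"]);
  r.max_pool = as<std::string>(a["pooling"]) == "max";
  r.dropout = as<double>(a["dropout"]);
  return r;
}

// --- tiled im2col ----------------------------------------------------------
// Tiles cover whole x-columns: global x-column index g in [g0, g1) maps to
// sample b = g / W and in-sample column x = g % W; pixels of one x-column
// (H of them) are contiguous. col is 9C x (g1-g0)*H.

static void im2col3_tile(const fmat& A, int H, int W, int g0, int g1,
                         fmat& col) {
  const int C = A.n_rows;
  const size_t cs = 9 * (size_t)C;
  const float* src = A.memptr();
  float* dst = col.memptr();
  for (int g = g0; g < g1; ++g) {
    const int x = g % W;
    const bool okm = x > 0, okp = x < W - 1;
    // base pointers of the three source x-columns (left, center, right)
    const float* sc[3] = {src + (size_t)(g - 1) * H * C,
                          src + (size_t)g * H * C,
                          src + (size_t)(g + 1) * H * C};
    const bool ok[3] = {okm, true, okp};
    float* d = dst + (size_t)(g - g0) * H * cs;
    for (int y = 0; y < H; ++y, d += cs) {
      for (int dx = 0; dx < 3; ++dx) {
        float* dk = d + (size_t)dx * 3 * C;     // k = dx*3 + dy-index
        if (!ok[dx]) {
          std::memset(dk, 0, 3 * C * sizeof(float));
          continue;
        }
        const float* s = sc[dx] + (size_t)y * C;
        // dy = -1, 0, +1
        if (y > 0) { const float* sm = s - C; for (int c = 0; c < C; ++c) dk[c] = sm[c]; }
        else std::memset(dk, 0, C * sizeof(float));
        float* dk0 = dk + C;
        for (int c = 0; c < C; ++c) dk0[c] = s[c];
        float* dkp = dk + 2 * C;
        if (y < H - 1) { const float* sp = s + C; for (int c = 0; c < C; ++c) dkp[c] = sp[c]; }
        else std::memset(dkp, 0, C * sizeof(float));
      }
    }
  }
}

// scatter-add transpose of im2col3_tile: col (9C x (g1-g0)*H) -> dA
static void col2im3_tile(const fmat& col, int H, int W, int g0, int g1,
                         fmat& dA) {
  const int C = dA.n_rows;
  const size_t cs = 9 * (size_t)C;
  const float* src = col.memptr();
  float* dst = dA.memptr();
  for (int g = g0; g < g1; ++g) {
    const int x = g % W;
    const bool ok[3] = {x > 0, true, x < W - 1};
    float* dc[3] = {dst + (size_t)(g - 1) * H * C,
                    dst + (size_t)g * H * C,
                    dst + (size_t)(g + 1) * H * C};
    const float* s = src + (size_t)(g - g0) * H * cs;
    for (int y = 0; y < H; ++y, s += cs) {
      for (int dx = 0; dx < 3; ++dx) {
        if (!ok[dx]) continue;
        const float* sk = s + (size_t)dx * 3 * C;
        float* d = dc[dx] + (size_t)y * C;
        if (y > 0) { float* dm = d - C; for (int c = 0; c < C; ++c) dm[c] += sk[c]; }
        const float* sk0 = sk + C;
        for (int c = 0; c < C; ++c) d[c] += sk0[c];
        if (y < H - 1) { const float* skp = sk + 2 * C; float* dp = d + C;
                         for (int c = 0; c < C; ++c) dp[c] += skp[c]; }
      }
    }
  }
}

static int conv_tile_xcols(int H) {
  // ~3k pixel columns per tile keeps the 9C x tile buffer in cache
  return std::max(2, 3072 / H);
}

// Z = relu(W * im2col(A) + b), tiled; Z preallocated Cout x (B*H*W)
static void conv_fwd(const fmat& Wm, const fvec& bias, const fmat& A,
                     int B, int H, int W, fmat& Z, fmat& colbuf) {
  const int Cout = Wm.n_rows, C = A.n_rows;
  const int G = B * W;                       // total x-columns
  const int gt = conv_tile_xcols(H);
  if ((int)colbuf.n_rows != 9 * C || (int)colbuf.n_cols < gt * H)
    colbuf.set_size(9 * C, gt * H);
  for (int g0 = 0; g0 < G; g0 += gt) {
    const int g1 = std::min(G, g0 + gt);
    const int n = (g1 - g0) * H;
    im2col3_tile(A, H, W, g0, g1, colbuf);
    fmat Zt = Wm * colbuf.cols(0, n - 1);
    float* zp = Z.colptr((size_t)g0 * H);
    const float* tp = Zt.memptr();
    const float* bp = bias.memptr();
    for (int j = 0; j < n; ++j, zp += Cout, tp += Cout)
      for (int c = 0; c < Cout; ++c) {
        const float v = tp[c] + bp[c];
        zp[c] = v > 0.0f ? v : 0.0f;
      }
  }
}

// backward through conv given dZ (already ReLU-masked): accumulates dW, db,
// and computes dA (zero-initialized by caller)
static void conv_bwd(const fmat& Wm, const fmat& A, const fmat& dZ,
                     int B, int H, int W, fmat& dW, fvec& db, fmat* dA,
                     fmat& colbuf, fmat& dcolbuf) {
  const int C = A.n_rows;
  const int G = B * W;
  const int gt = conv_tile_xcols(H);
  if ((int)colbuf.n_rows != 9 * C || (int)colbuf.n_cols < gt * H)
    colbuf.set_size(9 * C, gt * H);
  dW.zeros(Wm.n_rows, Wm.n_cols);
  db.zeros(Wm.n_rows);
  for (int g0 = 0; g0 < G; g0 += gt) {
    const int g1 = std::min(G, g0 + gt);
    const int n = (g1 - g0) * H;
    im2col3_tile(A, H, W, g0, g1, colbuf);
    const fmat dZt(const_cast<float*>(dZ.colptr((size_t)g0 * H)), dZ.n_rows, n,
                   false, true);
    dW += dZt * colbuf.cols(0, n - 1).t();
    db += arma::sum(dZt, 1);
    if (dA) {
      dcolbuf = Wm.t() * dZt;
      col2im3_tile(dcolbuf, H, W, g0, g1, *dA);
    }
  }
}

// --- pooling ---------------------------------------------------------------

static void pool_fwd(const fmat& A, int B, int H, int W, bool maxp,
                     fmat& out, arma::Mat<unsigned char>& which) {
  const int Ho = H / 2, Wo = W / 2, C = A.n_rows;
  out.set_size(C, (size_t)B * Ho * Wo);
  if (maxp) which.set_size(C, out.n_cols);
  const float* src = A.memptr();
  float* dst = out.memptr();
  for (int b = 0; b < B; ++b) {
    const size_t ibase = (size_t)b * H * W, obase = (size_t)b * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        const size_t orow = obase + (size_t)ox * Ho + oy;
        const size_t i00 = ibase + (size_t)(2 * ox) * H + 2 * oy;
        const float* p[4] = {src + i00 * C, src + (i00 + 1) * C,
                             src + (i00 + H) * C, src + (i00 + H + 1) * C};
        float* o = dst + orow * C;
        if (maxp) {
          unsigned char* wch = which.colptr(orow);
          for (int c = 0; c < C; ++c) {
            float m = p[0][c]; unsigned char arg = 0;
            if (p[1][c] > m) { m = p[1][c]; arg = 1; }
            if (p[2][c] > m) { m = p[2][c]; arg = 2; }
            if (p[3][c] > m) { m = p[3][c]; arg = 3; }
            o[c] = m; wch[c] = arg;
          }
        } else {
          for (int c = 0; c < C; ++c)
            o[c] = 0.25f * (p[0][c] + p[1][c] + p[2][c] + p[3][c]);
        }
      }
    }
  }
}

static void pool_bwd(const fmat& dout, int B, int H, int W, bool maxp,
                     const arma::Mat<unsigned char>& which, fmat& dA) {
  const int Ho = H / 2, Wo = W / 2, C = dout.n_rows;
  dA.zeros();
  const float* src = dout.memptr();
  float* dst = dA.memptr();
  for (int b = 0; b < B; ++b) {
    const size_t ibase = (size_t)b * H * W, obase = (size_t)b * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        const size_t orow = obase + (size_t)ox * Ho + oy;
        const size_t i00 = ibase + (size_t)(2 * ox) * H + 2 * oy;
        float* p[4] = {dst + i00 * C, dst + (i00 + 1) * C,
                       dst + (i00 + H) * C, dst + (i00 + H + 1) * C};
        const float* g = src + orow * C;
        if (maxp) {
          const unsigned char* wch = which.colptr(orow);
          for (int c = 0; c < C; ++c) p[wch[c]][c] += g[c];
        } else {
          for (int c = 0; c < C; ++c) {
            const float q = 0.25f * g[c];
            p[0][c] += q; p[1][c] += q; p[2][c] += q; p[3][c] += q;
          }
        }
      }
    }
  }
}

static inline void relu_inplace(fmat& Z) {
  float* p = Z.memptr();
  const size_t n = Z.n_elem;
  for (size_t i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

// dZ *= (act > 0)
static inline void relu_mask(const fmat& act, fmat& dZ) {
  const float* a = act.memptr();
  float* g = dZ.memptr();
  const size_t n = act.n_elem;
  for (size_t i = 0; i < n; ++i) if (a[i] <= 0.0f) g[i] = 0.0f;
}

// --- network ---------------------------------------------------------------

struct Net {
  Arch arch;
  std::vector<fmat> W;   // conv: Cout x 9Cin; fc: out x in  (transposed store)
  std::vector<fvec> b;
  int n_conv;

  void load(const List& weights, const Arch& a) {
    arch = a;
    n_conv = a.blocks * a.convs_per_block;
    const int n_layer = n_conv + a.fc_layers;
    W.resize(n_layer); b.resize(n_layer);
    for (int l = 0; l < n_layer; ++l) {
      List wl = weights[l];
      arma::mat wm = as<arma::mat>(wl["W"]);   // (9Cin x Cout) / (in x out)
      arma::vec bv = as<arma::vec>(wl["b"]);
      W[l] = arma::conv_to<fmat>::from(wm.t());
      b[l] = arma::conv_to<fvec>::from(bv);
    }
  }

  List dump() const {
    List out(W.size());
    for (size_t l = 0; l < W.size(); ++l) {
      out[l] = List::create(
        _["W"] = wrap(arma::conv_to<arma::mat>::from(W[l].t())),
        _["b"] = wrap(arma::conv_to<arma::vec>::from(b[l])));
    }
    return out;
  }
};

struct Tape {
  std::vector<fmat> act;        // post-ReLU conv activations (pool inputs are
                                // the block's last conv activation)
  std::vector<fmat> pooled;     // pooled activation per block
  std::vector<arma::Mat<unsigned char>> which;
  std::vector<fmat> fc_in;      // inputs to each fc layer
  std::vector<fmat> fc_act;     // post-ReLU fc activations
  std::vector<fmat> drop_mask;
};

// forward; with tape: keeps intermediates, dropout active
static fmat net_forward(const Net& net, const fmat& X, int B, Tape* tape,
                        std::mt19937* rng) {
  const Arch& a = net.arch;
  int H = a.in_h, Wd = a.in_w;
  fmat colbuf;
  fmat A;                         // local working activation (eval mode)
  const fmat* cur = &X;
  int l = 0;
  for (int blk = 0; blk < a.blocks; ++blk) {
    for (int k = 0; k < a.convs_per_block; ++k, ++l) {
      fmat Z(net.W[l].n_rows, (size_t)B * H * Wd);
      conv_fwd(net.W[l], net.b[l], *cur, B, H, Wd, Z, colbuf);
      if (tape) {
        tape->act.push_back(std::move(Z));
        cur = &tape->act.back();
      } else {
        A = std::move(Z);
        cur = &A;
      }
    }
    fmat pooled; arma::Mat<unsigned char> which;
    pool_fwd(*cur, B, H, Wd, a.max_pool, pooled, which);
    if (tape) {
      tape->pooled.push_back(std::move(pooled));
      tape->which.push_back(std::move(which));
      cur = &tape->pooled.back();
    } else {
      A = std::move(pooled);
      cur = &A;
    }
    H /= 2; Wd /= 2;
  }
  // flatten: per-sample blocks are contiguous, so this is a reshape
  fmat F(const_cast<float*>(cur->memptr()), cur->n_elem / B, B, true, true);
  for (int f = 0; f < a.fc_layers; ++f, ++l) {
    const bool last = (f == a.fc_layers - 1);
    if (tape) tape->fc_in.push_back(F);
    fmat Z = net.W[l] * F;
    Z.each_col() += net.b[l];
    if (!last) {
      relu_inplace(Z);
      if (tape) {
        tape->fc_act.push_back(Z);
        if (a.dropout > 0.0) {
          std::uniform_real_distribution<double> u(0.0, 1.0);
          fmat mask(Z.n_rows, Z.n_cols);
          const float keep = 1.0f - (float)a.dropout;
          float* mp = mask.memptr();
          for (size_t i = 0; i < mask.n_elem; ++i)
            mp[i] = (u(*rng) < keep) ? 1.0f / keep : 0.0f;
          Z %= mask;
          tape->drop_mask.push_back(std::move(mask));
        } else {
          tape->drop_mask.push_back(fmat());
        }
      }
    }
    F = std::move(Z);
  }
  return F;                       // out_dim x B
}

static void net_backward(const Net& net, Tape& tape, const fmat& X,
                         const fmat& dout, int B,
                         std::vector<fmat>& dW, std::vector<fvec>& db) {
  const Arch& a = net.arch;
  const int n_layer = net.n_conv + a.fc_layers;
  dW.resize(n_layer); db.resize(n_layer);
  fmat G = dout;                  // out x B
  for (int f = a.fc_layers - 1; f >= 0; --f) {
    const int l = net.n_conv + f;
    if (f < a.fc_layers - 1) {
      if (tape.drop_mask[f].n_elem) G %= tape.drop_mask[f];
      relu_mask(tape.fc_act[f], G);
    }
    dW[l] = G * tape.fc_in[f].t();
    db[l] = arma::sum(G, 1);
    G = net.W[l].t() * G;
  }
  // un-flatten back into the conv layout (reshape)
  int Hc = a.in_h, Wc = a.in_w;
  for (int blk = 0; blk < a.blocks; ++blk) { Hc /= 2; Wc /= 2; }
  const int c_last = a.base_channels << (a.blocks - 1);
  fmat dA(G.memptr(), c_last, (size_t)B * Hc * Wc);
  fmat colbuf, dcolbuf;
  for (int blk = a.blocks - 1; blk >= 0; --blk) {
    int Hin = a.in_h, Win = a.in_w;
    for (int j = 0; j < blk; ++j) { Hin /= 2; Win /= 2; }
    const int l_top = blk * a.convs_per_block + a.convs_per_block - 1;
    fmat dP(tape.act[l_top].n_rows, tape.act[l_top].n_cols);
    pool_bwd(dA, B, Hin, Win, a.max_pool, a.max_pool ? tape.which[blk]
                                                     : arma::Mat<unsigned char>(),
             dP);
    dA = std::move(dP);
    for (int k = a.convs_per_block - 1; k >= 0; --k) {
      const int l = blk * a.convs_per_block + k;
      relu_mask(tape.act[l], dA);
      const fmat& Ain = (l == 0) ? X
                        : (k == 0) ? tape.pooled[blk - 1]
                                   : tape.act[l - 1];
      if (l > 0) {
        fmat dprev(Ain.n_rows, Ain.n_cols);
        dprev.zeros();
        conv_bwd(net.W[l], Ain, dA, B, Hin, Win, dW[l], db[l], &dprev,
                 colbuf, dcolbuf);
        dA = std::move(dprev);
      } else {
        conv_bwd(net.W[l], Ain, dA, B, Hin, Win, dW[l], db[l], nullptr,
                 colbuf, dcolbuf);
      }
    }
  }
}

// gather selected columns of X (npix x N, double) into a 1 x (B*npix) batch
static void gather_batch(const arma::mat& X, const std::vector<int>& idx,
                         size_t from, size_t to, fmat& out) {
  const int B = to - from, npix = X.n_rows;
  out.set_size(1, (size_t)B * npix);
  float* dst = out.memptr();
  for (int b = 0; b < B; ++b) {
    const double* src = X.colptr(idx[from + b]);
    float* d = dst + (size_t)b * npix;
    for (int i = 0; i < npix; ++i) d[i] = (float)src[i];
  }
}

static double eval_loss(const Net& net, const arma::mat& X, const arma::mat& Y,
                        const std::vector<int>& idx, size_t batch) {
  double tot = 0.0; size_t n = 0;
  fmat Xb;
  for (size_t s = 0; s < idx.size(); s += batch) {
    const size_t to = std::min(idx.size(), s + batch);
    gather_batch(X, idx, s, to, Xb);
    fmat P = net_forward(net, Xb, to - s, nullptr, nullptr);
    for (size_t b = 0; b < to - s; ++b) {
      const double* y = Y.colptr(idx[s + b]);
      for (int j = 0; j < (int)P.n_rows; ++j) {
        const double e = P(j, b) - y[j];
        tot += e * e; ++n;
      }
    }
  }
  return tot / n;
}

// [[Rcpp::export]]
List fp_cnn_train(List arch, List weights0, const arma::mat& X,
                  const arma::mat& Y, IntegerVector train_idx,
                  IntegerVector val_idx, List opts) {
  Arch a = parse_arch(arch);
  Net net; net.load(weights0, a);
  const int n_layer = net.n_conv + a.fc_layers;

  const int epochs = as<int>(opts["epochs"]);
  const size_t batch = as<int>(opts["batch_size"]);
  const double lr0 = as<double>(opts["lr_initial"]);
  const int drop_every = as<int>(opts["lr_drop_every"]);
  const unsigned seed = (unsigned)as<int>(opts["seed"]);
  const bool adam = as<std::string>(opts["optimizer"]) == "adam";
  const double clip_norm = opts.containsElementNamed("clip_norm")
                             ? as<double>(opts["clip_norm"]) : 0.0;
  const float momentum = 0.9f;

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  for (auto& i : tr) --i;
  for (auto& i : va) --i;

  std::mt19937 rng(seed);
  std::vector<fmat> mW(n_layer), vW(n_layer), dW;
  std::vector<fvec> mb(n_layer), vb(n_layer), db;
  for (int l = 0; l < n_layer; ++l) {
    mW[l].zeros(net.W[l].n_rows, net.W[l].n_cols); vW[l] = mW[l];
    mb[l].zeros(net.b[l].n_elem); vb[l] = mb[l];
  }
  long step = 0;
  NumericVector hist_train(epochs), hist_val(epochs), hist_lr(epochs);
  List best_weights = net.dump();
  double best_val = R_PosInf;
  int best_epoch = 0;
  fmat Xb, Yb;

  for (int ep = 0; ep < epochs; ++ep) {
    const double lr = lr0 * std::pow(10.0, -(ep / drop_every));
    std::shuffle(tr.begin(), tr.end(), rng);
    double ep_loss = 0.0; long nb = 0;
    for (size_t s = 0; s < tr.size(); s += batch) {
      const size_t to = std::min(tr.size(), s + batch);
      const int B = to - s;
      gather_batch(X, tr, s, to, Xb);
      Yb.set_size(a.out_dim, B);
      for (int b = 0; b < B; ++b)
        for (int j = 0; j < a.out_dim; ++j)
          Yb(j, b) = (float)Y(j, tr[s + b]);
      Tape tape;
      fmat P = net_forward(net, Xb, B, &tape, &rng);
      if (!P.is_finite())
        stop("fp_cnn_train: non-finite activations at epoch %d (divergence)", ep + 1);
      fmat E = P - Yb;
      ep_loss += arma::accu(arma::square(arma::conv_to<arma::mat>::from(E))) / E.n_elem;
      ++nb;
      fmat G = E * (2.0f / (float)E.n_elem);
      net_backward(net, tape, Xb, G, B, dW, db);
      if (clip_norm > 0.0) {
        // clip the global gradient norm (stabilizes the large initial
        // learning rate of the staged schedule)
        double sq = 0.0;
        for (int l = 0; l < n_layer; ++l) {
          sq += arma::dot(dW[l], dW[l]);
          sq += arma::dot(db[l], db[l]);
        }
        const double nrm = std::sqrt(sq);
        if (nrm > clip_norm) {
          const float sc = (float)(clip_norm / nrm);
          for (int l = 0; l < n_layer; ++l) { dW[l] *= sc; db[l] *= sc; }
        }
      }
      ++step;
      for (int l = 0; l < n_layer; ++l) {
        if (adam) {
          const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
          mW[l] = b1 * mW[l] + (1 - b1) * dW[l];
          vW[l] = b2 * vW[l] + (1 - b2) * arma::square(dW[l]);
          mb[l] = b1 * mb[l] + (1 - b1) * db[l];
          vb[l] = b2 * vb[l] + (1 - b2) * arma::square(db[l]);
          const float c1 = 1.0f - std::pow(b1, (float)step);
          const float c2 = 1.0f - std::pow(b2, (float)step);
          net.W[l] -= (float)lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
          net.b[l] -= (float)lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
        } else {
          // SGD with Nesterov momentum
          mW[l] = momentum * mW[l] - (float)lr * dW[l];
          mb[l] = momentum * mb[l] - (float)lr * db[l];
          net.W[l] += momentum * mW[l] - (float)lr * dW[l];
          net.b[l] += momentum * mb[l] - (float)lr * db[l];
        }
      }
    }
    const double train_loss = ep_loss / nb;
    if (!std::isfinite(train_loss))
      stop("fp_cnn_train: loss diverged to non-finite at epoch %d", ep + 1);
    const double val_loss = va.empty() ? NA_REAL : eval_loss(net, X, Y, va, 256);
    hist_train[ep] = train_loss; hist_val[ep] = val_loss; hist_lr[ep] = lr;
    if (!va.empty() && val_loss < best_val) {
      best_val = val_loss; best_epoch = ep + 1;
      best_weights = net.dump();
    }
    Rcpp::checkUserInterrupt();
  }
  if (va.empty()) { best_weights = net.dump(); best_epoch = epochs; best_val = NA_REAL; }
  return List::create(
    _["weights"] = best_weights,
    _["final_weights"] = net.dump(),
    _["history"] = DataFrame::create(_["epoch"] = seq_len(epochs),
                                     _["lr"] = hist_lr,
                                     _["train_loss"] = hist_train,
                                     _["val_loss"] = hist_val),
    _["best_epoch"] = best_epoch,
    _["best_val_loss"] = best_val);
}

static arma::mat net_predict(const Net& net, const arma::mat& X, int batch) {
  const int N = X.n_cols;
  arma::mat out(net.arch.out_dim, N);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  fmat Xb;
  for (int s = 0; s < N; s += batch) {
    const int to = std::min(N, s + batch);
    gather_batch(X, idx, s, to, Xb);
    fmat P = net_forward(net, Xb, to - s, nullptr, nullptr);
    for (int b = 0; b < to - s; ++b)
      for (int j = 0; j < net.arch.out_dim; ++j)
        out(j, s + b) = P(j, b);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat fp_cnn_predict(List arch, List weights, const arma::mat& X,
                         int batch = 256) {
  Arch a = parse_arch(arch);
  Net net; net.load(weights, a);
  return net_predict(net, X, batch);
}

// persistent handle: avoids re-converting weights to float on every call
// [[Rcpp::export]]
SEXP fp_cnn_make(List arch, List weights) {
  Arch a = parse_arch(arch);
  XPtr<Net> p(new Net(), true);
  p->load(weights, a);
  return p;
}

// [[Rcpp::export]]
bool fp_cnn_ptr_ok(SEXP ptr) {
  if (TYPEOF(ptr) != EXTPTRSXP) return false;
  return R_ExternalPtrAddr(ptr) != nullptr;
}

// [[Rcpp::export]]
arma::mat fp_cnn_predict_ptr(SEXP ptr, const arma::mat& X, int batch = 256) {
  XPtr<Net> p(ptr);
  if (!p) stop("fp_cnn_predict_ptr: stale model handle");
  return net_predict(*p, X, batch);
}
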