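// Compact single-precision CNN backend for the truncated-VGG frame
// classifier: 3x3 same-padding convolutions via im2col + GEMM, 2x2
// max-pooling, global average pooling, dropout, dense softmax head,
// and Adam. Single-threaded and deterministic for a fixed seed.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

namespace {

struct Tensor {
  fmat W;      // parameters
  fvec b;
  fmat gW;     // accumulated gradients
  fvec gb;
  fmat mW, vW; // Adam moments
  fvec mb, vb;
};

// Activations are stored as (H*W x channels) matrices; pixel index is
// column-major (col * H + row), matching arma's matrix layout so a
// column reshapes directly to an (H x W) image.
struct ConvLayer {
  int inC = 0, outC = 0;
  Tensor par;         // W: (9*inC x outC)
  fmat XcolT;         // (H*W x 9*inC) cache
  fmat A;             // post-ReLU output (H*W x outC)
};

struct Net {
  int H = 0, Wd = 0, inC = 1, nClasses = 2;
  std::vector<int> blockFilters, blockConvs;
  std::vector<ConvLayer> convs;
  std::vector<int> poolAfter;   // conv-layer indices followed by a 2x2 pool
  Tensor dense;                 // W: (C_last x nClasses)
  float dropout = 0.5f;
  long step = 0;
  std::mt19937 rng;

  // per-forward caches
  std::vector<umat> poolArg;    // argmax source index per pooled pixel
  std::vector<fmat> poolIn;     // pre-pool activation shapes needed for bwd
  frowvec gap, dropMask;
  frowvec probs;
};

void initTensor(Tensor& t, int nr, int nc, float sd, std::mt19937& rng) {
  std::normal_distribution<float> g(0.0f, sd);
  t.W.set_size(nr, nc);
  for (uword j = 0; j < t.W.n_cols; ++j)
    for (uword i = 0; i < t.W.n_rows; ++i) t.W(i, j) = g(rng);
  t.b.zeros(nc);
  t.gW.zeros(nr, nc); t.gb.zeros(nc);
  t.mW.zeros(nr, nc); t.vW.zeros(nr, nc);
  t.mb.zeros(nc);     t.vb.zeros(nc);
}

// im2col for a 3x3 kernel with unit padding: out is (H*W x 9*inC).
void im2colT(const fmat& A, int H, int W, int inC, fmat& out) {
  out.zeros(static_cast<uword>(H) * W, 9u * inC);
  int r = 0;
  for (int c = 0; c < inC; ++c) {
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int i0 = std::max(0, -dr), i1 = std::min(H, H - dr);
        const int j0 = std::max(0, -dc), j1 = std::min(W, W - dc);
        for (int j = j0; j < j1; ++j) {
          const float* src = A.colptr(c) + static_cast<size_t>(j + dc) * H + (i0 + dr);
          float* dst = out.colptr(r) + static_cast<size_t>(j) * H + i0;
          std::memcpy(dst, src, sizeof(float) * (i1 - i0));
        }
        ++r;
      }
    }
  }
}

// adjoint of im2colT: scatter-add column gradients back onto the image
void col2imT(const fmat& dXcolT, int H, int W, int inC, fmat& dA) {
  dA.zeros(static_cast<uword>(H) * W, inC);
  int r = 0;
  for (int c = 0; c < inC; ++c) {
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int i0 = std::max(0, -dr), i1 = std::min(H, H - dr);
        const int j0 = std::max(0, -dc), j1 = std::min(W, W - dc);
        for (int j = j0; j < j1; ++j) {
          const float* src = dXcolT.colptr(r) + static_cast<size_t>(j) * H + i0;
          float* dst = dA.colptr(c) + static_cast<size_t>(j + dc) * H + (i0 + dr);
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
        ++r;
      }
    }
  }
}

void maxPool(const fmat& A, int H, int W, fmat& out, umat& arg) {
  const int Ho = H / 2, Wo = W / 2, C = A.n_cols;
  out.set_size(static_cast<uword>(Ho) * Wo, C);
  arg.set_size(static_cast<uword>(Ho) * Wo, C);
  for (int c = 0; c < C; ++c) {
    const float* a = A.colptr(c);
    float* o = out.colptr(c);
    uword* g = arg.colptr(c);
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int i = 2 * io, j = 2 * jo;
        uword idx[4] = {static_cast<uword>(j) * H + i,
                        static_cast<uword>(j) * H + i + 1,
                        static_cast<uword>(j + 1) * H + i,
                        static_cast<uword>(j + 1) * H + i + 1};
        uword best = idx[0];
        float v = a[idx[0]];
        for (int k = 1; k < 4; ++k) if (a[idx[k]] > v) { v = a[idx[k]]; best = idx[k]; }
        o[static_cast<size_t>(jo) * Ho + io] = v;
        g[static_cast<size_t>(jo) * Ho + io] = best;
      }
    }
  }
}

struct Dims { int H, W; };

// forward one frame; caches everything needed for backward when train=true
frowvec forwardOne(Net& net, const fmat& frame, bool train, bool cacheBlock) {
  (void)cacheBlock;
  fmat A = frame;               // (H*W x inC) with inC columns
  Dims d{net.H, net.Wd};
  const size_t nPool = net.poolAfter.size();
  net.poolArg.resize(nPool);
  net.poolIn.resize(nPool);
  size_t p = 0;
  for (size_t l = 0; l < net.convs.size(); ++l) {
    ConvLayer& L = net.convs[l];
    im2colT(A, d.H, d.W, L.inC, L.XcolT);
    L.A = L.XcolT * L.par.W;          // (H*W x outC)
    L.A.each_row() += L.par.b.t();
    L.A.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    if (p < nPool && net.poolAfter[p] == static_cast<int>(l)) {
      fmat pooled;
      maxPool(L.A, d.H, d.W, pooled, net.poolArg[p]);
      net.poolIn[p] = L.A;            // keep pre-pool activation for bwd shape
      A = pooled;
      d.H /= 2; d.W /= 2;
      ++p;
    } else {
      A = L.A;
    }
  }
  net.gap = mean(A, 0);               // (1 x C_last)
  frowvec h = net.gap;
  if (train && net.dropout > 0.0f) {
    std::uniform_real_distribution<float> u(0.0f, 1.0f);
    net.dropMask.set_size(h.n_elem);
    const float keep = 1.0f - net.dropout;
    for (uword k = 0; k < h.n_elem; ++k)
      net.dropMask(k) = (u(net.rng) < keep) ? 1.0f / keep : 0.0f;
    h %= net.dropMask;
  } else {
    net.dropMask.ones(h.n_elem);
  }
  frowvec logits = h * net.dense.W + net.dense.b.t();
  logits -= logits.max();
  frowvec e = exp(logits);
  net.probs = e / accu(e);
  return net.probs;
}

// backward one frame; accumulates gradients (scaled by `scale`) into .g*
void backwardOne(Net& net, int y, float w, float scale) {
  frowvec dlog = net.probs;
  dlog(y) -= 1.0f;
  dlog *= w * scale;
  frowvec h = net.gap % net.dropMask;
  net.dense.gW += h.t() * dlog;
  net.dense.gb += dlog.t();
  frowvec dh = dlog * net.dense.W.t();
  dh %= net.dropMask;

  // back through GAP into the last conv activation
  const ConvLayer& last = net.convs.back();
  const uword HW = last.A.n_rows;
  fmat dA(HW, last.outC);
  for (int c = 0; c < last.outC; ++c)
    dA.col(c).fill(dh(c) / static_cast<float>(HW));

  Dims d{net.H, net.Wd};
  std::vector<Dims> dimAt(net.convs.size());
  size_t p = 0;
  for (size_t l = 0; l < net.convs.size(); ++l) {
    dimAt[l] = d;
    if (p < net.poolAfter.size() && net.poolAfter[p] == static_cast<int>(l)) {
      d.H /= 2; d.W /= 2; ++p;
    }
  }

  p = net.poolAfter.size();
  for (int l = static_cast<int>(net.convs.size()) - 1; l >= 0; --l) {
    ConvLayer& L = net.convs[l];
    const bool pooledHere = p > 0 && net.poolAfter[p - 1] == l;
    if (pooledHere) {
      --p;
      const fmat& preA = net.poolIn[p];
      fmat up(preA.n_rows, preA.n_cols, fill::zeros);
      const umat& arg = net.poolArg[p];
      for (uword c = 0; c < up.n_cols; ++c) {
        const uword* g = arg.colptr(c);
        const float* s = dA.colptr(c);
        float* u = up.colptr(c);
        for (uword k = 0; k < arg.n_rows; ++k) u[g[k]] += s[k];
      }
      dA = std::move(up);
    }
    // ReLU gate
    dA %= conv_to<fmat>::from(L.A > 0.0f);
    L.par.gW += L.XcolT.t() * dA;
    L.par.gb += sum(dA, 0).t();
    if (l > 0) {
      fmat dXcolT = dA * L.par.W.t();
      fmat dPrev;
      col2imT(dXcolT, dimAt[l].H, dimAt[l].W, L.inC, dPrev);
      dA = std::move(dPrev);
    }
  }
}

void adamStep(Tensor& t, float lr, long step) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  const float c1 = 1.0f - std::pow(b1, static_cast<float>(step));
  const float c2 = 1.0f - std::pow(b2, static_cast<float>(step));
  t.mW = b1 * t.mW + (1.0f - b1) * t.gW;
  t.vW = b2 * t.vW + (1.0f - b2) * square(t.gW);
  t.W -= lr * (t.mW / c1) / (sqrt(t.vW / c2) + eps);
  t.mb = b1 * t.mb + (1.0f - b1) * t.gb;
  t.vb = b2 * t.vb + (1.0f - b2) * square(t.gb);
  t.b -= lr * (t.mb / c1) / (sqrt(t.vb / c2) + eps);
  t.gW.zeros(); t.gb.zeros();
}

fmat frameToMat(const Rcpp::NumericMatrix& x) {
  fmat f(x.nrow() * x.ncol(), 1);
  std::copy(x.begin(), x.end(), f.colptr(0));
  return f;
}

Net* getNet(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  return p.get();
}

} // namespace

// [[Rcpp::export(name = ".cnn_create")]]
SEXP cnn_create(int height, int width, int in_channels,
                Rcpp::IntegerVector block_filters,
                Rcpp::IntegerVector block_convs,
                int n_classes, double dropout, int seed) {
  if (height % 4 != 0 || width % 4 != 0)
    Rcpp::stop("input dimensions must be divisible by 4 (two 2x2 pooling stages)");
  Rcpp::XPtr<Net> ptr(new Net(), true);
  Net& net = *ptr;
  net.H = height; net.Wd = width; net.inC = in_channels;
  net.nClasses = n_classes;
  net.dropout = static_cast<float>(dropout);
  net.rng.seed(static_cast<unsigned>(seed));
  int inC = in_channels, li = 0;
  for (int b = 0; b < block_filters.size(); ++b) {
    for (int k = 0; k < block_convs[b]; ++k) {
      ConvLayer L;
      L.inC = inC; L.outC = block_filters[b];
      const float sd = std::sqrt(2.0f / (9.0f * inC)); // He init
      initTensor(L.par, 9 * inC, L.outC, sd, net.rng);
      net.convs.push_back(std::move(L));
      inC = block_filters[b];
      ++li;
    }
    if (b < block_filters.size() - 1) net.poolAfter.push_back(li - 1);
  }
  const float sdd = std::sqrt(2.0f / inC);
  initTensor(net.dense, inC, n_classes, sdd, net.rng);
  return ptr;
}

// [[Rcpp::export(name = ".cnn_is_valid")]]
bool cnn_is_valid(SEXP ptr) {
  if (TYPEOF(ptr) != EXTPTRSXP) return false;
  Rcpp::XPtr<Net> p(ptr);
  return p.get() != nullptr;
}

// [[Rcpp::export(name = ".cnn_num_params")]]
double cnn_num_params(SEXP ptr) {
  Net& net = *getNet(ptr);
  double n = 0;
  for (auto& L : net.convs) n += L.par.W.n_elem + L.par.b.n_elem;
  n += net.dense.W.n_elem + net.dense.b.n_elem;
  return n;
}

// [[Rcpp::export(name = ".cnn_get_weights")]]
Rcpp::List cnn_get_weights(SEXP ptr) {
  Net& net = *getNet(ptr);
  Rcpp::List out;
  for (size_t l = 0; l < net.convs.size(); ++l) {
    Tensor& t = net.convs[l].par;
    out.push_back(Rcpp::List::create(
        Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(t.W)),
        Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(t.b))));
  }
  out.push_back(Rcpp::List::create(
      Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(net.dense.W)),
      Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(net.dense.b))));
  return out;
}

// [[Rcpp::export(name = ".cnn_set_weights")]]
void cnn_set_weights(SEXP ptr, Rcpp::List weights) {
  Net& net = *getNet(ptr);
  if (static_cast<size_t>(weights.size()) != net.convs.size() + 1)
    Rcpp::stop("weight list length does not match the architecture");
  for (size_t l = 0; l < net.convs.size(); ++l) {
    Rcpp::List wl = weights[l];
    Tensor& t = net.convs[l].par;
    fmat W = conv_to<fmat>::from(Rcpp::as<mat>(wl["W"]));
    fvec b = conv_to<fvec>::from(Rcpp::as<vec>(wl["b"]));
    if (W.n_rows != t.W.n_rows || W.n_cols != t.W.n_cols)
      Rcpp::stop("conv weight shape mismatch at layer %d", static_cast<int>(l) + 1);
    t.W = W; t.b = b;
    t.mW.zeros(); t.vW.zeros(); t.mb.zeros(); t.vb.zeros();
    t.gW.zeros(); t.gb.zeros();
  }
  Rcpp::List dl = weights[net.convs.size()];
  net.dense.W = conv_to<fmat>::from(Rcpp::as<mat>(dl["W"]));
  net.dense.b = conv_to<fvec>::from(Rcpp::as<vec>(dl["b"]));
  net.dense.mW.zeros(); net.dense.vW.zeros();
  net.dense.mb.zeros(); net.dense.vb.zeros();
  net.dense.gW.zeros(); net.dense.gb.zeros();
  net.step = 0;
}

// [[Rcpp::export(name = ".cnn_forward")]]
Rcpp::NumericMatrix cnn_forward(SEXP ptr, Rcpp::NumericVector frames) {
  Net& net = *getNet(ptr);
  Rcpp::IntegerVector dims = frames.attr("dim");
  if (dims.size() != 3 || dims[0] != net.H || dims[1] != net.Wd)
    Rcpp::stop("frames must be an H x W x N array matching the model input shape");
  const int N = dims[2];
  const size_t HW = static_cast<size_t>(net.H) * net.Wd;
  Rcpp::NumericMatrix out(N, net.nClasses);
  fmat frame(HW, 1);
  for (int i = 0; i < N; ++i) {
    std::copy(frames.begin() + i * HW, frames.begin() + (i + 1) * HW,
              frame.colptr(0));
    frowvec p = forwardOne(net, frame, false, false);
    for (int c = 0; c < net.nClasses; ++c) out(i, c) = p(c);
  }
  return out;
}

// [[Rcpp::export(name = ".cnn_block_activations")]]
Rcpp::NumericVector cnn_block_activations(SEXP ptr, Rcpp::NumericMatrix frame) {
  Net& net = *getNet(ptr);
  if (frame.nrow() != net.H || frame.ncol() != net.Wd)
    Rcpp::stop("frame does not match the model input shape");
  fmat f = frameToMat(frame);
  forwardOne(net, f, false, true);
  const ConvLayer& last = net.convs.back();
  const int ds = 1 << net.poolAfter.size();
  const int Ho = net.H / ds, Wo = net.Wd / ds;
  Rcpp::NumericVector out(static_cast<R_xlen_t>(last.A.n_elem));
  std::copy(last.A.begin(), last.A.end(), out.begin());
  out.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, last.outC);
  return out;
}

// [[Rcpp::export(name = ".cnn_loss_grad")]]
Rcpp::List cnn_loss_grad(SEXP ptr, Rcpp::NumericMatrix frame, int y,
                         double weight) {
  Net& net = *getNet(ptr);
  for (auto& L : net.convs) { L.par.gW.zeros(); L.par.gb.zeros(); }
  net.dense.gW.zeros(); net.dense.gb.zeros();
  fmat f = frameToMat(frame);
  const float keep = net.dropout;
  net.dropout = 0.0f; // exact gradients, no stochastic mask
  frowvec p = forwardOne(net, f, true, false);
  backwardOne(net, y, static_cast<float>(weight), 1.0f);
  net.dropout = keep;
  const double loss = -weight * std::log(std::max(p(y), 1e-12f));
  Rcpp::List grads;
  for (auto& L : net.convs) {
    grads.push_back(Rcpp::List::create(
        Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(L.par.gW)),
        Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(L.par.gb))));
    L.par.gW.zeros(); L.par.gb.zeros();
  }
  grads.push_back(Rcpp::List::create(
      Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(net.dense.gW)),
      Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(net.dense.gb))));
  net.dense.gW.zeros(); net.dense.gb.zeros();
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}

// [[Rcpp::export(name = ".cnn_train_batch")]]
double cnn_train_batch(SEXP ptr, Rcpp::NumericVector frames,
                       Rcpp::IntegerVector y, Rcpp::NumericVector class_weights,
                       double lr) {
  Net& net = *getNet(ptr);
  Rcpp::IntegerVector dims = frames.attr("dim");
  if (dims.size() != 3 || dims[0] != net.H || dims[1] != net.Wd)
    Rcpp::stop("frames must be an H x W x N array matching the model input shape");
  const int N = dims[2];
  if (y.size() != N) Rcpp::stop("label length mismatch");
  const size_t HW = static_cast<size_t>(net.H) * net.Wd;
  fmat frame(HW, 1);
  double loss = 0.0;
  const float scale = 1.0f / N;
  for (int i = 0; i < N; ++i) {
    std::copy(frames.begin() + i * HW, frames.begin() + (i + 1) * HW,
              frame.colptr(0));
    frowvec p = forwardOne(net, frame, true, false);
    const int yi = y[i];
    const float w = static_cast<float>(class_weights[yi]);
    loss += -w * std::log(std::max(p(yi), 1e-12f)) / N;
    backwardOne(net, yi, w, scale);
  }
  ++net.step;
  const float flr = static_cast<float>(lr);
  for (auto& L : net.convs) adamStep(L.par, flr, net.step);
  adamStep(net.dense, flr, net.step);
  return loss;
}
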