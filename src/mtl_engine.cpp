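// Multi-task U-Net engine: shared contracting path, segmentation decoder with
// skip connections, classification head off the bottleneck. Forward and
// backward passes are hand-rolled as im2col + GEMM in single precision; the
// BLAS does the heavy lifting. Activation layout: C x (H*W*N) with pixel
// index p = row + col*H (column-major, matching R arrays); sample n occupies
// the column block [n*HW, (n+1)*HW).
//
// Weight conventions (all matrices column-major):
//   3x3 conv:   W is Cout x (9*Cin), input index k = o*Cin + ci with
//               offset o = (dy+1)*3 + (dx+1), dy outer; bias length Cout.
//   2x2 tconv:  W is Cout x (4*Cin), offset o = dy*2 + dx, dy,dx in {0,1}.
//   1x1 conv:   W is Cout x Cin.
//   dense:      W is out x in.

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;
using arma::uword;

static fmat as_fmat(SEXP s) {
  NumericMatrix m(s);
  fmat out(m.nrow(), m.ncol());
  const double *src = m.begin();
  float *dst = out.memptr();
  const size_t n = out.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
  return out;
}

static fvec as_fvec(SEXP s) {
  NumericVector v(s);
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = static_cast<float>(v[i]);
  return out;
}

static NumericMatrix to_rmat(const fmat &m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  const float *src = m.memptr();
  double *dst = out.begin();
  const size_t n = m.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<double>(src[i]);
  return out;
}

static NumericVector to_rvec(const fvec &v) {
  NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = static_cast<double>(v[i]);
  return out;
}

struct LayerW {
  fmat W;
  fvec b;
};

static LayerW get_layer(const List &weights, const std::string &nm) {
  if (!weights.containsElementNamed(nm.c_str()))
    stop("missing weight entry '%s'", nm.c_str());
  List l = weights[nm];
  LayerW out;
  out.W = as_fmat(l["W"]);
  out.b = as_fvec(l["b"]);
  return out;
}

static void relu_(fmat &a) {
  float *p = a.memptr();
  const size_t n = a.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (p[i] < 0.0f) p[i] = 0.0f;
}

// zero grad entries where the post-ReLU activation is zero
static void relu_mask_(fmat &g, const fmat &act) {
  float *p = g.memptr();
  const float *a = act.memptr();
  const size_t n = g.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (a[i] <= 0.0f) p[i] = 0.0f;
}

// 3x3 same-padding im2col: X (C x HW*N) -> col (9C x HW*N)
static fmat im2col3(const fmat &X, int H, int W, int N) {
  const int C = X.n_rows, HW = H * W;
  fmat col(9 * C, (size_t)HW * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const int base = n * HW;
    int o = 0;
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        const int rb = o * C;
        const int c0 = std::max(0, -dx), c1 = W - 1 - std::max(0, dx);
        const int r0 = std::max(0, -dy), r1 = H - 1 - std::max(0, dy);
        if (c1 < c0 || r1 < r0) continue;
        for (int c = c0; c <= c1; ++c) {
          const int dp = base + r0 + c * H;
          const int sp = base + (r0 + dy) + (c + dx) * H;
          col.submat(rb, dp, rb + C - 1, dp + (r1 - r0)) =
              X.cols(sp, sp + (r1 - r0));
        }
      }
    }
  }
  return col;
}

// adjoint of im2col3: dcol (9C x HW*N) -> dX (C x HW*N)
static fmat col2im3(const fmat &dcol, int C, int H, int W, int N) {
  const int HW = H * W;
  fmat dX(C, (size_t)HW * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const int base = n * HW;
    int o = 0;
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        const int rb = o * C;
        const int c0 = std::max(0, -dx), c1 = W - 1 - std::max(0, dx);
        const int r0 = std::max(0, -dy), r1 = H - 1 - std::max(0, dy);
        if (c1 < c0 || r1 < r0) continue;
        for (int c = c0; c <= c1; ++c) {
          const int dp = base + r0 + c * H;
          const int sp = base + (r0 + dy) + (c + dx) * H;
          dX.cols(sp, sp + (r1 - r0)) +=
              dcol.submat(rb, dp, rb + C - 1, dp + (r1 - r0));
        }
      }
    }
  }
  return dX;
}

static fmat conv_fwd(const LayerW &w, const fmat &col) {
  fmat y = w.W * col;
  y.each_col() += w.b;
  return y;
}

// 2x2 max pooling; idx records the winning source column per (channel, out pixel)
static void maxpool2(const fmat &X, int H, int W, int N, fmat &Y, umat &idx) {
  const int C = X.n_rows, Ho = H / 2, Wo = W / 2, HWo = Ho * Wo, HW = H * W;
  Y.set_size(C, (size_t)HWo * N);
  idx.set_size(C, (size_t)HWo * N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        const uword dp = (uword)n * HWo + ro + co * Ho;
        const int s00 = n * HW + (2 * ro) + (2 * co) * H;
        const int cand[4] = {s00, s00 + 1, s00 + H, s00 + H + 1};
        for (int ch = 0; ch < C; ++ch) {
          float best = X(ch, cand[0]);
          int bi = cand[0];
          for (int k = 1; k < 4; ++k) {
            const float v = X(ch, cand[k]);
            if (v > best) { best = v; bi = cand[k]; }
          }
          Y(ch, dp) = best;
          idx(ch, dp) = (uword)bi;
        }
      }
    }
  }
}

static fmat maxpool2_bwd(const fmat &dY, const umat &idx, int C, int HW, int N) {
  fmat dX(C, (size_t)HW * N, arma::fill::zeros);
  for (uword j = 0; j < dY.n_cols; ++j)
    for (int ch = 0; ch < C; ++ch)
      dX(ch, idx(ch, j)) += dY(ch, j);
  return dX;
}

// 2x2 stride-2 transposed convolution: X (Cin x HW*N) -> Y (Cout x 4HW*N)
static fmat tconv2_fwd(const LayerW &w, const fmat &X, int H, int W, int N) {
  const int Cin = X.n_rows, Cout = w.W.n_rows;
  const int Ho = 2 * H, Wo = 2 * W, HW = H * W, HWo = Ho * Wo;
  fmat Y(Cout, (size_t)HWo * N);
  Y.each_col() = w.b;
  for (int o = 0; o < 4; ++o) {
    const int dy = o / 2, dx = o % 2;
    fmat Yo = w.W.cols(o * Cin, (o + 1) * Cin - 1) * X;  // Cout x HW*N
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          const uword sp = (uword)n * HW + r + c * H;
          const uword dp = (uword)n * HWo + (2 * r + dy) + (2 * c + dx) * Ho;
          Y.col(dp) += Yo.col(sp);
        }
      }
    }
  }
  return Y;
}

// returns dX; accumulates dW, db
static fmat tconv2_bwd(const LayerW &w, const fmat &X, const fmat &dY,
                       int H, int W, int N, fmat &dW, fvec &db) {
  const int Cin = X.n_rows, Cout = w.W.n_rows;
  const int Ho = 2 * H, Wo = 2 * W, HW = H * W, HWo = Ho * Wo;
  fmat dX(Cin, (size_t)HW * N, arma::fill::zeros);
  db += arma::sum(dY, 1);
  for (int o = 0; o < 4; ++o) {
    const int dy = o / 2, dx = o % 2;
    fmat dYo(Cout, (size_t)HW * N);
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          const uword sp = (uword)n * HW + r + c * H;
          const uword dp = (uword)n * HWo + (2 * r + dy) + (2 * c + dx) * Ho;
          dYo.col(sp) = dY.col(dp);
        }
      }
    }
    dW.cols(o * Cin, (o + 1) * Cin - 1) += dYo * X.t();
    dX += w.W.cols(o * Cin, (o + 1) * Cin - 1).t() * dYo;
  }
  return dX;
}

struct NetCfg {
  int size, depth, base, mult, in_ch, hidden;
  std::vector<int> ch;  // encoder channels per level, 1..depth
  int cb;               // bottleneck channels
};

static NetCfg parse_cfg(const List &cfg) {
  NetCfg c;
  c.size = as<int>(cfg["input_size"]);
  c.depth = as<int>(cfg["depth"]);
  c.base = as<int>(cfg["base_channels"]);
  c.mult = as<int>(cfg["channel_multiplier"]);
  c.in_ch = as<int>(cfg["in_channels"]);
  c.hidden = as<int>(cfg["hidden_units"]);
  int ch = c.base;
  for (int l = 0; l < c.depth; ++l) {
    c.ch.push_back(ch);
    ch *= c.mult;
  }
  c.cb = ch;
  return c;
}

struct ForwardState {
  // encoder
  std::vector<fmat> col1, col2, a1, a2;  // per level
  std::vector<umat> pidx;
  // bottleneck
  fmat bcol1, bcol2, ba1, ba2;
  // decoder, indexed by level (1-based -> index l-1)
  std::vector<fmat> up_in, dcol1, dcol2, da1, da2;
  // heads
  fmat seg_sig;  // 1 x HW*N
  fmat gap, h1, clsp;
  int H_top, N;
};

static void forward_pass(const List &weights, const NetCfg &c, const fmat &input,
                         int N, ForwardState &st, bool keep_cols) {
  const int S = c.size;
  st.N = N;
  st.H_top = S;
  st.col1.resize(c.depth); st.col2.resize(c.depth);
  st.a1.resize(c.depth); st.a2.resize(c.depth);
  st.pidx.resize(c.depth);
  st.up_in.resize(c.depth); st.dcol1.resize(c.depth); st.dcol2.resize(c.depth);
  st.da1.resize(c.depth); st.da2.resize(c.depth);

  fmat A = input;
  int H = S;
  for (int l = 0; l < c.depth; ++l) {
    char nm[32];
    snprintf(nm, sizeof(nm), "enc%d_conv1", l + 1);
    LayerW w1 = get_layer(weights, nm);
    snprintf(nm, sizeof(nm), "enc%d_conv2", l + 1);
    LayerW w2 = get_layer(weights, nm);
    fmat col = im2col3(A, H, H, N);
    fmat a1 = conv_fwd(w1, col);
    relu_(a1);
    if (keep_cols) st.col1[l] = std::move(col);
    fmat col2 = im2col3(a1, H, H, N);
    fmat a2 = conv_fwd(w2, col2);
    relu_(a2);
    if (keep_cols) st.col2[l] = std::move(col2);
    st.a1[l] = std::move(a1);
    umat idx;
    fmat P;
    maxpool2(a2, H, H, N, P, idx);
    st.a2[l] = std::move(a2);
    st.pidx[l] = std::move(idx);
    A = std::move(P);
    H /= 2;
  }
  {
    LayerW w1 = get_layer(weights, "bott_conv1");
    LayerW w2 = get_layer(weights, "bott_conv2");
    fmat col = im2col3(A, H, H, N);
    fmat a1 = conv_fwd(w1, col);
    relu_(a1);
    if (keep_cols) st.bcol1 = std::move(col);
    fmat col2 = im2col3(a1, H, H, N);
    fmat a2 = conv_fwd(w2, col2);
    relu_(a2);
    if (keep_cols) st.bcol2 = std::move(col2);
    st.ba1 = std::move(a1);
    st.ba2 = a2;
    A = std::move(a2);
  }
  // classification head off the bottleneck: global average pooling
  {
    const int HWb = H * H;
    fmat gap(c.cb, N);
    for (int n = 0; n < N; ++n)
      gap.col(n) = arma::mean(st.ba2.cols((uword)n * HWb, (uword)(n + 1) * HWb - 1), 1);
    LayerW f1 = get_layer(weights, "cls_fc1");
    LayerW f2 = get_layer(weights, "cls_fc2");
    fmat h1 = f1.W * gap;
    h1.each_col() += f1.b;
    relu_(h1);
    fmat z2 = f2.W * h1;
    z2.each_col() += f2.b;
    // column-wise stable softmax
    fmat p = z2;
    for (int n = 0; n < N; ++n) {
      fvec col = p.col(n);
      col -= col.max();
      col = arma::exp(col);
      p.col(n) = col / arma::accu(col);
    }
    st.gap = std::move(gap);
    st.h1 = std::move(h1);
    st.clsp = std::move(p);
  }
  // decoder
  for (int l = c.depth; l >= 1; --l) {
    char nm[32];
    snprintf(nm, sizeof(nm), "up%d", l);
    LayerW wu = get_layer(weights, nm);
    snprintf(nm, sizeof(nm), "dec%d_conv1", l);
    LayerW w1 = get_layer(weights, nm);
    snprintf(nm, sizeof(nm), "dec%d_conv2", l);
    LayerW w2 = get_layer(weights, nm);
    st.up_in[l - 1] = A;
    fmat U = tconv2_fwd(wu, A, H, H, N);
    H *= 2;
    fmat cat = arma::join_cols(U, st.a2[l - 1]);
    fmat col = im2col3(cat, H, H, N);
    fmat d1 = conv_fwd(w1, col);
    relu_(d1);
    if (keep_cols) st.dcol1[l - 1] = std::move(col);
    fmat col2 = im2col3(d1, H, H, N);
    fmat d2 = conv_fwd(w2, col2);
    relu_(d2);
    if (keep_cols) st.dcol2[l - 1] = std::move(col2);
    st.da1[l - 1] = std::move(d1);
    st.da2[l - 1] = d2;
    A = std::move(d2);
  }
  // segmentation head: 1x1 conv + sigmoid
  {
    LayerW ws = get_layer(weights, "seg_out");
    fmat z = ws.W * A;
    z.each_col() += ws.b;
    fmat sig = z;
    float *p = sig.memptr();
    for (size_t i = 0; i < sig.n_elem; ++i)
      p[i] = 1.0f / (1.0f + std::exp(-p[i]));
    st.seg_sig = std::move(sig);
  }
}

// [[Rcpp::export]]
List eng_forward(List weights, List cfg, NumericVector x) {
  NetCfg c = parse_cfg(cfg);
  IntegerVector dims = x.attr("dim");
  if (dims.size() < 3) stop("input must be an H x W x C (x N) array");
  const int H = dims[0], W = dims[1], Cin = dims[2];
  const int N = dims.size() == 4 ? dims[3] : 1;
  if (H != c.size || W != c.size) stop("input spatial dims do not match config");
  if (Cin != c.in_ch) stop("input channel count does not match config");
  const int HW = H * W;
  fmat input(c.in_ch, (size_t)HW * N);
  const double *xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int ch = 0; ch < Cin; ++ch)
      for (int p = 0; p < HW; ++p)
        input(ch, (uword)n * HW + p) =
            (float)xp[p + (size_t)ch * HW + (size_t)n * HW * Cin];
  ForwardState st;
  forward_pass(weights, c, input, N, st, false);
  NumericVector seg((size_t)HW * N);
  for (size_t i = 0; i < (size_t)HW * N; ++i) seg[i] = st.seg_sig[i];
  seg.attr("dim") = IntegerVector::create(H, W, N);
  return List::create(_["seg"] = seg, _["cls"] = to_rmat(st.clsp));
}

// [[Rcpp::export]]
List eng_train_batch(List weights, List cfg, NumericVector x, NumericVector mask,
                     IntegerVector label, double eps) {
  NetCfg c = parse_cfg(cfg);
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], Cin = dims[2];
  const int N = dims.size() == 4 ? dims[3] : 1;
  if (H != c.size) stop("input spatial dims do not match config");
  const int HW = H * H;
  fmat input(c.in_ch, (size_t)HW * N);
  const double *xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int ch = 0; ch < Cin; ++ch)
      for (int p = 0; p < HW; ++p)
        input(ch, (uword)n * HW + p) =
            (float)xp[p + (size_t)ch * HW + (size_t)n * HW * Cin];

  ForwardState st;
  forward_pass(weights, c, input, N, st, true);

  // ---- losses (double accumulation, clamped probabilities) ----
  const double *mp = mask.begin();
  double seg_loss = 0.0;
  for (int n = 0; n < N; ++n) {
    for (int p = 0; p < HW; ++p) {
      double pr = (double)st.seg_sig(0, (uword)n * HW + p);
      pr = std::min(std::max(pr, eps), 1.0 - eps);
      const double m = mp[p + (size_t)n * HW];
      seg_loss -= m * std::log(pr) + (1.0 - m) * std::log(1.0 - pr);
    }
  }
  seg_loss /= (double)HW * N;
  double cls_loss = 0.0;
  for (int n = 0; n < N; ++n) {
    double pt = (double)st.clsp(label[n], n);
    pt = std::min(std::max(pt, eps), 1.0 - eps);
    cls_loss -= std::log(pt);
  }
  cls_loss /= (double)N;

  // ---- gradient containers ----
  std::vector<std::string> names;
  for (int l = 1; l <= c.depth; ++l) {
    names.push_back("enc" + std::to_string(l) + "_conv1");
    names.push_back("enc" + std::to_string(l) + "_conv2");
  }
  names.push_back("bott_conv1");
  names.push_back("bott_conv2");
  for (int l = c.depth; l >= 1; --l) {
    names.push_back("up" + std::to_string(l));
    names.push_back("dec" + std::to_string(l) + "_conv1");
    names.push_back("dec" + std::to_string(l) + "_conv2");
  }
  names.push_back("seg_out");
  names.push_back("cls_fc1");
  names.push_back("cls_fc2");
  std::map<std::string, LayerW> W;
  std::map<std::string, fmat> dW;
  std::map<std::string, fvec> db;
  for (const auto &nm : names) {
    W[nm] = get_layer(weights, nm);
    dW[nm] = fmat(W[nm].W.n_rows, W[nm].W.n_cols, arma::fill::zeros);
    db[nm] = fvec(W[nm].b.n_elem, arma::fill::zeros);
  }

  // ---- classification head backward ----
  const int Hb = c.size >> c.depth;
  const int HWb = Hb * Hb;
  fmat dz2 = st.clsp;
  for (int n = 0; n < N; ++n) dz2(label[n], n) -= 1.0f;
  dz2 /= (float)N;
  dW["cls_fc2"] += dz2 * st.h1.t();
  db["cls_fc2"] += arma::sum(dz2, 1);
  fmat dh1 = W["cls_fc2"].W.t() * dz2;
  relu_mask_(dh1, st.h1);
  dW["cls_fc1"] += dh1 * st.gap.t();
  db["cls_fc1"] += arma::sum(dh1, 1);
  fmat dgap = W["cls_fc1"].W.t() * dh1;  // cb x N
  fmat dBott_cls(c.cb, (size_t)HWb * N);
  for (int n = 0; n < N; ++n) {
    fvec g = dgap.col(n) / (float)HWb;
    for (int p = 0; p < HWb; ++p) dBott_cls.col((uword)n * HWb + p) = g;
  }

  // ---- segmentation head backward ----
  fmat dzseg(1, (size_t)HW * N);
  {
    const float scale = 1.0f / ((float)HW * N);
    for (int n = 0; n < N; ++n)
      for (int p = 0; p < HW; ++p) {
        const uword j = (uword)n * HW + p;
        dzseg(0, j) = (st.seg_sig(0, j) - (float)mp[p + (size_t)n * HW]) * scale;
      }
  }
  dW["seg_out"] += dzseg * st.da2[0].t();
  db["seg_out"] += arma::sum(dzseg, 1);
  fmat dD = W["seg_out"].W.t() * dzseg;  // ch[0] x HW*N

  // ---- decoder backward (levels 1 .. depth) ----
  std::vector<fmat> dskip(c.depth);
  int Hl = c.size;
  for (int l = 1; l <= c.depth; ++l) {
    const std::string n1 = "dec" + std::to_string(l) + "_conv1";
    const std::string n2 = "dec" + std::to_string(l) + "_conv2";
    const std::string nu = "up" + std::to_string(l);
    const int cl = c.ch[l - 1];
    fmat dz2m = dD;
    relu_mask_(dz2m, st.da2[l - 1]);
    dW[n2] += dz2m * st.dcol2[l - 1].t();
    db[n2] += arma::sum(dz2m, 1);
    fmat dd1 = col2im3(W[n2].W.t() * dz2m, cl, Hl, Hl, N);
    relu_mask_(dd1, st.da1[l - 1]);
    dW[n1] += dd1 * st.dcol1[l - 1].t();
    db[n1] += arma::sum(dd1, 1);
    fmat dcat = col2im3(W[n1].W.t() * dd1, 2 * cl, Hl, Hl, N);
    fmat dU = dcat.rows(0, cl - 1);
    dskip[l - 1] = dcat.rows(cl, 2 * cl - 1);
    dD = tconv2_bwd(W[nu], st.up_in[l - 1], dU, Hl / 2, Hl / 2, N,
                    dW[nu], db[nu]);
    Hl /= 2;
  }
  // Hl is now the bottleneck resolution; dD is the bottleneck output grad
  fmat dB = dD + dBott_cls;

  // ---- bottleneck backward ----
  {
    fmat dz2m = dB;
    relu_mask_(dz2m, st.ba2);
    dW["bott_conv2"] += dz2m * st.bcol2.t();
    db["bott_conv2"] += arma::sum(dz2m, 1);
    fmat da1 = col2im3(W["bott_conv2"].W.t() * dz2m,
                       st.ba1.n_rows, Hl, Hl, N);
    relu_mask_(da1, st.ba1);
    dW["bott_conv1"] += da1 * st.bcol1.t();
    db["bott_conv1"] += arma::sum(da1, 1);
    dB = col2im3(W["bott_conv1"].W.t() * da1, c.ch[c.depth - 1], Hl, Hl, N);
  }

  // ---- encoder backward (levels depth .. 1) ----
  for (int l = c.depth; l >= 1; --l) {
    const std::string n1 = "enc" + std::to_string(l) + "_conv1";
    const std::string n2 = "enc" + std::to_string(l) + "_conv2";
    const int cl = c.ch[l - 1];
    const int Hcur = Hl * 2;  // resolution of this level's activations
    fmat dA2 = maxpool2_bwd(dB, st.pidx[l - 1], cl, Hcur * Hcur, N);
    dA2 += dskip[l - 1];
    relu_mask_(dA2, st.a2[l - 1]);
    dW[n2] += dA2 * st.col2[l - 1].t();
    db[n2] += arma::sum(dA2, 1);
    fmat da1 = col2im3(W[n2].W.t() * dA2, cl, Hcur, Hcur, N);
    relu_mask_(da1, st.a1[l - 1]);
    dW[n1] += da1 * st.col1[l - 1].t();
    db[n1] += arma::sum(da1, 1);
    if (l > 1) {
      dB = col2im3(W[n1].W.t() * da1, c.ch[l - 2], Hcur, Hcur, N);
    }
    Hl = Hcur;
  }

  List grads;
  for (const auto &nm : names)
    grads[nm] = List::create(_["W"] = to_rmat(dW[nm]), _["b"] = to_rvec(db[nm]));
  return List::create(_["seg_loss"] = seg_loss, _["cls_loss"] = cls_loss,
                      _["total"] = seg_loss + cls_loss, _["grads"] = grads);
}
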