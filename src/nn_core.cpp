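// Compiled backend for the dual-stream attention regressor and the
// sequence baselines: hand-written forward/backward passes over
// single-precision Armadillo matrices, AdamW optimization, and a full
// training loop with early stopping on validation MAE.
//
// Layout conventions:
//   * sequence activations are (B*T) x C matrices, row index = b*T + t
//   * per-sample attention operates on contiguous T x C row blocks
//   * minute data is stored once as a cube (T x d_ts x N)

#include <RcppArmadillo.h>
#include <random>
#include <memory>
#include <chrono>
#include <dlfcn.h>

// The network's GEMMs are small; threaded BLAS oversubscribes a single
// core and slows them down badly.  Cap OpenBLAS at one thread if the
// symbol is available (no-op with other BLAS implementations).
static void ensure_single_thread_blas() {
  static bool done = false;
  if (done) return;
  done = true;
  typedef void (*set_threads_t)(int);
  set_threads_t f = (set_threads_t)dlsym(RTLD_DEFAULT,
                                         "openblas_set_num_threads");
  if (f) f(1);
}

// coarse stage timing, enabled with FATNET_PROFILE=1
static bool prof_on() {
  static int v = -1;
  if (v < 0) {
    const char* e = std::getenv("FATNET_PROFILE");
    v = (e && e[0] == '1') ? 1 : 0;
  }
  return v == 1;
}
static std::map<std::string, double> prof_acc;
struct ProfT {
  std::string key;
  std::chrono::high_resolution_clock::time_point t0;
  explicit ProfT(const char* k) : key(k) {
    if (prof_on()) t0 = std::chrono::high_resolution_clock::now();
  }
  ~ProfT() {
    if (prof_on())
      prof_acc[key] += std::chrono::duration<double>(
        std::chrono::high_resolution_clock::now() - t0).count();
  }
};
// [[Rcpp::export]]
Rcpp::List nn_profile_report() {
  Rcpp::List out;
  for (auto& kv : prof_acc) out[kv.first] = kv.second;
  prof_acc.clear();
  return out;
}
// [[Rcpp::depends(RcppArmadillo)]]

// fast single-precision exp/tanh (relative error ~1e-5), used in the
// hot activation loops; backward passes reuse cached forward values so
// analytic gradients stay consistent with the approximation
static inline float fast_expf(float x) {
  x *= 1.442695041f;                       // to base-2 exponent
  if (x < -87.f) return 0.f;
  if (x > 88.f) x = 88.f;
  float fi = std::floor(x);
  float f = x - fi;
  float p = 1.f + f * (0.693147182f + f * (0.240226507f +
            f * (0.055504109f + f * (0.009618129f +
            f * (0.001333355f + f * 0.000154035f)))));
  union { float fv; int32_t iv; } u;
  u.iv = ((int32_t)fi + 127) << 23;
  return p * u.fv;
}
static inline float fast_sigmoidf(float x) {
  return 1.f / (1.f + fast_expf(-x));
}
static inline float fast_tanhf(float x) {
  if (x > 9.f) return 1.f;
  if (x < -9.f) return -1.f;
  float e = fast_expf(2.f * x);
  return (e - 1.f) / (e + 1.f);
}

typedef arma::fmat Mat;
typedef arma::frowvec RowV;
typedef arma::fvec Vec;
typedef arma::fcube Cube;

struct RNG {
  std::mt19937 gen;
  std::normal_distribution<float> norm;
  std::uniform_real_distribution<float> unif;
  explicit RNG(unsigned int seed) : gen(seed), norm(0.f, 1.f),
                                    unif(0.f, 1.f) {}
  float normal() { return norm(gen); }
  float uniform() { return unif(gen); }
};

struct Param {
  Mat w, g, m, v;
  bool decay;
  Param() : decay(false) {}
  void init(int r, int c, bool decay_) {
    w.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
    decay = decay_;
  }
  void glorot(RNG& rng) {
    float lim = std::sqrt(6.f / (w.n_rows + w.n_cols));
    for (arma::uword i = 0; i < w.n_elem; ++i)
      w(i) = (2.f * rng.uniform() - 1.f) * lim;
  }
};

struct AdamW {
  float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long t = 0;
  void step(std::vector<Param*>& ps, float lr, float wd) {
    ++t;
    float c1 = 1.f - std::pow(b1, (float)t);
    float c2 = 1.f - std::pow(b2, (float)t);
    float isc2 = 1.f / std::sqrt(c2);
    for (Param* p : ps) {
      float* w = p->w.memptr();
      float* g = p->g.memptr();
      float* m = p->m.memptr();
      float* v = p->v.memptr();
      float dec = p->decay ? wd : 0.f;
      arma::uword n = p->w.n_elem;
      for (arma::uword i = 0; i < n; ++i) {
        m[i] = b1 * m[i] + (1.f - b1) * g[i];
        v[i] = b2 * v[i] + (1.f - b2) * g[i] * g[i];
        w[i] -= lr * ((m[i] / c1) / (std::sqrt(v[i]) * isc2 + eps) +
                      dec * w[i]);
      }
    }
  }
};

// ---------------------------------------------------------------- layers

struct Linear {
  Param W, b;
  Mat xc;
  void init(int in, int out, RNG& rng) {
    W.init(in, out, true); b.init(1, out, false); W.glorot(rng);
  }
  Mat forward(const Mat& x, bool cache = true) {
    if (cache) xc = x;
    Mat y = x * W.w;
    y.each_row() += b.w.row(0);
    return y;
  }
  // returns dx
  Mat backward(const Mat& dy, bool need_dx = true) {
    W.g += xc.t() * dy;
    b.g += arma::sum(dy, 0);
    if (!need_dx) return Mat();
    return dy * W.w.t();
  }
  void reg(std::vector<Param*>& ps) { ps.push_back(&W); ps.push_back(&b); }
};

// row-wise layer normalization, fused column-sweep implementation
// (row statistics are accumulated down contiguous columns)
struct LayerNorm {
  Param g, b;
  Mat xhat; Vec invstd;
  static constexpr float eps = 1e-5f;
  void init(int c) { g.init(1, c, false); b.init(1, c, false); g.w.ones(); }
  Mat forward(const Mat& x) {
    arma::uword R = x.n_rows, C = x.n_cols;
    Vec mu(R, arma::fill::zeros), va(R, arma::fill::zeros);
    for (arma::uword j = 0; j < C; ++j) {
      const float* xc = x.colptr(j);
      for (arma::uword i = 0; i < R; ++i) mu(i) += xc[i];
    }
    mu /= (float)C;
    for (arma::uword j = 0; j < C; ++j) {
      const float* xc = x.colptr(j);
      for (arma::uword i = 0; i < R; ++i) {
        float d = xc[i] - mu(i);
        va(i) += d * d;
      }
    }
    invstd = 1.f / arma::sqrt(va / (float)C + eps);
    xhat.set_size(R, C);
    Mat y(R, C);
    for (arma::uword j = 0; j < C; ++j) {
      const float* xc = x.colptr(j);
      float* xh = xhat.colptr(j);
      float* yc = y.colptr(j);
      float gj = g.w(0, j), bj = b.w(0, j);
      for (arma::uword i = 0; i < R; ++i) {
        xh[i] = (xc[i] - mu(i)) * invstd(i);
        yc[i] = xh[i] * gj + bj;
      }
    }
    return y;
  }
  Mat backward(const Mat& dy) {
    arma::uword R = dy.n_rows, C = dy.n_cols;
    Vec m1(R, arma::fill::zeros), m2(R, arma::fill::zeros);
    Mat dx(R, C);
    for (arma::uword j = 0; j < C; ++j) {
      const float* dyc = dy.colptr(j);
      const float* xh = xhat.colptr(j);
      float* dxc = dx.colptr(j);
      float gj = g.w(0, j);
      float gg = 0.f, bg = 0.f;
      for (arma::uword i = 0; i < R; ++i) {
        gg += dyc[i] * xh[i];
        bg += dyc[i];
        float t = dyc[i] * gj;
        dxc[i] = t;
        m1(i) += t;
        m2(i) += t * xh[i];
      }
      g.g(0, j) += gg;
      b.g(0, j) += bg;
    }
    m1 /= (float)C; m2 /= (float)C;
    for (arma::uword j = 0; j < C; ++j) {
      const float* xh = xhat.colptr(j);
      float* dxc = dx.colptr(j);
      for (arma::uword i = 0; i < R; ++i)
        dxc[i] = (dxc[i] - m1(i) - xh[i] * m2(i)) * invstd(i);
    }
    return dx;
  }
  void reg(std::vector<Param*>& ps) { ps.push_back(&g); ps.push_back(&b); }
};

struct BatchNorm {
  Param g, b;
  Mat run_mu, run_var;       // non-learned state, serialized with params
  RowV invstd;
  Mat xhat;
  float momentum = 0.9f;
  static constexpr float eps = 1e-5f;
  void init(int c) {
    g.init(1, c, false); b.init(1, c, false); g.w.ones();
    run_mu.zeros(1, c); run_var.ones(1, c);
  }
  Mat forward(const Mat& x, bool train, bool update_running = true) {
    RowV mu, va;
    if (train) {
      mu = arma::mean(x, 0);
      va = arma::mean(arma::square(x.each_row() - mu), 0);
      if (update_running) {
        run_mu = momentum * run_mu + (1.f - momentum) * mu;
        run_var = momentum * run_var + (1.f - momentum) * va;
      }
    } else { mu = run_mu.row(0); va = run_var.row(0); }
    invstd = 1.f / arma::sqrt(va + eps);
    xhat = (x.each_row() - mu).each_row() % invstd;
    Mat y = xhat.each_row() % g.w.row(0);
    y.each_row() += b.w.row(0);
    return y;
  }
  Mat backward(const Mat& dy) {
    g.g += arma::sum(dy % xhat, 0);
    b.g += arma::sum(dy, 0);
    Mat dxh = dy.each_row() % g.w.row(0);
    RowV m1 = arma::mean(dxh, 0);
    RowV m2 = arma::mean(dxh % xhat, 0);
    Mat dx = dxh;
    dx.each_row() -= m1;
    dx -= xhat.each_row() % m2;
    dx.each_row() %= invstd;
    return dx;
  }
  void reg(std::vector<Param*>& ps) { ps.push_back(&g); ps.push_back(&b); }
  void reg_state(std::vector<Mat*>& st) {
    st.push_back(&run_mu); st.push_back(&run_var);
  }
};

// GELU, tanh parameterization (the form most deep-learning frameworks use)
struct Gelu {
  Mat xc, tc;
  static constexpr float a = 0.7978845608f;   // sqrt(2/pi)
  static constexpr float b = 0.044715f;
  Mat forward(const Mat& x) {
    xc = x;
    tc.set_size(x.n_rows, x.n_cols);
    Mat y(x.n_rows, x.n_cols);
    const float* xp = x.memptr();
    float* tp = tc.memptr();
    float* yp = y.memptr();
    arma::uword n = x.n_elem;
    for (arma::uword i = 0; i < n; ++i) {
      float v = xp[i];
      float t = fast_tanhf(a * (v + b * v * v * v));
      tp[i] = t;
      yp[i] = 0.5f * v * (1.f + t);
    }
    return y;
  }
  Mat backward(const Mat& dy) {
    Mat dx(dy.n_rows, dy.n_cols);
    const float* dyp = dy.memptr();
    const float* xp = xc.memptr();
    const float* tp = tc.memptr();
    float* dxp = dx.memptr();
    arma::uword n = dy.n_elem;
    for (arma::uword i = 0; i < n; ++i) {
      float v = xp[i], t = tp[i];
      float du = a * (1.f + 3.f * b * v * v);
      dxp[i] = dyp[i] * (0.5f * (1.f + t) + 0.5f * v * (1.f - t * t) * du);
    }
    return dx;
  }
};

struct Relu {
  arma::umat mask;
  Mat forward(const Mat& x) {
    mask = (x > 0.f);
    return x % arma::conv_to<Mat>::from(mask);
  }
  Mat backward(const Mat& dy) {
    return dy % arma::conv_to<Mat>::from(mask);
  }
};

struct Dropout {
  Mat mask;
  float p;
  explicit Dropout(float p_ = 0.f) : p(p_) {}
  Mat forward(const Mat& x, bool train, RNG& rng) {
    if (!train || p <= 0.f) { mask.reset(); return x; }
    mask.set_size(x.n_rows, x.n_cols);
    float keep = 1.f - p;
    float inv_keep = 1.f / keep;
    // cheap xorshift stream reseeded from the model RNG per call
    uint32_t s = (uint32_t)rng.gen() | 1u;
    Mat y(x.n_rows, x.n_cols);
    const float* xp = x.memptr();
    float* mp = mask.memptr();
    float* yp = y.memptr();
    arma::uword n = x.n_elem;
    for (arma::uword i = 0; i < n; ++i) {
      s ^= s << 13; s ^= s >> 17; s ^= s << 5;
      float u = (s >> 8) * (1.f / 16777216.f);
      float m = u < keep ? inv_keep : 0.f;
      mp[i] = m;
      yp[i] = xp[i] * m;
    }
    return y;
  }
  Mat backward(const Mat& dy) {
    if (mask.is_empty()) return dy;
    return dy % mask;
  }
};

// 1-D convolution over time, stride 1.  "same" (centered) padding for the
// encoder stack; causal left padding with dilation for the TCN baseline.
struct Conv1d {
  int k, cin, cout, dil;
  bool causal;
  Param W, b;
  Mat M;       // im2col cache, (B*T) x (k*cin)
  int B = 0, T = 0;
  void init(int k_, int cin_, int cout_, RNG& rng, bool causal_ = false,
            int dil_ = 1) {
    k = k_; cin = cin_; cout = cout_; causal = causal_; dil = dil_;
    W.init(k * cin, cout, true); b.init(1, cout, false); W.glorot(rng);
  }
  int shift(int j) const { return causal ? (j - (k - 1)) * dil : j - k / 2; }
  Mat forward(const Mat& X, int B_, int T_) {
    B = B_; T = T_;
    M.zeros(B * T, k * cin);
    for (int j = 0; j < k; ++j) {
      int s = shift(j);
      int t0 = std::max(0, -s), t1 = std::min(T, T - s);   // dest t range
      if (t0 >= t1) continue;
      for (int bb = 0; bb < B; ++bb)
        M.submat(bb * T + t0, j * cin, bb * T + t1 - 1, (j + 1) * cin - 1) =
          X.rows(bb * T + t0 + s, bb * T + t1 - 1 + s);
    }
    Mat Y = M * W.w;
    Y.each_row() += b.w.row(0);
    return Y;
  }
  Mat backward(const Mat& dY, bool need_dx = true) {
    W.g += M.t() * dY;
    b.g += arma::sum(dY, 0);
    if (!need_dx) return Mat();
    Mat dM = dY * W.w.t();
    Mat dX(B * T, cin, arma::fill::zeros);
    for (int j = 0; j < k; ++j) {
      int s = shift(j);
      int t0 = std::max(0, -s), t1 = std::min(T, T - s);
      if (t0 >= t1) continue;
      for (int bb = 0; bb < B; ++bb)
        dX.rows(bb * T + t0 + s, bb * T + t1 - 1 + s) +=
          dM.submat(bb * T + t0, j * cin, bb * T + t1 - 1, (j + 1) * cin - 1);
    }
    return dX;
  }
  void reg(std::vector<Param*>& ps) { ps.push_back(&W); ps.push_back(&b); }
};

// One LSTM direction over (B*T) x cin sequence layout.  The input
// projection X * Wx and its gradients are computed as single GEMMs
// outside the time loop; only the recurrent part iterates over steps.
struct LSTMdir {
  int cin, H;
  bool reverse;
  Param Wx, Wh, b;
  Cube IG, FG, GG, OG, HCH, CPREV, HPREV;   // (B x H x T), step-indexed
  Mat Xc;
  int B = 0, T = 0;
  void init(int cin_, int H_, bool rev, RNG& rng) {
    cin = cin_; H = H_; reverse = rev;
    Wx.init(cin, 4 * H, true); Wh.init(H, 4 * H, true); b.init(1, 4 * H, false);
    Wx.glorot(rng); Wh.glorot(rng);
    b.w.cols(H, 2 * H - 1).fill(1.f);   // forget-gate bias
  }
  arma::uvec rows_t(int t) const {
    arma::uvec r(B);
    for (int bb = 0; bb < B; ++bb) r(bb) = bb * T + t;
    return r;
  }
  // writes output into Hout columns [col0, col0+H)
  void forward(const Mat& X, int B_, int T_, Mat& Hout, int col0) {
    B = B_; T = T_;
    Xc = X;
    IG.set_size(B, H, T); FG.set_size(B, H, T); GG.set_size(B, H, T);
    OG.set_size(B, H, T); HCH.set_size(B, H, T);
    CPREV.set_size(B, H, T); HPREV.set_size(B, H, T);
    Mat Xp = X * Wx.w;                     // (B*T) x 4H
    Xp.each_row() += b.w.row(0);
    Mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
    for (int s = 0; s < T; ++s) {
      int t = reverse ? T - 1 - s : s;
      arma::uvec rt = rows_t(t);
      HPREV.slice(s) = h; CPREV.slice(s) = c;
      Mat A = Xp.rows(rt) + h * Wh.w;
      float* ig = IG.slice_memptr(s);
      float* fg = FG.slice_memptr(s);
      float* gg = GG.slice_memptr(s);
      float* og = OG.slice_memptr(s);
      const float* ap = A.memptr();
      int BH = B * H;
      for (int i = 0; i < BH; ++i) {
        ig[i] = fast_sigmoidf(ap[i]);
        fg[i] = fast_sigmoidf(ap[BH + i]);
        gg[i] = fast_tanhf(ap[2 * BH + i]);
        og[i] = fast_sigmoidf(ap[3 * BH + i]);
      }
      c = FG.slice(s) % c + IG.slice(s) % GG.slice(s);
      {
        float* hc = HCH.slice_memptr(s);
        const float* cp = c.memptr();
        for (int i = 0; i < BH; ++i) hc[i] = fast_tanhf(cp[i]);
      }
      h = OG.slice(s) % HCH.slice(s);
      Hout.submat(rt, arma::regspace<arma::uvec>(col0, col0 + H - 1)) = h;
    }
  }
  void backward(const Mat& dHout, int col0, Mat& dX) {
    Mat dh_next(B, H, arma::fill::zeros), dc_next(B, H, arma::fill::zeros);
    Mat dAall(B * T, 4 * H);
    arma::uvec cols = arma::regspace<arma::uvec>(col0, col0 + H - 1);
    for (int s = T - 1; s >= 0; --s) {
      int t = reverse ? T - 1 - s : s;
      arma::uvec rt = rows_t(t);
      Mat dh = dHout.submat(rt, cols) + dh_next;
      Mat do_ = dh % HCH.slice(s);
      Mat dc = dc_next + dh % OG.slice(s) % (1.f - arma::square(HCH.slice(s)));
      Mat dA(B, 4 * H);
      dA.cols(0, H - 1) = (dc % GG.slice(s)) % IG.slice(s) % (1.f - IG.slice(s));
      dA.cols(H, 2 * H - 1) = (dc % CPREV.slice(s)) % FG.slice(s) %
        (1.f - FG.slice(s));
      dA.cols(2 * H, 3 * H - 1) = (dc % IG.slice(s)) %
        (1.f - arma::square(GG.slice(s)));
      dA.cols(3 * H, 4 * H - 1) = do_ % OG.slice(s) % (1.f - OG.slice(s));
      Wh.g += HPREV.slice(s).t() * dA;
      dAall.rows(rt) = dA;
      dh_next = dA * Wh.w.t();
      dc_next = dc % FG.slice(s);
    }
    Wx.g += Xc.t() * dAall;
    b.g += arma::sum(dAall, 0);
    dX += dAall * Wx.w.t();
  }
  void reg(std::vector<Param*>& ps) {
    ps.push_back(&Wx); ps.push_back(&Wh); ps.push_back(&b);
  }
};

struct BiLSTM {
  LSTMdir fwd, rev;
  int H2;
  void init(int cin, int h, RNG& rng) {
    H2 = h / 2;
    fwd.init(cin, H2, false, rng);
    rev.init(cin, H2, true, rng);
  }
  Mat forward(const Mat& X, int B, int T) {
    Mat H(B * T, 2 * H2);
    fwd.forward(X, B, T, H, 0);
    rev.forward(X, B, T, H, H2);
    return H;
  }
  Mat backward(const Mat& dH, int B, int T) {
    Mat dX(B * T, fwd.cin, arma::fill::zeros);
    fwd.backward(dH, 0, dX);
    rev.backward(dH, H2, dX);
    return dX;
  }
  void reg(std::vector<Param*>& ps) { fwd.reg(ps); rev.reg(ps); }
};

// interpolated lookup table for exp(x) on [-20, 0] (max-shifted softmax
// arguments are non-positive; below -20 the weight is numerically zero)
struct ExpTable {
  static constexpr int N = 4096;
  float tab[N + 1];
  ExpTable() {
    for (int i = 0; i <= N; ++i)
      tab[i] = std::exp(-20.0 + 20.0 * i / N);
  }
  inline float operator()(float x) const {   // x <= 0
    if (x <= -20.f) return 0.f;
    float u = (x + 20.f) * (N / 20.f);
    int i = (int)u;
    float w = u - i;
    return tab[i] + (tab[i + 1] - tab[i]) * w;
  }
};
static const ExpTable exp_table;

// fused in-place row softmax (max-shifted), column-sweep accumulation
static void softmax_rows(Mat& S) {
  arma::uword R = S.n_rows, C = S.n_cols;
  Vec mx(R);
  mx.fill(-std::numeric_limits<float>::infinity());
  for (arma::uword j = 0; j < C; ++j) {
    const float* c = S.colptr(j);
    for (arma::uword i = 0; i < R; ++i) if (c[i] > mx(i)) mx(i) = c[i];
  }
  Vec rs(R, arma::fill::zeros);
  for (arma::uword j = 0; j < C; ++j) {
    float* c = S.colptr(j);
    for (arma::uword i = 0; i < R; ++i) {
      float v = exp_table(c[i] - mx(i));
      c[i] = v;
      rs(i) += v;
    }
  }
  rs = 1.f / rs;
  for (arma::uword j = 0; j < C; ++j) {
    float* c = S.colptr(j);
    for (arma::uword i = 0; i < R; ++i) c[i] *= rs(i);
  }
}

// multi-head scaled-dot-product attention, processed per sample;
// all projections map width h -> h, nh heads of width dk = h/nh
struct MHA {
  int h, nh, dk;
  Param Wq, Wk, Wv, Wo;
  Param bq, bk, bv, bo;
  std::vector<Mat> Qc, Kc, Vc, Ctx, Xqc, Xkvc;
  std::vector<Cube> Pc;
  void init(int h_, int nh_, RNG& rng) {
    h = h_; nh = nh_; dk = h / nh;
    Wq.init(h, h, true); Wk.init(h, h, true);
    Wv.init(h, h, true); Wo.init(h, h, true);
    Wq.glorot(rng); Wk.glorot(rng); Wv.glorot(rng); Wo.glorot(rng);
    bq.init(1, h, false); bk.init(1, h, false);
    bv.init(1, h, false); bo.init(1, h, false);
  }
  void begin_batch(int B) {
    Qc.assign(B, Mat()); Kc.assign(B, Mat()); Vc.assign(B, Mat());
    Ctx.assign(B, Mat()); Xqc.assign(B, Mat()); Xkvc.assign(B, Mat());
    Pc.assign(B, Cube());
  }
  Mat forward_sample(int bix, const Mat& Xq, const Mat& Xkv) {
    Xqc[bix] = Xq; Xkvc[bix] = Xkv;
    Mat Q = Xq * Wq.w;  Q.each_row() += bq.w.row(0);
    Mat K = Xkv * Wk.w; K.each_row() += bk.w.row(0);
    Mat V = Xkv * Wv.w; V.each_row() += bv.w.row(0);
    Qc[bix] = Q; Kc[bix] = K; Vc[bix] = V;
    int Tq = Q.n_rows, Tk = K.n_rows;
    Cube P(Tq, Tk, nh);
    Mat C(Tq, h);
    float scale = 1.f / std::sqrt((float)dk);
    for (int hd = 0; hd < nh; ++hd) {
      int c0 = hd * dk, c1 = (hd + 1) * dk - 1;
      Mat S = Q.cols(c0, c1) * K.cols(c0, c1).t() * scale;
      softmax_rows(S);
      P.slice(hd) = S;
      C.cols(c0, c1) = S * V.cols(c0, c1);
    }
    Pc[bix] = P; Ctx[bix] = C;
    Mat Y = C * Wo.w;
    Y.each_row() += bo.w.row(0);
    return Y;
  }
  void backward_sample(int bix, const Mat& dY, Mat& dXq, Mat& dXkv) {
    const Mat &Q = Qc[bix], &K = Kc[bix], &V = Vc[bix], &C = Ctx[bix];
    Wo.g += C.t() * dY;
    bo.g += arma::sum(dY, 0);
    Mat dC = dY * Wo.w.t();
    Mat dQ(Q.n_rows, h, arma::fill::zeros);
    Mat dK(K.n_rows, h, arma::fill::zeros);
    Mat dV(V.n_rows, h, arma::fill::zeros);
    float scale = 1.f / std::sqrt((float)dk);
    for (int hd = 0; hd < nh; ++hd) {
      int c0 = hd * dk, c1 = (hd + 1) * dk - 1;
      const Mat& P = Pc[bix].slice(hd);
      Mat dP = dC.cols(c0, c1) * V.cols(c0, c1).t();
      dV.cols(c0, c1) = P.t() * dC.cols(c0, c1);
      Vec rowdot = arma::sum(dP % P, 1);
      Mat dS = (P % (dP.each_col() - rowdot)) * scale;
      dQ.cols(c0, c1) = dS * K.cols(c0, c1);
      dK.cols(c0, c1) = dS.t() * Q.cols(c0, c1);
    }
    Wq.g += Xqc[bix].t() * dQ;  bq.g += arma::sum(dQ, 0);
    Wk.g += Xkvc[bix].t() * dK; bk.g += arma::sum(dK, 0);
    Wv.g += Xkvc[bix].t() * dV; bv.g += arma::sum(dV, 0);
    dXq += dQ * Wq.w.t();
    dXkv += dK * Wk.w.t() + dV * Wv.w.t();
  }
  void reg(std::vector<Param*>& ps) {
    ps.push_back(&Wq); ps.push_back(&Wk); ps.push_back(&Wv); ps.push_back(&Wo);
    ps.push_back(&bq); ps.push_back(&bk); ps.push_back(&bv); ps.push_back(&bo);
  }
};

// ---------------------------------------------------------------- models

struct NetConfig {
  int T = 240, d_ts = 2, d_ds = 19, h = 64, n_heads = 4;
  int conv_filters[3] = {32, 64, 128};
  int conv_kernels[3] = {5, 3, 3};
  float conv_dropout = 0.1f;
  int mlp_dims[2] = {64, 128};
  float mlp_dropout = 0.2f;
  int ffn_hidden[2] = {512, 512};
  int head_hidden = 256;
  float head_dropout = 0.2f;
  // TCN baseline
  int tcn_kernel = 7;
  int tcn_dilations[3] = {1, 4, 16};
};

struct Net {
  NetConfig cfg;
  RNG rng;
  std::vector<Param*> ps;
  std::vector<Mat*> state;   // non-learned state (batch-norm running stats)
  explicit Net(unsigned int seed) : rng(seed) {}
  virtual ~Net() {}
  virtual Vec forward(const Cube& Xmin, const Mat& Xds,
                      const std::vector<int>& idx, bool train) = 0;
  virtual void backward(const Vec& dy) = 0;
  void zero_grad() { for (Param* p : ps) p->g.zeros(); }
  arma::vec get_params() const {
    size_t n = 0;
    for (const Param* p : ps) n += p->w.n_elem;
    for (const Mat* s : state) n += s->n_elem;
    arma::vec out(n);
    size_t at = 0;
    for (const Param* p : ps)
      for (arma::uword i = 0; i < p->w.n_elem; ++i) out(at++) = p->w(i);
    for (const Mat* s : state)
      for (arma::uword i = 0; i < s->n_elem; ++i) out(at++) = (*s)(i);
    return out;
  }
  void set_params(const arma::vec& v) {
    size_t at = 0;
    for (Param* p : ps)
      for (arma::uword i = 0; i < p->w.n_elem; ++i) p->w(i) = (float)v(at++);
    for (Mat* s : state)
      for (arma::uword i = 0; i < s->n_elem; ++i) (*s)(i) = (float)v(at++);
  }
  arma::vec get_grads() const {
    size_t n = 0;
    for (const Param* p : ps) n += p->w.n_elem;
    for (const Mat* s : state) n += s->n_elem;
    arma::vec out(n, arma::fill::zeros);   // state entries have zero grad
    size_t at = 0;
    for (const Param* p : ps)
      for (arma::uword i = 0; i < p->g.n_elem; ++i) out(at++) = p->g(i);
    return out;
  }
  // builds the (B*T) x d_ts input block for a batch
  Mat gather_seq(const Cube& Xmin, const std::vector<int>& idx) const {
    int B = idx.size(), T = cfg.T;
    Mat X(B * T, cfg.d_ts);
    for (int bb = 0; bb < B; ++bb)
      X.rows(bb * T, bb * T + T - 1) = Xmin.slice(idx[bb]);
    return X;
  }
  Mat gather_ds(const Mat& Xds, const std::vector<int>& idx) const {
    Mat X(idx.size(), Xds.n_cols);
    for (size_t bb = 0; bb < idx.size(); ++bb)
      X.row(bb) = Xds.row(idx[bb]);
    return X;
  }
};

// the dual-stream fusion network
struct FatNet : Net {
  Conv1d conv1, conv2, conv3;
  LayerNorm ln1, ln2, ln3;
  Gelu ge1, ge2, ge3;
  Dropout cd1, cd2, cd3;
  BiLSTM lstm;
  MHA self_attn, cross_a, cross_b;
  Linear m1, m2, m3;
  BatchNorm bn1, bn2, bn3;
  Relu mr1, mr2, mr3;
  Dropout md1, md2, md3;
  Param E;              // per-feature token embedding, d_ds x h
  Linear f1, f2, f3;    // fusion FFN
  Relu fr1, fr2;
  Linear h1, h2;        // prediction head
  Relu hr1;
  Dropout hd1;

  // batch caches
  int B = 0;
  Mat Hts, U, vTS, vDS, Xds_b, F0;
  std::vector<Mat> Tok, Amat;
  Cube lastXmin;        // unused; placeholder

  FatNet(const NetConfig& c, unsigned int seed) : Net(seed) {
    cfg = c;
    if (cfg.h % 2) Rcpp::stop("config error: embedding width h must be even");
    if (cfg.h % cfg.n_heads)
      Rcpp::stop("config error: n_heads must divide h");
    if (cfg.T < cfg.conv_kernels[0])
      Rcpp::stop("T smaller than the largest convolution kernel");
    conv1.init(cfg.conv_kernels[0], cfg.d_ts, cfg.conv_filters[0], rng);
    conv2.init(cfg.conv_kernels[1], cfg.conv_filters[0], cfg.conv_filters[1], rng);
    conv3.init(cfg.conv_kernels[2], cfg.conv_filters[1], cfg.conv_filters[2], rng);
    ln1.init(cfg.conv_filters[0]); ln2.init(cfg.conv_filters[1]);
    ln3.init(cfg.conv_filters[2]);
    cd1 = cd2 = cd3 = Dropout(cfg.conv_dropout);
    lstm.init(cfg.conv_filters[2], cfg.h, rng);
    self_attn.init(cfg.h, cfg.n_heads, rng);
    cross_a.init(cfg.h, cfg.n_heads, rng);
    cross_b.init(cfg.h, cfg.n_heads, rng);
    m1.init(cfg.d_ds, cfg.mlp_dims[0], rng);
    m2.init(cfg.mlp_dims[0], cfg.mlp_dims[1], rng);
    m3.init(cfg.mlp_dims[1], cfg.h, rng);
    bn1.init(cfg.mlp_dims[0]); bn2.init(cfg.mlp_dims[1]); bn3.init(cfg.h);
    md1 = md2 = md3 = Dropout(cfg.mlp_dropout);
    E.init(cfg.d_ds, cfg.h, true); E.glorot(rng);
    f1.init(2 * cfg.h, cfg.ffn_hidden[0], rng);
    f2.init(cfg.ffn_hidden[0], cfg.ffn_hidden[1], rng);
    f3.init(cfg.ffn_hidden[1], 2 * cfg.h, rng);
    h1.init(2 * cfg.h, cfg.head_hidden, rng);
    h2.init(cfg.head_hidden, 1, rng);
    hd1 = Dropout(cfg.head_dropout);
    conv1.reg(ps); ln1.reg(ps); conv2.reg(ps); ln2.reg(ps);
    conv3.reg(ps); ln3.reg(ps); lstm.reg(ps); self_attn.reg(ps);
    m1.reg(ps); bn1.reg(ps); m2.reg(ps); bn2.reg(ps); m3.reg(ps); bn3.reg(ps);
    ps.push_back(&E);
    cross_a.reg(ps); cross_b.reg(ps);
    f1.reg(ps); f2.reg(ps); f3.reg(ps); h1.reg(ps); h2.reg(ps);
    bn1.reg_state(state); bn2.reg_state(state); bn3.reg_state(state);
  }

  Vec forward(const Cube& Xmin, const Mat& Xds,
              const std::vector<int>& idx, bool train) override {
    return forward_impl(Xmin, Xds, idx, train, true);
  }

  Vec forward_impl(const Cube& Xmin, const Mat& Xds,
                   const std::vector<int>& idx, bool train,
                   bool update_running) {
    B = idx.size();
    int T = cfg.T, h = cfg.h, dds = cfg.d_ds;
    Mat X0 = gather_seq(Xmin, idx);
    Mat A;
    {
      ProfT pt("fwd_conv");
      A = cd1.forward(ge1.forward(ln1.forward(
                conv1.forward(X0, B, T))), train, rng);
      A = cd2.forward(ge2.forward(ln2.forward(
                conv2.forward(A, B, T))), train, rng);
      A = cd3.forward(ge3.forward(ln3.forward(
                conv3.forward(A, B, T))), train, rng);
    }
    {
      ProfT pt("fwd_lstm");
      Hts = lstm.forward(A, B, T);
    }

    {
      ProfT pt("fwd_attn");
      self_attn.begin_batch(B);
      U.set_size(B * T, h);
      vTS.set_size(B, h);
      for (int bb = 0; bb < B; ++bb) {
        Mat Hb = Hts.rows(bb * T, bb * T + T - 1);
        Mat Ub = self_attn.forward_sample(bb, Hb, Hb);
        U.rows(bb * T, bb * T + T - 1) = Ub;
        vTS.row(bb) = arma::mean(Ub, 0);
      }
    }

    ProfT pt("fwd_rest");
    Xds_b = gather_ds(Xds, idx);
    Mat Z = md1.forward(mr1.forward(bn1.forward(
              m1.forward(Xds_b), train, update_running)), train, rng);
    Z = md2.forward(mr2.forward(bn2.forward(
              m2.forward(Z), train, update_running)), train, rng);
    vDS = md3.forward(mr3.forward(bn3.forward(
              m3.forward(Z), train, update_running)), train, rng);

    Tok.assign(B, Mat());
    Amat.assign(B, Mat());
    cross_a.begin_batch(B);
    cross_b.begin_batch(B);
    F0.set_size(B, 2 * h);
    for (int bb = 0; bb < B; ++bb) {
      Tok[bb] = E.w.each_col() % Xds_b.row(bb).t();   // d_ds x h tokens
      Mat Ub = U.rows(bb * T, bb * T + T - 1);
      Amat[bb] = cross_a.forward_sample(bb, Tok[bb], Ub);
      RowV apool = arma::mean(Amat[bb], 0);
      Mat qb = vTS.row(bb);
      Mat rb = cross_b.forward_sample(bb, qb, Tok[bb]);
      F0.submat(bb, 0, bb, h - 1) = rb.row(0) + vTS.row(bb);
      F0.submat(bb, h, bb, 2 * h - 1) = apool + vDS.row(bb);
    }
    Mat F = f3.forward(fr2.forward(f2.forward(fr1.forward(f1.forward(F0)))));
    Mat yh = h2.forward(hd1.forward(hr1.forward(h1.forward(F)), train, rng));
    return yh.col(0);
  }

  void backward(const Vec& dy) override {
    int T = cfg.T, h = cfg.h, dds = cfg.d_ds;
    Mat dyh(dy.n_elem, 1);
    dyh.col(0) = dy;
    Mat dF = h1.backward(hr1.backward(hd1.backward(h2.backward(dyh))));
    Mat dF0 = f1.backward(fr1.backward(f2.backward(fr2.backward(
                f3.backward(dF)))));
    Mat dU(B * T, h, arma::fill::zeros);
    Mat dvTS(B, h, arma::fill::zeros);
    Mat dvDS(B, h, arma::fill::zeros);
    Mat dXds_tok(B, dds, arma::fill::zeros);
    for (int bb = 0; bb < B; ++bb) {
      Mat dTok(dds, h, arma::fill::zeros);
      // block B: rb + residual vTS
      Mat drb = dF0.submat(bb, 0, bb, h - 1);
      dvTS.row(bb) += drb.row(0);
      Mat dqb(1, h, arma::fill::zeros);
      cross_b.backward_sample(bb, drb, dqb, dTok);
      dvTS.row(bb) += dqb.row(0);
      // block A: mean-pooled + residual vDS
      RowV dap = dF0.submat(bb, h, bb, 2 * h - 1);
      dvDS.row(bb) += dap;
      Mat dA(dds, h);
      dA.each_row() = dap / (float)dds;
      Mat dUb(T, h, arma::fill::zeros);
      cross_a.backward_sample(bb, dA, dTok, dUb);
      dU.rows(bb * T, bb * T + T - 1) += dUb;
      // token embedding: Tok = diag(x) * E
      E.g += dTok.each_col() % Xds_b.row(bb).t();
      dXds_tok.row(bb) += arma::sum(dTok % E.w, 1).t();
    }
    // summary MLP
    Mat dZ = bn3.backward(mr3.backward(md3.backward(dvDS)));
    dZ = m3.backward(dZ);
    dZ = bn2.backward(mr2.backward(md2.backward(dZ)));
    dZ = m2.backward(dZ);
    dZ = bn1.backward(mr1.backward(md1.backward(dZ)));
    m1.backward(dZ, false);   // input grads of raw features not needed
    (void)dXds_tok;
    // self-attention + pooling
    Mat dHts(B * T, h, arma::fill::zeros);
    for (int bb = 0; bb < B; ++bb) {
      Mat dUb = dU.rows(bb * T, bb * T + T - 1);
      dUb.each_row() += dvTS.row(bb) / (float)T;   // mean-pool route
      Mat dHb(T, h, arma::fill::zeros);
      Mat dHb2(T, h, arma::fill::zeros);
      self_attn.backward_sample(bb, dUb, dHb, dHb2);
      dHts.rows(bb * T, bb * T + T - 1) += dHb + dHb2;
    }
    Mat dA3 = lstm.backward(dHts, B, cfg.T);
    dA3 = ln3.backward(ge3.backward(cd3.backward(dA3)));
    Mat dA2 = conv3.backward(dA3);
    dA2 = ln2.backward(ge2.backward(cd2.backward(dA2)));
    Mat dA1 = conv2.backward(dA2);
    dA1 = ln1.backward(ge1.backward(cd1.backward(dA1)));
    conv1.backward(dA1, false);
  }

  // attention maps for one already-forwarded sample (index 0 of the batch)
  Rcpp::List attention_maps() {
    arma::cube self = arma::conv_to<arma::cube>::from(self_attn.Pc[0]);
    // cross A: queries are summary features, keys are time steps
    arma::mat crossA =
      arma::conv_to<arma::mat>::from(Mat(arma::mean(cross_a.Pc[0], 2)));
    // cross B: temporal query over the summary tokens
    arma::mat crossB =
      arma::conv_to<arma::mat>::from(Mat(arma::mean(cross_b.Pc[0], 2)));
    return Rcpp::List::create(
      Rcpp::Named("self") = self,
      Rcpp::Named("cross") = crossA,
      Rcpp::Named("cross_temporal") = arma::rowvec(crossB.row(0)));
  }
};

// single-stream LSTM baseline: LSTM(h) over the minute series, mean-pooled,
// concatenated with the daily summary vector, then a small head
struct LstmReg : Net {
  LSTMdir lstmd;
  Linear l1, l2;
  Relu r1;
  int B = 0;
  Mat Hseq, pooled, Xds_b, cat;
  LstmReg(const NetConfig& c, unsigned int seed) : Net(seed) {
    cfg = c;
    lstmd.init(cfg.d_ts, cfg.h, false, rng);
    l1.init(cfg.h + cfg.d_ds, 64, rng);
    l2.init(64, 1, rng);
    lstmd.reg(ps); l1.reg(ps); l2.reg(ps);
  }
  Vec forward(const Cube& Xmin, const Mat& Xds,
              const std::vector<int>& idx, bool train) override {
    B = idx.size();
    int T = cfg.T;
    Mat X0 = gather_seq(Xmin, idx);
    Hseq.set_size(B * T, cfg.h);
    lstmd.forward(X0, B, T, Hseq, 0);
    pooled.set_size(B, cfg.h);
    for (int bb = 0; bb < B; ++bb)
      pooled.row(bb) = arma::mean(Hseq.rows(bb * T, bb * T + T - 1), 0);
    Xds_b = gather_ds(Xds, idx);
    cat = arma::join_rows(pooled, Xds_b);
    Mat yh = l2.forward(r1.forward(l1.forward(cat)));
    return yh.col(0);
  }
  void backward(const Vec& dy) override {
    int T = cfg.T;
    Mat dyh(dy.n_elem, 1); dyh.col(0) = dy;
    Mat dcat = l1.backward(r1.backward(l2.backward(dyh)));
    Mat dpool = dcat.cols(0, cfg.h - 1);
    Mat dH(B * T, cfg.h, arma::fill::zeros);
    for (int bb = 0; bb < B; ++bb)
      for (int t = 0; t < T; ++t)
        dH.row(bb * T + t) = dpool.row(bb) / (float)T;
    Mat dX(B * T, cfg.d_ts, arma::fill::zeros);
    lstmd.backward(dH, 0, dX);
  }
};

// dilated causal convolution baseline
struct TcnReg : Net {
  Conv1d c1, c2, c3;
  Relu r1, r2, r3, rh;
  Linear l1, l2;
  int B = 0;
  Mat pooled, Xds_b, cat;
  TcnReg(const NetConfig& c, unsigned int seed) : Net(seed) {
    cfg = c;
    c1.init(cfg.tcn_kernel, cfg.d_ts, cfg.conv_filters[0], rng, true,
            cfg.tcn_dilations[0]);
    c2.init(cfg.tcn_kernel, cfg.conv_filters[0], cfg.conv_filters[1], rng,
            true, cfg.tcn_dilations[1]);
    c3.init(cfg.tcn_kernel, cfg.conv_filters[1], cfg.conv_filters[2], rng,
            true, cfg.tcn_dilations[2]);
    l1.init(cfg.conv_filters[2] + cfg.d_ds, 64, rng);
    l2.init(64, 1, rng);
    c1.reg(ps); c2.reg(ps); c3.reg(ps); l1.reg(ps); l2.reg(ps);
  }
  int receptive_field() const {
    int rf = 1;
    for (int dil : cfg.tcn_dilations) rf += (cfg.tcn_kernel - 1) * dil;
    return rf;
  }
  Vec forward(const Cube& Xmin, const Mat& Xds,
              const std::vector<int>& idx, bool train) override {
    B = idx.size();
    int T = cfg.T;
    Mat X0 = gather_seq(Xmin, idx);
    Mat A = r3.forward(c3.forward(r2.forward(c2.forward(
              r1.forward(c1.forward(X0, B, T)), B, T)), B, T));
    pooled.set_size(B, cfg.conv_filters[2]);
    for (int bb = 0; bb < B; ++bb)
      pooled.row(bb) = arma::mean(A.rows(bb * T, bb * T + T - 1), 0);
    Xds_b = gather_ds(Xds, idx);
    cat = arma::join_rows(pooled, Xds_b);
    Mat yh = l2.forward(rh.forward(l1.forward(cat)));
    return yh.col(0);
  }
  void backward(const Vec& dy) override {
    int T = cfg.T;
    Mat dyh(dy.n_elem, 1); dyh.col(0) = dy;
    Mat dcat = l1.backward(rh.backward(l2.backward(dyh)));
    Mat dpool = dcat.cols(0, cfg.conv_filters[2] - 1);
    Mat dA(B * T, cfg.conv_filters[2], arma::fill::zeros);
    for (int bb = 0; bb < B; ++bb)
      for (int t = 0; t < T; ++t)
        dA.row(bb * T + t) = dpool.row(bb) / (float)T;
    Mat d2 = c3.backward(r3.backward(dA));
    Mat d1 = c2.backward(r2.backward(d2));
    c1.backward(r1.backward(d1), false);
  }
};

// ------------------------------------------------------------- handle

struct NetHandle {
  std::unique_ptr<Net> net;
  std::string type;
  Cube Xtr, Xval;       // (T x d_ts x N)
  Mat DStr, DSval;
  Vec ytr, yval;
  AdamW opt;
  std::mt19937 shuffle_rng;
  NetHandle() : shuffle_rng(0) {}
};

static NetConfig parse_config(const Rcpp::List& conf) {
  NetConfig c;
  if (conf.containsElementNamed("T")) c.T = Rcpp::as<int>(conf["T"]);
  if (conf.containsElementNamed("d_ts")) c.d_ts = Rcpp::as<int>(conf["d_ts"]);
  if (conf.containsElementNamed("d_ds")) c.d_ds = Rcpp::as<int>(conf["d_ds"]);
  if (conf.containsElementNamed("h")) c.h = Rcpp::as<int>(conf["h"]);
  if (conf.containsElementNamed("n_heads"))
    c.n_heads = Rcpp::as<int>(conf["n_heads"]);
  if (conf.containsElementNamed("conv_filters")) {
    Rcpp::IntegerVector v = conf["conv_filters"];
    for (int i = 0; i < 3; ++i) c.conv_filters[i] = v[i];
  }
  if (conf.containsElementNamed("conv_kernels")) {
    Rcpp::IntegerVector v = conf["conv_kernels"];
    for (int i = 0; i < 3; ++i) c.conv_kernels[i] = v[i];
  }
  if (conf.containsElementNamed("conv_dropout"))
    c.conv_dropout = Rcpp::as<float>(conf["conv_dropout"]);
  if (conf.containsElementNamed("mlp_dims")) {
    Rcpp::IntegerVector v = conf["mlp_dims"];
    c.mlp_dims[0] = v[0]; c.mlp_dims[1] = v[1];
  }
  if (conf.containsElementNamed("mlp_dropout"))
    c.mlp_dropout = Rcpp::as<float>(conf["mlp_dropout"]);
  if (conf.containsElementNamed("ffn_hidden")) {
    Rcpp::IntegerVector v = conf["ffn_hidden"];
    c.ffn_hidden[0] = v[0]; c.ffn_hidden[1] = v[1];
  }
  if (conf.containsElementNamed("head_hidden"))
    c.head_hidden = Rcpp::as<int>(conf["head_hidden"]);
  if (conf.containsElementNamed("head_dropout"))
    c.head_dropout = Rcpp::as<float>(conf["head_dropout"]);
  if (conf.containsElementNamed("tcn_kernel"))
    c.tcn_kernel = Rcpp::as<int>(conf["tcn_kernel"]);
  if (conf.containsElementNamed("tcn_dilations")) {
    Rcpp::IntegerVector v = conf["tcn_dilations"];
    for (int i = 0; i < 3; ++i) c.tcn_dilations[i] = v[i];
  }
  return c;
}

// R array (N, T, d_ts) -> cube (T, d_ts, N)
static Cube array_to_cube(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  int N = d[0], T = d[1], C = d[2];
  Cube out(T, C, N);
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < T; ++t)
      for (int n = 0; n < N; ++n)
        out(t, c, n) = (float)x[n + (size_t)N * t + (size_t)N * T * c];
  return out;
}

static Mat matrix_to_fmat(const Rcpp::NumericMatrix& x) {
  Mat out(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i)
      out(i, j) = (float)x(i, j);
  return out;
}

// [[Rcpp::export]]
SEXP nn_create(std::string type, Rcpp::List config, int seed) {
  ensure_single_thread_blas();
  NetConfig c = parse_config(config);
  Rcpp::XPtr<NetHandle> ptr(new NetHandle(), true);
  if (type == "fatnet") ptr->net.reset(new FatNet(c, (unsigned)seed));
  else if (type == "lstm") ptr->net.reset(new LstmReg(c, (unsigned)seed));
  else if (type == "tcn") ptr->net.reset(new TcnReg(c, (unsigned)seed));
  else Rcpp::stop("unknown network type '" + type + "'");
  ptr->type = type;
  ptr->shuffle_rng.seed((unsigned)seed + 1000003u);
  return ptr;
}

// [[Rcpp::export]]
void nn_set_data(SEXP handle, Rcpp::NumericVector x_min,
                 Rcpp::NumericMatrix x_day, Rcpp::NumericVector y,
                 std::string which) {
  Rcpp::XPtr<NetHandle> ptr(handle);
  Cube X = array_to_cube(x_min);
  Mat DS = matrix_to_fmat(x_day);
  Vec yy(y.size());
  for (int i = 0; i < y.size(); ++i) yy(i) = (float)y[i];
  if (which == "train") { ptr->Xtr = X; ptr->DStr = DS; ptr->ytr = yy; }
  else { ptr->Xval = X; ptr->DSval = DS; ptr->yval = yy; }
}

static Vec predict_all(NetHandle* h, const Cube& X, const Mat& DS,
                       int batch = 64) {
  int N = X.n_slices;
  Vec out(N);
  for (int at = 0; at < N; at += batch) {
    int hi = std::min(N, at + batch);
    std::vector<int> idx;
    for (int i = at; i < hi; ++i) idx.push_back(i);
    Vec yh = h->net->forward(X, DS, idx, false);
    out.subvec(at, hi - 1) = yh;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_train(SEXP handle, double lr, double weight_decay,
                    int batch_size, int max_epochs, int patience,
                    int min_epochs = 0, bool verbose = false) {
  Rcpp::XPtr<NetHandle> ptr(handle);
  NetHandle* h = ptr.get();
  int N = h->Xtr.n_slices;
  if (N == 0) Rcpp::stop("empty training set");
  if ((int)h->Xval.n_slices == 0) Rcpp::stop("empty validation set");
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::vector<double> tr_loss, val_mae;
  arma::vec best_params = h->net->get_params();
  double best_mae = std::numeric_limits<double>::infinity();
  int best_epoch = -1, wait = 0;
  for (int ep = 0; ep < max_epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), h->shuffle_rng);
    double ep_loss = 0; int nb = 0;
    for (int at = 0; at < N; at += batch_size) {
      int hi = std::min(N, at + batch_size);
      std::vector<int> idx(order.begin() + at, order.begin() + hi);
      Vec yh = h->net->forward(h->Xtr, h->DStr, idx, true);
      Vec yt(idx.size());
      for (size_t i = 0; i < idx.size(); ++i) yt(i) = h->ytr(idx[i]);
      Vec err = yh - yt;
      double mse = arma::mean(arma::square(
        arma::conv_to<arma::vec>::from(err)));
      if (!std::isfinite(mse))
        Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
      h->net->zero_grad();
      Vec dy = 2.f * err / (float)idx.size();
      h->net->backward(dy);
      h->opt.step(h->net->ps, (float)lr, (float)weight_decay);
      ep_loss += mse; ++nb;
      Rcpp::checkUserInterrupt();
    }
    tr_loss.push_back(ep_loss / nb);
    Vec yhv = predict_all(h, h->Xval, h->DSval);
    double mae = arma::mean(arma::abs(
      arma::conv_to<arma::vec>::from(yhv - h->yval)));
    val_mae.push_back(mae);
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << " train mse " << tr_loss.back()
                  << " val mae " << mae << "\n";
    if (mae < best_mae - 1e-6) {
      best_mae = mae; best_epoch = ep; wait = 0;
      best_params = h->net->get_params();
    } else if (++wait >= patience && ep + 1 >= min_epochs) break;
  }
  h->net->set_params(best_params);
  return Rcpp::List::create(
    Rcpp::Named("train_loss") = tr_loss,
    Rcpp::Named("val_mae") = val_mae,
    Rcpp::Named("best_epoch") = best_epoch + 1,
    Rcpp::Named("best_val_mae") = best_mae,
    Rcpp::Named("n_epochs") = (int)tr_loss.size());
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_predict(SEXP handle, Rcpp::NumericVector x_min,
                               Rcpp::NumericMatrix x_day) {
  Rcpp::XPtr<NetHandle> ptr(handle);
  Cube X = array_to_cube(x_min);
  Mat DS = matrix_to_fmat(x_day);
  Vec yh = predict_all(ptr.get(), X, DS);
  return Rcpp::wrap(arma::conv_to<arma::vec>::from(yh));
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_get_params(SEXP handle) {
  Rcpp::XPtr<NetHandle> ptr(handle);
  return Rcpp::wrap(ptr->net->get_params());
}

// [[Rcpp::export]]
void nn_set_params(SEXP handle, Rcpp::NumericVector v) {
  Rcpp::XPtr<NetHandle> ptr(handle);
  ptr->net->set_params(Rcpp::as<arma::vec>(v));
}

// [[Rcpp::export]]
int nn_n_params(SEXP handle) {
  Rcpp::XPtr<NetHandle> ptr(handle);
  return (int)ptr->net->get_params().n_elem;
}

// loss (MSE + lambda * ||theta||^2) and its parameter gradient at the
// current parameters; dropout disabled, batch statistics used but running
// statistics frozen, so repeated calls are a pure function of the
// parameters (the basis of the finite-difference gradient checks)
// [[Rcpp::export]]
Rcpp::List nn_loss_grad(SEXP handle, Rcpp::NumericVector x_min,
                        Rcpp::NumericMatrix x_day, Rcpp::NumericVector y,
                        double lambda = 0.0, bool want_grad = true) {
  Rcpp::XPtr<NetHandle> ptr(handle);
  Cube X = array_to_cube(x_min);
  Mat DS = matrix_to_fmat(x_day);
  int N = X.n_slices;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  Vec yt(N);
  for (int i = 0; i < N; ++i) yt(i) = (float)y[i];
  Vec yh;
  FatNet* fn = dynamic_cast<FatNet*>(ptr->net.get());
  if (fn) yh = fn->forward_impl(X, DS, idx, true, false);
  else yh = ptr->net->forward(X, DS, idx, true);
  // note: for baselines "train" mode has no stochastic layers
  Vec err = yh - yt;
  double mse = arma::mean(arma::square(arma::conv_to<arma::vec>::from(err)));
  arma::vec theta = ptr->net->get_params();
  double loss = mse + lambda * arma::dot(theta, theta);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loss") = loss);
  if (want_grad) {
    ptr->net->zero_grad();
    Vec dy = 2.f * err / (float)N;
    ptr->net->backward(dy);
    arma::vec g = ptr->net->get_grads() + 2.0 * lambda * theta;
    out["grad"] = Rcpp::wrap(g);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_attention(SEXP handle, Rcpp::NumericVector x_min,
                        Rcpp::NumericMatrix x_day) {
  Rcpp::XPtr<NetHandle> ptr(handle);
  FatNet* fn = dynamic_cast<FatNet*>(ptr->net.get());
  if (!fn) Rcpp::stop("attention maps are only defined for the fusion model");
  Cube X = array_to_cube(x_min);
  Mat DS = matrix_to_fmat(x_day);
  std::vector<int> idx(1, 0);
  fn->forward(X, DS, idx, false);
  return fn->attention_maps();
}

// intermediate tensor shapes and pooling diagnostics for one sample
// [[Rcpp::export]]
Rcpp::List nn_trace(SEXP handle, Rcpp::NumericVector x_min,
                    Rcpp::NumericMatrix x_day) {
  Rcpp::XPtr<NetHandle> ptr(handle);
  FatNet* fn = dynamic_cast<FatNet*>(ptr->net.get());
  if (!fn) Rcpp::stop("trace is only defined for the fusion model");
  Cube X = array_to_cube(x_min);
  Mat DS = matrix_to_fmat(x_day);
  std::vector<int> idx(1, 0);
  Vec yh = fn->forward(X, DS, idx, false);
  int T = fn->cfg.T;
  return Rcpp::List::create(
    Rcpp::Named("H_ts") = Rcpp::wrap(arma::conv_to<arma::mat>::from(
      fn->Hts.rows(0, T - 1))),
    Rcpp::Named("U") = Rcpp::wrap(arma::conv_to<arma::mat>::from(
      fn->U.rows(0, T - 1))),
    Rcpp::Named("v_ts") = Rcpp::wrap(arma::conv_to<arma::rowvec>::from(
      fn->vTS.row(0))),
    Rcpp::Named("v_ds") = Rcpp::wrap(arma::conv_to<arma::rowvec>::from(
      fn->vDS.row(0))),
    Rcpp::Named("tokens") = Rcpp::wrap(arma::conv_to<arma::mat>::from(
      fn->Tok[0])),
    Rcpp::Named("F0") = Rcpp::wrap(arma::conv_to<arma::rowvec>::from(
      fn->F0.row(0))),
    Rcpp::Named("y_hat") = (double)yh(0));
}

// [[Rcpp::export]]
int nn_receptive_field(SEXP handle) {
  Rcpp::XPtr<NetHandle> ptr(handle);
  TcnReg* t = dynamic_cast<TcnReg*>(ptr->net.get());
  if (!t) Rcpp::stop("receptive field is defined for the TCN baseline");
  return t->receptive_field();
}
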