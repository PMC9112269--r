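// Three-branch late-fusion CNN for radar-image regression.
//
// Per branch: depth x (valid 3x3 convolution -> ReLU -> 2x2 average pooling,
// stride 2, floor). Branch outputs are flattened, concatenated (the CAT
// layer), passed through one fully connected ReLU layer and a single-unit
// linear regression head. Training: minibatch Adam on the MSE of z-scored
// targets. Everything is deterministic given the initial weights and the
// epoch permutations supplied from R.
//
// Internals run in single precision with one im2col + GEMM per
// layer/branch/minibatch and preallocated per-layer workspaces; weights
// cross the R boundary as doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Spec {
  int depth, filters, fc, n_branches;
  int H, W, C;
};

// input spatial size of layer l (hs/ws hold post-pool sizes)
inline int in_h(const Spec& sp, const std::vector<int>& hs, int l) {
  return l == 0 ? sp.H : hs[l - 1];
}
inline int in_w(const Spec& sp, const std::vector<int>& ws, int l) {
  return l == 0 ? sp.W : ws[l - 1];
}

void block_sizes(const Spec& sp, std::vector<int>& hs, std::vector<int>& ws) {
  int h = sp.H, w = sp.W;
  hs.clear(); ws.clear();
  for (int l = 0; l < sp.depth; ++l) {
    h -= 2; w -= 2;              // valid 3x3 conv
    if (h < 1 || w < 1) Rcpp::stop("pooled size < 1: input too small for depth");
    h /= 2; w /= 2;              // 2x2 average pool, stride 2, floor
    if (h < 1 || w < 1) Rcpp::stop("pooled size < 1: input too small for depth");
    hs.push_back(h); ws.push_back(w);
  }
}

// im2col for a valid 3x3 convolution, written into rows [r0, r0+oh*ow) of
// `col`; row r0 + oi + oh*oj, column ch*9 + p*3 + q
void im2col3_into(const fcube& x, fmat& col, uword r0) {
  const int oh = x.n_rows - 2, ow = x.n_cols - 2, C = x.n_slices;
  for (int ch = 0; ch < C; ++ch)
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < 3; ++q) {
        const fmat& s = x.slice(ch);
        float* dst = col.colptr(ch * 9 + p * 3 + q) + r0;
        for (int oj = 0; oj < ow; ++oj)
          std::memcpy(dst + (uword)oj * oh, s.colptr(oj + q) + p,
                      sizeof(float) * oh);
      }
}

// scatter-add the column gradient of one image back to its (zeroed) input
void col2im3_add(fcube& dx, const fmat& dcol, uword r0) {
  const int oh = dx.n_rows - 2, ow = dx.n_cols - 2, C = dx.n_slices;
  for (int ch = 0; ch < C; ++ch)
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < 3; ++q) {
        fmat& s = dx.slice(ch);
        const float* src = dcol.colptr(ch * 9 + p * 3 + q) + r0;
        for (int oj = 0; oj < ow; ++oj) {
          float* dst = s.colptr(oj + q) + p;
          const float* c = src + (uword)oj * oh;
          for (int oi = 0; oi < oh; ++oi) dst[oi] += c[oi];
        }
      }
}

// 2x2 average pooling of one image's activation rows (rows r0.. of A)
void avgpool2(const fmat& A, uword r0, int oh, int ow, fcube& out) {
  const int F = A.n_cols, ph = oh / 2, pw = ow / 2;
  for (int f = 0; f < F; ++f) {
    const float* a = A.colptr(f) + r0;
    fmat& o = out.slice(f);
    for (int j = 0; j < pw; ++j) {
      const float* c0 = a + (uword)(2 * j) * oh;
      const float* c1 = a + (uword)(2 * j + 1) * oh;
      float* dst = o.colptr(j);
      for (int i = 0; i < ph; ++i)
        dst[i] = 0.25f * (c0[2 * i] + c0[2 * i + 1] + c1[2 * i] + c1[2 * i + 1]);
    }
  }
}

// adjoint of avgpool2, overwriting one image's rows of dA (edge rows/cols
// dropped by the floor get zeros)
void avgpool2_back(const fcube& dpool, fmat& dA, uword r0, int oh, int ow) {
  const int F = dpool.n_slices, ph = dpool.n_rows, pw = dpool.n_cols;
  for (int f = 0; f < F; ++f) {
    float* a = dA.colptr(f) + r0;
    const fmat& d = dpool.slice(f);
    for (int j = 0; j < pw; ++j) {
      float* c0 = a + (uword)(2 * j) * oh;
      float* c1 = a + (uword)(2 * j + 1) * oh;
      const float* src = d.colptr(j);
      for (int i = 0; i < ph; ++i) {
        const float g = 0.25f * src[i];
        c0[2 * i] = g; c0[2 * i + 1] = g; c1[2 * i] = g; c1[2 * i + 1] = g;
      }
      if (oh > 2 * ph) c0[oh - 1] = c1[oh - 1] = 0.0f;
    }
    if (ow > 2 * pw)
      std::memset(a + (uword)(2 * pw) * oh, 0, sizeof(float) * oh);
  }
}

// image (item n, branch b) from the flat 8-bit data, scaled to [-0.5, 0.5]
void load_image(const int* d, const Spec& sp, int n, int b, fcube& x) {
  x.set_size(sp.H, sp.W, sp.C);
  const R_xlen_t plane = (R_xlen_t)sp.H * sp.W;
  const R_xlen_t base = plane * sp.C * ((R_xlen_t)sp.n_branches * n + b);
  for (int ch = 0; ch < sp.C; ++ch) {
    float* dst = x.slice(ch).memptr();
    const int* src = d + base + plane * ch;
    for (R_xlen_t t = 0; t < plane; ++t)
      dst[t] = (float)src[t] / 255.0f - 0.5f;
  }
}

struct Weights {
  std::vector<std::vector<fmat>> cw;   // [branch][layer] (9*C_in) x F
  std::vector<std::vector<frowvec>> cb;
  fmat fc_w;      // D x fc
  frowvec fc_b;   // fc
  fvec out_w;     // fc
  float out_b;
  void zero() {
    for (auto& b : cw) for (auto& m : b) m.zeros();
    for (auto& b : cb) for (auto& m : b) m.zeros();
    fc_w.zeros(); fc_b.zeros(); out_w.zeros(); out_b = 0;
  }
};

Weights weights_from_list(const Rcpp::List& wl, const Spec& sp) {
  Weights w;
  Rcpp::List cw = wl["conv_w"], cb = wl["conv_b"];
  for (int b = 0; b < sp.n_branches; ++b) {
    Rcpp::List cwb = cw[b], cbb = cb[b];
    std::vector<fmat> ws; std::vector<frowvec> bs;
    for (int l = 0; l < sp.depth; ++l) {
      ws.push_back(conv_to<fmat>::from(Rcpp::as<mat>(cwb[l])));
      bs.push_back(conv_to<frowvec>::from(Rcpp::as<rowvec>(cbb[l])));
    }
    w.cw.push_back(ws); w.cb.push_back(bs);
  }
  w.fc_w = conv_to<fmat>::from(Rcpp::as<mat>(wl["fc_w"]));
  w.fc_b = conv_to<frowvec>::from(Rcpp::as<rowvec>(wl["fc_b"]));
  w.out_w = conv_to<fvec>::from(Rcpp::as<vec>(wl["out_w"]));
  w.out_b = (float)Rcpp::as<double>(wl["out_b"]);
  return w;
}

Rcpp::List weights_to_list(const Weights& w, const Spec& sp) {
  Rcpp::List cw(sp.n_branches), cb(sp.n_branches);
  for (int b = 0; b < sp.n_branches; ++b) {
    Rcpp::List cwb(sp.depth), cbb(sp.depth);
    for (int l = 0; l < sp.depth; ++l) {
      cwb[l] = Rcpp::wrap(conv_to<mat>::from(w.cw[b][l]));
      cbb[l] = Rcpp::wrap(conv_to<vec>::from(w.cb[b][l].t()));
    }
    cw[b] = cwb; cb[b] = cbb;
  }
  return Rcpp::List::create(
    Rcpp::Named("conv_w") = cw, Rcpp::Named("conv_b") = cb,
    Rcpp::Named("fc_w") = Rcpp::wrap(conv_to<mat>::from(w.fc_w)),
    Rcpp::Named("fc_b") = Rcpp::wrap(conv_to<vec>::from(w.fc_b.t())),
    Rcpp::Named("out_w") = Rcpp::wrap(conv_to<vec>::from(w.out_w)),
    Rcpp::Named("out_b") = (double)w.out_b);
}

Spec spec_from_lists(const Rcpp::List& spec, const Rcpp::IntegerVector& dims) {
  Spec sp;
  sp.depth = Rcpp::as<int>(spec["depth"]);
  sp.filters = Rcpp::as<int>(spec["n_filters"]);
  sp.fc = Rcpp::as<int>(spec["fc_out"]);
  sp.n_branches = Rcpp::as<int>(spec["n_branches"]);
  sp.H = dims[0]; sp.W = dims[1]; sp.C = dims[2];
  if (dims[3] != sp.n_branches) Rcpp::stop("data branch count does not match spec");
  return sp;
}

// preallocated per-layer buffers, reused across minibatches
struct Workspace {
  std::vector<std::vector<fmat>> col, act;   // [branch][layer]
  std::vector<fmat> dA, dcol;                // [layer]
  std::vector<fcube> cur, dpool;             // per image, reused
  fmat X;
  Workspace(const Spec& sp, const std::vector<int>& hs,
            const std::vector<int>& ws, int Bmax, uword Db) {
    col.resize(sp.n_branches); act.resize(sp.n_branches);
    dA.resize(sp.depth); dcol.resize(sp.depth);
    for (int l = 0; l < sp.depth; ++l) {
      const uword ohw = (uword)(in_h(sp, hs, l) - 2) * (in_w(sp, ws, l) - 2);
      const int cin = l == 0 ? sp.C : sp.filters;
      for (int b = 0; b < sp.n_branches; ++b) {
        col[b].push_back(fmat(ohw * Bmax, 9 * cin));
        act[b].push_back(fmat(ohw * Bmax, sp.filters));
      }
      dA[l].set_size(ohw * Bmax, sp.filters);
      dcol[l].set_size(ohw * Bmax, 9 * cin);
    }
    cur.resize(Bmax); dpool.resize(Bmax);
    X.set_size(Bmax, Db * sp.n_branches);
  }
};

// forward one branch for items `items`, filling rows 0..B-1 of ws.X
void branch_forward(const int* data, const std::vector<int>& items,
                    const Weights& w, int b, const Spec& sp,
                    const std::vector<int>& hs, const std::vector<int>& ws_,
                    uword Db, Workspace& ws) {
  const int B = items.size();
  for (int i = 0; i < B; ++i) load_image(data, sp, items[i], b, ws.cur[i]);
  for (int l = 0; l < sp.depth; ++l) {
    const int oh = in_h(sp, hs, l) - 2, ow = in_w(sp, ws_, l) - 2;
    const uword ohw = (uword)oh * ow;
    fmat col(ws.col[b][l].memptr(), ohw * B, ws.col[b][l].n_cols, false, true);
    for (int i = 0; i < B; ++i) im2col3_into(ws.cur[i], col, ohw * i);
    fmat A(ws.act[b][l].memptr(), ohw * B, sp.filters, false, true);
    A = col * w.cw[b][l];
    A.each_row() += w.cb[b][l];
    A.clamp(0.0f, std::numeric_limits<float>::max());   // ReLU
    for (int i = 0; i < B; ++i) {
      ws.cur[i].set_size(hs[l], ws_[l], sp.filters);
      avgpool2(A, ohw * i, oh, ow, ws.cur[i]);
    }
  }
  for (int i = 0; i < B; ++i)
    ws.X(span(i, i), span(Db * b, Db * (b + 1) - 1)) =
      fmat(ws.cur[i].memptr(), 1, Db);
}

vec forward_pass(const int* data, const std::vector<int>& items,
                 const Weights& w, const Spec& sp, const std::vector<int>& hs,
                 const std::vector<int>& ws_, uword Db, Workspace& ws,
                 fmat& Hpre_out, fmat& Hfc_out) {
  const int B = items.size();
  for (int b = 0; b < sp.n_branches; ++b)
    branch_forward(data, items, w, b, sp, hs, ws_, Db, ws);
  fmat Xb = ws.X.rows(0, B - 1);
  Hpre_out = Xb * w.fc_w;
  Hpre_out.each_row() += w.fc_b;
  Hfc_out = Hpre_out;
  Hfc_out.clamp(0.0f, std::numeric_limits<float>::max());
  return conv_to<vec>::from(Hfc_out * w.out_w + w.out_b);
}

} // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cnn_forward(Rcpp::IntegerVector data,
                                Rcpp::IntegerVector dims, Rcpp::List weights,
                                Rcpp::List spec, Rcpp::IntegerVector idx) {
  Spec sp = spec_from_lists(spec, dims);
  Weights w = weights_from_list(weights, sp);
  std::vector<int> hs, ws_;
  block_sizes(sp, hs, ws_);
  const uword Db = (uword)hs[sp.depth - 1] * ws_[sp.depth - 1] * sp.filters;
  const int* d = INTEGER(data);
  const int chunk = std::min<int>(16, idx.size());
  Workspace wk(sp, hs, ws_, chunk, Db);
  Rcpp::NumericVector out(idx.size());
  for (int start = 0; start < idx.size(); start += chunk) {
    const int B = std::min<int>(chunk, idx.size() - start);
    std::vector<int> items(B);
    for (int i = 0; i < B; ++i) items[i] = idx[start + i] - 1;
    fmat Hpre, Hfc;
    vec yhat = forward_pass(d, items, w, sp, hs, ws_, Db, wk, Hpre, Hfc);
    for (int i = 0; i < B; ++i) out[start + i] = yhat[i];
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_train(Rcpp::IntegerVector data, Rcpp::IntegerVector dims,
                     Rcpp::NumericVector y, Rcpp::List spec, Rcpp::List weights,
                     Rcpp::IntegerMatrix perm, double lr, int minibatch,
                     double beta1_, double beta2_, double eps_) {
  Spec sp = spec_from_lists(spec, dims);
  Weights w = weights_from_list(weights, sp);
  const float beta1 = beta1_, beta2 = beta2_, eps = eps_, flr = lr;
  const int epochs = perm.ncol();
  const int N = perm.nrow();
  std::vector<int> hs, ws_;
  block_sizes(sp, hs, ws_);
  const uword Db = (uword)hs[sp.depth - 1] * ws_[sp.depth - 1] * sp.filters;
  const int* dptr = INTEGER(data);
  const int Bmax = std::min(minibatch, N);
  Workspace wk(sp, hs, ws_, Bmax, Db);

  Weights m = w, v = w;
  m.zero(); v.zero();
  long step = 0;

  auto adam = [&](fmat& W, fmat& M, fmat& V, const fmat& G, float bc1, float bc2) {
    M = beta1 * M + (1 - beta1) * G;
    V = beta2 * V + (1 - beta2) * square(G);
    W -= flr * (M / bc1) / (sqrt(V / bc2) + eps);
  };
  auto adam_row = [&](frowvec& W, frowvec& M, frowvec& V, const frowvec& G,
                      float bc1, float bc2) {
    M = beta1 * M + (1 - beta1) * G;
    V = beta2 * V + (1 - beta2) * square(G);
    W -= flr * (M / bc1) / (sqrt(V / bc2) + eps);
  };

  Rcpp::NumericVector history(epochs);
  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0; int n_batches = 0;
    for (int start = 0; start < N; start += minibatch) {
      const int B = std::min(minibatch, N - start);
      std::vector<int> items(B);
      vec yb(B);
      for (int i = 0; i < B; ++i) {
        items[i] = perm(start + i, e) - 1;
        yb[i] = y[items[i]];
      }
      fmat Hpre, Hfc;
      vec yhat = forward_pass(dptr, items, w, sp, hs, ws_, Db, wk, Hpre, Hfc);
      vec diff = yhat - yb;
      loss_sum += mean(square(diff)); ++n_batches;

      // ---- backward ----
      fvec dyhat = conv_to<fvec>::from(2.0 * diff / B);
      fvec g_out_w = Hfc.t() * dyhat;
      float g_out_b = accu(dyhat);
      fmat dH = dyhat * w.out_w.t();
      dH.elem(find(Hpre <= 0)).zeros();
      fmat Xb = wk.X.rows(0, B - 1);
      fmat g_fc_w = Xb.t() * dH;
      frowvec g_fc_b = sum(dH, 0);
      fmat dX = dH * w.fc_w.t();

      ++step;
      const float bc1 = 1 - std::pow(beta1, (float)step);
      const float bc2 = 1 - std::pow(beta2, (float)step);

      for (int b = 0; b < sp.n_branches; ++b) {
        for (int i = 0; i < B; ++i) {
          wk.dpool[i].set_size(hs[sp.depth - 1], ws_[sp.depth - 1], sp.filters);
          fmat row = dX.submat(i, Db * b, i, Db * (b + 1) - 1);
          std::memcpy(wk.dpool[i].memptr(), row.memptr(), sizeof(float) * Db);
        }
        for (int l = sp.depth - 1; l >= 0; --l) {
          const int oh = in_h(sp, hs, l) - 2, ow = in_w(sp, ws_, l) - 2;
          const uword ohw = (uword)oh * ow;
          fmat dA(wk.dA[l].memptr(), ohw * B, sp.filters, false, true);
          for (int i = 0; i < B; ++i)
            avgpool2_back(wk.dpool[i], dA, ohw * i, oh, ow);
          // ReLU mask from the stored post-activation values
          {
            const float* a = wk.act[b][l].memptr();
            float* g = dA.memptr();
            const uword nel = ohw * B * (uword)sp.filters;
            for (uword t = 0; t < nel; ++t) if (a[t] == 0.0f) g[t] = 0.0f;
          }
          fmat col(wk.col[b][l].memptr(), ohw * B, wk.col[b][l].n_cols,
                   false, true);
          fmat g_w = col.t() * dA;
          frowvec g_b = sum(dA, 0);
          if (l > 0) {
            fmat dcol(wk.dcol[l].memptr(), ohw * B, wk.dcol[l].n_cols,
                      false, true);
            dcol = dA * w.cw[b][l].t();
            for (int i = 0; i < B; ++i) {
              wk.dpool[i].zeros(oh + 2, ow + 2, sp.filters);
              col2im3_add(wk.dpool[i], dcol, ohw * i);
            }
          }
          adam(w.cw[b][l], m.cw[b][l], v.cw[b][l], g_w, bc1, bc2);
          adam_row(w.cb[b][l], m.cb[b][l], v.cb[b][l], g_b, bc1, bc2);
        }
      }
      adam(w.fc_w, m.fc_w, v.fc_w, g_fc_w, bc1, bc2);
      adam_row(w.fc_b, m.fc_b, v.fc_b, g_fc_b, bc1, bc2);
      {
        fvec& M = m.out_w; fvec& V = v.out_w;
        M = beta1 * M + (1 - beta1) * g_out_w;
        V = beta2 * V + (1 - beta2) * square(g_out_w);
        w.out_w -= flr * (M / bc1) / (sqrt(V / bc2) + eps);
      }
      m.out_b = beta1 * m.out_b + (1 - beta1) * g_out_b;
      v.out_b = beta2 * v.out_b + (1 - beta2) * g_out_b * g_out_b;
      w.out_b -= flr * (m.out_b / bc1) / (std::sqrt(v.out_b / bc2) + eps);
    }
    history[e] = loss_sum / n_batches;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("weights") = weights_to_list(w, sp),
                            Rcpp::Named("history") = history);
}
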