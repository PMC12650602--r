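// Single-precision forward/backward engine for the dual-branch beat
// classifier (residual CNN + Transformer encoder + gated fusion). The
// network is small and static, so gradients are written out by hand layer
// by layer; all heavy lifting is BLAS sgemm through Armadillo. A pure-R
// double-precision reference path (R/model.R) mirrors this computation and
// the two are parity-tested.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <unordered_map>
#include <malloc.h>
#include <string>
#include <vector>

using namespace arma;

typedef std::unordered_map<std::string, fmat> PMap;

static const float BN_EPS = 1e-5f;
static const float LN_EPS = 1e-5f;

// ---------------------------------------------------------------- utils --

static PMap list_to_pmap(const Rcpp::List& lst) {
  PMap out;
  if (lst.size() == 0) return out;
  Rcpp::CharacterVector names = lst.names();
  for (int i = 0; i < lst.size(); ++i) {
    Rcpp::NumericVector v(lst[i]);
    fmat m;
    if (v.hasAttribute("dim")) {
      Rcpp::IntegerVector d = v.attr("dim");
      m.set_size(d[0], d[1]);
    } else {
      m.set_size(v.size(), 1);
    }
    std::copy(v.begin(), v.end(), m.memptr());
    out[std::string(names[i])] = std::move(m);
  }
  return out;
}

// Convert gradients back to R, matching each parameter's original shape.
static Rcpp::List pmap_to_list(const PMap& grads, const Rcpp::List& tmpl) {
  if (tmpl.size() == 0) return Rcpp::List();
  Rcpp::CharacterVector names = tmpl.names();
  Rcpp::List out(tmpl.size());
  for (int i = 0; i < tmpl.size(); ++i) {
    std::string nm(names[i]);
    PMap::const_iterator it = grads.find(nm);
    if (it == grads.end()) Rcpp::stop("missing gradient for %s", nm);
    const fmat& g = it->second;
    Rcpp::NumericVector tv(tmpl[i]);
    Rcpp::NumericVector v(g.n_elem);
    std::copy(g.begin(), g.end(), v.begin());
    if (tv.hasAttribute("dim")) v.attr("dim") = tv.attr("dim");
    out[i] = v;
  }
  out.names() = names;
  return out;
}

static const fmat& P(const PMap& p, const std::string& nm) {
  PMap::const_iterator it = p.find(nm);
  if (it == p.end()) Rcpp::stop("missing parameter %s", nm);
  return it->second;
}
static fvec Pv(const PMap& p, const std::string& nm) {
  return fvec(P(p, nm).col(0));
}

// xorshift128+ for dropout masks (fast, seeded per batch)
struct XRng {
  uint64_t s0, s1;
  explicit XRng(uint64_t seed) {
    s0 = seed * 2685821657736338717ULL + 1ULL;
    s1 = (seed ^ 0x9E3779B97F4A7C15ULL) * 6364136223846793005ULL + 1442695040888963407ULL;
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y; x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  float unif() { return (next() >> 40) * (1.0f / 16777216.0f); }
};

static fmat dropout_mask(int nr, int nc, float p, XRng& rng) {
  fmat m(nr, nc);
  const float scale = 1.0f / (1.0f - p);
  float* ptr = m.memptr();
  const uword n = m.n_elem;
  for (uword i = 0; i < n; ++i) ptr[i] = (rng.unif() >= p) ? scale : 0.0f;
  return m;
}

// ------------------------------------------------------------- conv1d ----

struct ConvCache {
  fmat xpad;   // [C_in x B*Tp]
  uvec base;   // window start column per output position
  int B, T_in, T_out, pad, stride, c_in, k;
};

// Stride-1 convolutions run as k GEMMs on contiguous shifted views of the
// padded buffer (output columns that straddle sample boundaries are junk
// and dropped when gathering per-sample ranges); strided convolutions use
// an indexed column gather instead.
static fmat conv_fwd(const fmat& x, int B, int T_in, const fmat& W,
                     const fvec& b, int stride, int pad, ConvCache& cc) {
  const int c_in = x.n_rows;
  const int k = W.n_cols / c_in;
  const int Tp = T_in + 2 * pad;
  const int T_out = (Tp - k) / stride + 1;
  cc.B = B; cc.T_in = T_in; cc.T_out = T_out; cc.pad = pad;
  cc.stride = stride; cc.c_in = c_in; cc.k = k;
  cc.xpad.zeros(c_in, (uword)B * Tp);
  for (int s = 0; s < B; ++s) {
    cc.xpad.cols((uword)s * Tp + pad, (uword)s * Tp + pad + T_in - 1) =
      x.cols((uword)s * T_in, (uword)(s + 1) * T_in - 1);
  }
  fmat y(W.n_rows, (uword)B * T_out);
  if (stride == 1) {
    const uword Nv = (uword)B * Tp - (k - 1);
    fmat yfull = W.cols(0, c_in - 1) * cc.xpad.cols(0, Nv - 1);
    for (int j = 1; j < k; ++j) {
      yfull += W.cols((uword)j * c_in, (uword)(j + 1) * c_in - 1) *
               cc.xpad.cols(j, j + Nv - 1);
    }
    for (int s = 0; s < B; ++s) {
      y.cols((uword)s * T_out, (uword)(s + 1) * T_out - 1) =
        yfull.cols((uword)s * Tp, (uword)s * Tp + T_out - 1);
    }
    y.each_col() += b;
    return y;
  }
  cc.base.set_size((uword)B * T_out);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < T_out; ++t)
      cc.base[(uword)s * T_out + t] = (uword)s * Tp + (uword)t * stride;
  y.each_col() = b;
  for (int j = 0; j < k; ++j) {
    fmat xj = cc.xpad.cols(cc.base + j);
    y += W.cols((uword)j * c_in, (uword)(j + 1) * c_in - 1) * xj;
  }
  return y;
}

static fmat conv_bwd(const fmat& dY, const fmat& W, const ConvCache& cc,
                     fmat& dW, fvec& db) {
  db = sum(dY, 1);
  dW.set_size(W.n_rows, W.n_cols);
  const int Tp = cc.T_in + 2 * cc.pad;
  fmat dxpad(cc.xpad.n_rows, cc.xpad.n_cols, fill::zeros);
  if (cc.stride == 1) {
    const uword Nv = (uword)cc.B * Tp - (cc.k - 1);
    // scatter dY back onto the padded grid (junk columns stay zero)
    fmat dyfull(dY.n_rows, Nv, fill::zeros);
    for (int s = 0; s < cc.B; ++s) {
      dyfull.cols((uword)s * Tp, (uword)s * Tp + cc.T_out - 1) =
        dY.cols((uword)s * cc.T_out, (uword)(s + 1) * cc.T_out - 1);
    }
    for (int j = 0; j < cc.k; ++j) {
      dW.cols((uword)j * cc.c_in, (uword)(j + 1) * cc.c_in - 1) =
        dyfull * cc.xpad.cols(j, j + Nv - 1).t();
      dxpad.cols(j, j + Nv - 1) +=
        W.cols((uword)j * cc.c_in, (uword)(j + 1) * cc.c_in - 1).t() * dyfull;
    }
  } else {
    for (int j = 0; j < cc.k; ++j) {
      fmat xj = cc.xpad.cols(cc.base + j);
      dW.cols((uword)j * cc.c_in, (uword)(j + 1) * cc.c_in - 1) = dY * xj.t();
      fmat dxj = W.cols((uword)j * cc.c_in, (uword)(j + 1) * cc.c_in - 1).t() * dY;
      dxpad.cols(cc.base + j) += dxj;
    }
  }
  fmat dx(cc.c_in, (uword)cc.B * cc.T_in);
  for (int s = 0; s < cc.B; ++s) {
    dx.cols((uword)s * cc.T_in, (uword)(s + 1) * cc.T_in - 1) =
      dxpad.cols((uword)s * Tp + cc.pad, (uword)s * Tp + cc.pad + cc.T_in - 1);
  }
  return dx;
}

// Apply ReLU in place and return the 0/1 mask in one pass.
static fmat relu_mask(fmat& h) {
  fmat m(h.n_rows, h.n_cols);
  float* hp = h.memptr();
  float* mp = m.memptr();
  const uword n = h.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (hp[i] > 0.0f) mp[i] = 1.0f;
    else { mp[i] = 0.0f; hp[i] = 0.0f; }
  }
  return m;
}

// ---------------------------------------------------------- batch norm ---

struct BNCache { fmat xhat; fvec istd; };

static fmat bn_fwd(const fmat& x, const fvec& gamma, const fvec& beta,
                   bool training, fvec& rmean, fvec& rvar, float momentum,
                   BNCache& bc) {
  fvec mu, var;
  if (training) {
    mu = mean(x, 1);
    fmat xc = x.each_col() - mu;
    var = mean(square(xc), 1);
    bc.istd = 1.0f / sqrt(var + BN_EPS);
    bc.xhat = xc.each_col() % bc.istd;
    rmean = (1.0f - momentum) * rmean + momentum * mu;
    rvar = (1.0f - momentum) * rvar + momentum * var;
  } else {
    bc.istd = 1.0f / sqrt(rvar + BN_EPS);
    bc.xhat = (x.each_col() - rmean);
    bc.xhat.each_col() %= bc.istd;
  }
  fmat y = bc.xhat.each_col() % gamma;
  y.each_col() += beta;
  return y;
}

static fmat bn_bwd(const fmat& dy, const fvec& gamma, const BNCache& bc,
                   fvec& dgamma, fvec& dbeta) {
  dgamma = sum(dy % bc.xhat, 1);
  dbeta = sum(dy, 1);
  fmat dxhat = dy.each_col() % gamma;
  fvec m1 = mean(dxhat, 1);
  fvec m2 = mean(dxhat % bc.xhat, 1);
  fmat dx = dxhat.each_col() - m1;
  dx -= bc.xhat.each_col() % m2;
  dx.each_col() %= bc.istd;
  return dx;
}

// ---------------------------------------------------------- layer norm ---

struct LNCache { fmat xhat; frowvec istd; };

static fmat ln_fwd(const fmat& x, const fvec& gamma, const fvec& beta,
                   LNCache& lc) {
  frowvec mu = mean(x, 0);
  fmat xc = x.each_row() - mu;
  frowvec var = mean(square(xc), 0);
  lc.istd = 1.0f / sqrt(var + LN_EPS);
  lc.xhat = xc.each_row() % lc.istd;
  fmat y = lc.xhat.each_col() % gamma;
  y.each_col() += beta;
  return y;
}

static fmat ln_bwd(const fmat& dy, const fvec& gamma, const LNCache& lc,
                   fvec& dgamma, fvec& dbeta) {
  dgamma = sum(dy % lc.xhat, 1);
  dbeta = sum(dy, 1);
  fmat dxhat = dy.each_col() % gamma;
  frowvec m1 = mean(dxhat, 0);
  frowvec m2 = mean(dxhat % lc.xhat, 0);
  fmat dx = dxhat.each_row() - m1;
  fmat t2 = lc.xhat;
  t2.each_row() %= m2;
  dx -= t2;
  dx.each_row() %= lc.istd;
  return dx;
}

// ------------------------------------------------------- residual block --

struct ResCache {
  ConvCache c1, c2, cd;
  BNCache b1, b2;
  fmat relu_mid, relu_out;  // masks (0/1)
  bool has_down;
};

static fmat res_fwd(const fmat& x, int B, int T_in, const std::string& nm,
                    const PMap& p, PMap& st, bool training, float momentum,
                    int stride, ResCache& rc, int& T_out) {
  fvec rm1 = Pv(st, nm + ".bn1.mean"), rv1 = Pv(st, nm + ".bn1.var");
  fvec rm2 = Pv(st, nm + ".bn2.mean"), rv2 = Pv(st, nm + ".bn2.var");
  fmat h = conv_fwd(x, B, T_in, P(p, nm + ".conv1.W"), Pv(p, nm + ".conv1.b"),
                    stride, 1, rc.c1);
  h = bn_fwd(h, Pv(p, nm + ".bn1.gamma"), Pv(p, nm + ".bn1.beta"), training,
             rm1, rv1, momentum, rc.b1);
  rc.relu_mid = relu_mask(h);
  fmat f = conv_fwd(h, B, rc.c1.T_out, P(p, nm + ".conv2.W"),
                    Pv(p, nm + ".conv2.b"), 1, 1, rc.c2);
  f = bn_fwd(f, Pv(p, nm + ".bn2.gamma"), Pv(p, nm + ".bn2.beta"), training,
             rm2, rv2, momentum, rc.b2);
  rc.has_down = p.count(nm + ".down.W") > 0;
  fmat skip;
  if (rc.has_down) {
    skip = conv_fwd(x, B, T_in, P(p, nm + ".down.W"), Pv(p, nm + ".down.b"),
                    stride, 0, rc.cd);
  } else {
    skip = x;
  }
  fmat y = f + skip;
  rc.relu_out = relu_mask(y);
  if (training) {
    st[nm + ".bn1.mean"] = rm1; st[nm + ".bn1.var"] = rv1;
    st[nm + ".bn2.mean"] = rm2; st[nm + ".bn2.var"] = rv2;
  }
  T_out = rc.c2.T_out;
  return y;
}

static fmat res_bwd(const fmat& dy_in, const std::string& nm, const PMap& p,
                    const ResCache& rc, PMap& g) {
  fmat dy = dy_in % rc.relu_out;
  // skip path
  fmat dx;
  if (rc.has_down) {
    fmat dWd; fvec dbd;
    dx = conv_bwd(dy, P(p, nm + ".down.W"), rc.cd, dWd, dbd);
    g[nm + ".down.W"] = dWd; g[nm + ".down.b"] = dbd;
  } else {
    dx = dy;
  }
  // main path: bn2 <- conv2 <- relu <- bn1 <- conv1
  fvec dg2, db2;
  fmat dh = bn_bwd(dy, Pv(p, nm + ".bn2.gamma"), rc.b2, dg2, db2);
  g[nm + ".bn2.gamma"] = dg2; g[nm + ".bn2.beta"] = db2;
  fmat dW2; fvec dbc2;
  dh = conv_bwd(dh, P(p, nm + ".conv2.W"), rc.c2, dW2, dbc2);
  g[nm + ".conv2.W"] = dW2; g[nm + ".conv2.b"] = dbc2;
  dh %= rc.relu_mid;
  fvec dg1, db1;
  dh = bn_bwd(dh, Pv(p, nm + ".bn1.gamma"), rc.b1, dg1, db1);
  g[nm + ".bn1.gamma"] = dg1; g[nm + ".bn1.beta"] = db1;
  fmat dW1; fvec dbc1;
  dh = conv_bwd(dh, P(p, nm + ".conv1.W"), rc.c1, dW1, dbc1);
  g[nm + ".conv1.W"] = dW1; g[nm + ".conv1.b"] = dbc1;
  return dx + dh;
}

// --------------------------------------------------------- transformer ---

struct TrCache {
  fmat h_in;          // layer input [d x BL]
  fcube qc, kc, vc;   // projections as contiguous [dk x L] per-(sample,head) slices
  fmat O;             // attention output [d x BL]
  fmat attn_drop, ffn_relu, ffn_act_drop, ffn_out_drop;
  fmat h_mid;         // after first residual+LN
  fmat ffn_h;         // ReLU(W1 h_mid + b1) after dropout
  LNCache ln1, ln2;
};

// Reorder between the [d x B*L] column-sample-major layout and contiguous
// per-(sample, head) [dk x L] cube slices (slice index s*H + h).
static void mat_to_heads(const fmat& M, int B, int L, int H, int dk,
                         fcube& C) {
  C.set_size(dk, L, (uword)B * H);
  for (int s = 0; s < B; ++s)
    for (int hh = 0; hh < H; ++hh)
      C.slice((uword)s * H + hh) =
        M.submat((uword)hh * dk, (uword)s * L,
                 (uword)(hh + 1) * dk - 1, (uword)(s + 1) * L - 1);
}

static void heads_to_mat(const fcube& C, int B, int L, int H, int dk,
                         fmat& M) {
  M.set_size((uword)H * dk, (uword)B * L);
  for (int s = 0; s < B; ++s)
    for (int hh = 0; hh < H; ++hh)
      M.submat((uword)hh * dk, (uword)s * L,
               (uword)(hh + 1) * dk - 1, (uword)(s + 1) * L - 1) =
        C.slice((uword)s * H + hh);
}

// Column-wise softmax of K^T Q / sqrt(dk) for one (sample, head) slice.
static fmat attn_probs(const fmat& Kb, const fmat& Qb, float iscale) {
  fmat S = Kb.t() * Qb;
  S *= iscale;
  S.each_row() -= max(S, 0);
  S = exp(S);
  S.each_row() /= sum(S, 0);
  return S;
}

// ------------------------------------------------------------ the model --

struct Features {
  fmat c_feat, t_feat, ct, tt, gate, fused, probs;
};

// Variant codes: 0 full, 1 cnn_only, 2 transformer_only, 3 concat_no_gate
static bool has_cnn(int v) { return v == 0 || v == 1 || v == 3; }
static bool has_tr(int v) { return v == 0 || v == 2 || v == 3; }
static bool has_proj(int v) { return v == 0 || v == 3; }

// Runs forward (and optionally backward). When y has length B the
// cross-entropy loss and gradients are computed.
static Rcpp::List engine_run(const Rcpp::List& params_r,
                             const Rcpp::List& state_r,
                             const Rcpp::NumericMatrix& pe_r,
                             const Rcpp::NumericMatrix& X_r,
                             const Rcpp::IntegerVector& y_r,
                             int variant, int n_layers, int n_heads,
                             bool training, double drop_tr, double drop_clf,
                             int seed, double momentum, bool want_features) {
  // keep large temporaries on the heap instead of per-allocation mmap;
  // repeated mmap/munmap + page faults dominate runtime otherwise
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
  const int B = X_r.nrow();
  const int L = X_r.ncol();
  const bool backward = y_r.size() > 0;
  PMap p = list_to_pmap(params_r);
  PMap st = list_to_pmap(state_r);
  PMap stv;  // state as fvec-backed fmat, updated in place via res_fwd
  for (PMap::iterator it = st.begin(); it != st.end(); ++it) stv[it->first] = it->second;
  PMap g;
  XRng rng((uint64_t)(seed < 0 ? -seed : seed) + 7919u);
  const float p_tr = training ? (float)drop_tr : 0.0f;
  const float p_clf = training ? (float)drop_clf : 0.0f;

  // single-channel input layout [1 x B*L], columns sample-major
  fmat x0(1, (uword)B * L);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < L; ++t)
      x0(0, (uword)s * L + t) = (float)X_r(s, t);

  Features ft;

  // ---- CNN branch ----
  ConvCache stem_cc; BNCache stem_bc; fmat stem_relu;
  ResCache rc[3];
  int strides[3] = {1, 2, 1};
  int T_stages[4];
  fmat h_cnn;
  if (has_cnn(variant)) {
    fvec rm = Pv(stv, "stem.bn.mean"), rv = Pv(stv, "stem.bn.var");
    h_cnn = conv_fwd(x0, B, L, P(p, "stem.W"), Pv(p, "stem.b"), 1, 3, stem_cc);
    h_cnn = bn_fwd(h_cnn, Pv(p, "stem.bn.gamma"), Pv(p, "stem.bn.beta"),
                   training, rm, rv, (float)momentum, stem_bc);
    if (training) { stv["stem.bn.mean"] = rm; stv["stem.bn.var"] = rv; }
    stem_relu = relu_mask(h_cnn);
    T_stages[0] = stem_cc.T_out;
    for (int bi = 0; bi < 3; ++bi) {
      char nm[8]; snprintf(nm, sizeof(nm), "res%d", bi + 1);
      h_cnn = res_fwd(h_cnn, B, T_stages[bi], nm, p, stv, training,
                      (float)momentum, strides[bi], rc[bi], T_stages[bi + 1]);
    }
    // global average pool over time
    const int Tf = T_stages[3];
    ft.c_feat.set_size(h_cnn.n_rows, B);
    for (int s = 0; s < B; ++s)
      ft.c_feat.col(s) = mean(h_cnn.cols((uword)s * Tf, (uword)(s + 1) * Tf - 1), 1);
  }

  // ---- Transformer branch ----
  std::vector<TrCache> tc(n_layers);
  fmat pe_t;  // [d x L]
  fmat h_tr;
  const int d = has_tr(variant) ? P(p, "embed.W").n_rows : 0;
  const int dk = has_tr(variant) ? d / n_heads : 0;
  if (has_tr(variant)) {
    pe_t.set_size(d, L);
    for (int t = 0; t < L; ++t)
      for (int j = 0; j < d; ++j) pe_t(j, t) = (float)pe_r(t, j);
    h_tr = P(p, "embed.W") * x0;
    h_tr.each_col() += Pv(p, "embed.b");
    for (int s = 0; s < B; ++s)
      h_tr.cols((uword)s * L, (uword)(s + 1) * L - 1) += pe_t;
    const float iscale = 1.0f / std::sqrt((float)dk);
    for (int li = 0; li < n_layers; ++li) {
      char nm[8]; snprintf(nm, sizeof(nm), "tr%d", li + 1);
      std::string pre(nm);
      TrCache& c = tc[li];
      c.h_in = h_tr;
      {
        fmat M = P(p, pre + ".Wq.W") * h_tr; M.each_col() += Pv(p, pre + ".Wq.b");
        mat_to_heads(M, B, L, n_heads, dk, c.qc);
        M = P(p, pre + ".Wk.W") * h_tr; M.each_col() += Pv(p, pre + ".Wk.b");
        mat_to_heads(M, B, L, n_heads, dk, c.kc);
        M = P(p, pre + ".Wv.W") * h_tr; M.each_col() += Pv(p, pre + ".Wv.b");
        mat_to_heads(M, B, L, n_heads, dk, c.vc);
      }
      {
        fcube oc(dk, L, (uword)B * n_heads);
        for (uword sl = 0; sl < (uword)B * n_heads; ++sl) {
          fmat S = attn_probs(c.kc.slice(sl), c.qc.slice(sl), iscale);
          oc.slice(sl) = c.vc.slice(sl) * S;       // S is [key x query]
        }
        heads_to_mat(oc, B, L, n_heads, dk, c.O);
      }
      fmat a = P(p, pre + ".Wo.W") * c.O;
      a.each_col() += Pv(p, pre + ".Wo.b");
      if (p_tr > 0) { c.attn_drop = dropout_mask(a.n_rows, a.n_cols, p_tr, rng); a %= c.attn_drop; }
      c.h_mid = ln_fwd(c.h_in + a, Pv(p, pre + ".ln1.gamma"),
                       Pv(p, pre + ".ln1.beta"), c.ln1);
      fmat z = P(p, pre + ".ffn1.W") * c.h_mid;
      z.each_col() += Pv(p, pre + ".ffn1.b");
      c.ffn_relu = relu_mask(z);
      if (p_tr > 0) { c.ffn_act_drop = dropout_mask(z.n_rows, z.n_cols, p_tr, rng); z %= c.ffn_act_drop; }
      c.ffn_h = z;
      fmat f2 = P(p, pre + ".ffn2.W") * z;
      f2.each_col() += Pv(p, pre + ".ffn2.b");
      if (p_tr > 0) { c.ffn_out_drop = dropout_mask(f2.n_rows, f2.n_cols, p_tr, rng); f2 %= c.ffn_out_drop; }
      h_tr = ln_fwd(c.h_mid + f2, Pv(p, pre + ".ln2.gamma"),
                    Pv(p, pre + ".ln2.beta"), c.ln2);
    }
    ft.t_feat.set_size(d, B);
    for (int s = 0; s < B; ++s)
      ft.t_feat.col(s) = mean(h_tr.cols((uword)s * L, (uword)(s + 1) * L - 1), 1);
  }

  // ---- fusion ----
  fmat feat, gate_h1;
  if (has_proj(variant)) {
    ft.ct = P(p, "fus.c.W") * ft.c_feat; ft.ct.each_col() += Pv(p, "fus.c.b");
    ft.tt = P(p, "fus.t.W") * ft.t_feat; ft.tt.each_col() += Pv(p, "fus.t.b");
    if (variant == 0) {
      fmat zcat = join_cols(ft.ct, ft.tt);
      gate_h1 = P(p, "fus.gate1.W") * zcat;
      gate_h1.each_col() += Pv(p, "fus.gate1.b");
      gate_h1 %= conv_to<fmat>::from(gate_h1 > 0.0f);  // mask folded below
      fmat gz = P(p, "fus.gate2.W") * gate_h1;
      gz.each_col() += Pv(p, "fus.gate2.b");
      ft.gate = 1.0f / (1.0f + exp(-gz));
      feat = ft.gate % ft.ct + (1.0f - ft.gate) % ft.tt;
    } else {
      feat = join_cols(ft.ct, ft.tt);
    }
  } else if (variant == 1) {
    feat = ft.c_feat;
  } else {
    feat = ft.t_feat;
  }
  ft.fused = feat;

  // ---- classifier ----
  fmat ch = P(p, "clf1.W") * feat;
  ch.each_col() += Pv(p, "clf1.b");
  fmat clf_relu = relu_mask(ch);
  fmat clf_drop;
  if (p_clf > 0) { clf_drop = dropout_mask(ch.n_rows, ch.n_cols, p_clf, rng); ch %= clf_drop; }
  fmat z = P(p, "clf2.W") * ch;
  z.each_col() += Pv(p, "clf2.b");
  z.each_row() -= max(z, 0);
  fmat probs = exp(z);
  probs.each_row() /= sum(probs, 0);
  ft.probs = probs;

  double loss = NA_REAL;
  if (backward) {
    loss = 0.0;
    for (int s = 0; s < B; ++s)
      loss -= std::log(std::max(probs(y_r[s], s), 1e-12f));
    loss /= B;

    // ---- classifier backward ----
    fmat dz = probs;
    for (int s = 0; s < B; ++s) dz(y_r[s], s) -= 1.0f;
    dz /= (float)B;
    g["clf2.W"] = dz * ch.t();
    g["clf2.b"] = sum(dz, 1);
    fmat dch = P(p, "clf2.W").t() * dz;
    if (p_clf > 0) dch %= clf_drop;
    dch %= clf_relu;
    g["clf1.W"] = dch * feat.t();
    g["clf1.b"] = sum(dch, 1);
    fmat dfeat = P(p, "clf1.W").t() * dch;

    fmat dc_feat, dt_feat;
    if (has_proj(variant)) {
      fmat dct, dtt;
      if (variant == 0) {
        fmat dgate = dfeat % (ft.ct - ft.tt);
        dct = dfeat % ft.gate;
        dtt = dfeat % (1.0f - ft.gate);
        fmat dgz = dgate % ft.gate % (1.0f - ft.gate);
        g["fus.gate2.W"] = dgz * gate_h1.t();
        g["fus.gate2.b"] = sum(dgz, 1);
        fmat dg1 = P(p, "fus.gate2.W").t() * dgz;
        dg1 %= conv_to<fmat>::from(gate_h1 > 0.0f);
        fmat zcat = join_cols(ft.ct, ft.tt);
        g["fus.gate1.W"] = dg1 * zcat.t();
        g["fus.gate1.b"] = sum(dg1, 1);
        fmat dzcat = P(p, "fus.gate1.W").t() * dg1;
        dct += dzcat.rows(0, ft.ct.n_rows - 1);
        dtt += dzcat.rows(ft.ct.n_rows, dzcat.n_rows - 1);
      } else {
        dct = dfeat.rows(0, ft.ct.n_rows - 1);
        dtt = dfeat.rows(ft.ct.n_rows, dfeat.n_rows - 1);
      }
      g["fus.c.W"] = dct * ft.c_feat.t();
      g["fus.c.b"] = sum(dct, 1);
      dc_feat = P(p, "fus.c.W").t() * dct;
      g["fus.t.W"] = dtt * ft.t_feat.t();
      g["fus.t.b"] = sum(dtt, 1);
      dt_feat = P(p, "fus.t.W").t() * dtt;
    } else if (variant == 1) {
      dc_feat = dfeat;
    } else {
      dt_feat = dfeat;
    }

    // ---- transformer backward ----
    if (has_tr(variant)) {
      fmat dh(d, (uword)B * L);
      const float invL = 1.0f / (float)L;
      for (int s = 0; s < B; ++s)
        dh.cols((uword)s * L, (uword)(s + 1) * L - 1) =
          repmat(dt_feat.col(s) * invL, 1, L);
      const float iscale = 1.0f / std::sqrt((float)dk);
      for (int li = n_layers - 1; li >= 0; --li) {
        char nm[8]; snprintf(nm, sizeof(nm), "tr%d", li + 1);
        std::string pre(nm);
        TrCache& c = tc[li];
        fvec dgam, dbet;
        fmat dr2 = ln_bwd(dh, Pv(p, pre + ".ln2.gamma"), c.ln2, dgam, dbet);
        g[pre + ".ln2.gamma"] = dgam; g[pre + ".ln2.beta"] = dbet;
        fmat df2 = dr2;
        if (p_tr > 0) df2 %= c.ffn_out_drop;
        g[pre + ".ffn2.W"] = df2 * c.ffn_h.t();
        g[pre + ".ffn2.b"] = sum(df2, 1);
        fmat dzf = P(p, pre + ".ffn2.W").t() * df2;
        if (p_tr > 0) dzf %= c.ffn_act_drop;
        dzf %= c.ffn_relu;
        g[pre + ".ffn1.W"] = dzf * c.h_mid.t();
        g[pre + ".ffn1.b"] = sum(dzf, 1);
        fmat dh_mid = dr2 + P(p, pre + ".ffn1.W").t() * dzf;
        fmat dr1 = ln_bwd(dh_mid, Pv(p, pre + ".ln1.gamma"), c.ln1, dgam, dbet);
        g[pre + ".ln1.gamma"] = dgam; g[pre + ".ln1.beta"] = dbet;
        fmat da = dr1;
        if (p_tr > 0) da %= c.attn_drop;
        g[pre + ".Wo.W"] = da * c.O.t();
        g[pre + ".Wo.b"] = sum(da, 1);
        fmat dOm = P(p, pre + ".Wo.W").t() * da;
        fmat dQ, dK, dV;
        {
          fcube doc;
          mat_to_heads(dOm, B, L, n_heads, dk, doc);
          fcube dqc(dk, L, (uword)B * n_heads), dkc(dk, L, (uword)B * n_heads),
                dvc(dk, L, (uword)B * n_heads);
          fmat Pm(L, L), dPm(L, L), dS(L, L);
          for (uword sl = 0; sl < (uword)B * n_heads; ++sl) {
            // recompute the attention probabilities (bit-identical to the
            // forward pass) instead of caching ~L^2 per slice
            Pm = attn_probs(c.kc.slice(sl), c.qc.slice(sl), iscale);
            const fmat& dOb = doc.slice(sl);
            dPm = c.vc.slice(sl).t() * dOb;         // [L x L]
            dvc.slice(sl) = dOb * Pm.t();
            frowvec colsum = sum(dPm % Pm, 0);
            dS = dPm;
            dS.each_row() -= colsum;
            dS %= Pm;
            dS *= iscale;
            dqc.slice(sl) = c.kc.slice(sl) * dS;
            dkc.slice(sl) = c.qc.slice(sl) * dS.t();
          }
          heads_to_mat(dqc, B, L, n_heads, dk, dQ);
          heads_to_mat(dkc, B, L, n_heads, dk, dK);
          heads_to_mat(dvc, B, L, n_heads, dk, dV);
        }
        g[pre + ".Wq.W"] = dQ * c.h_in.t(); g[pre + ".Wq.b"] = sum(dQ, 1);
        g[pre + ".Wk.W"] = dK * c.h_in.t(); g[pre + ".Wk.b"] = sum(dK, 1);
        g[pre + ".Wv.W"] = dV * c.h_in.t(); g[pre + ".Wv.b"] = sum(dV, 1);
        dh = dr1 + P(p, pre + ".Wq.W").t() * dQ +
             P(p, pre + ".Wk.W").t() * dK + P(p, pre + ".Wv.W").t() * dV;
      }
      g["embed.W"] = dh * x0.t();
      g["embed.b"] = sum(dh, 1);
    }

    // ---- CNN backward ----
    if (has_cnn(variant)) {
      const int Tf = T_stages[3];
      fmat dhc(h_cnn.n_rows, (uword)B * Tf);
      const float invT = 1.0f / (float)Tf;
      for (int s = 0; s < B; ++s)
        dhc.cols((uword)s * Tf, (uword)(s + 1) * Tf - 1) =
          repmat(dc_feat.col(s) * invT, 1, Tf);
      for (int bi = 2; bi >= 0; --bi) {
        char nm[8]; snprintf(nm, sizeof(nm), "res%d", bi + 1);
        dhc = res_bwd(dhc, nm, p, rc[bi], g);
      }
      dhc %= stem_relu;
      fvec dgam, dbet;
      dhc = bn_bwd(dhc, Pv(p, "stem.bn.gamma"), stem_bc, dgam, dbet);
      g["stem.bn.gamma"] = dgam; g["stem.bn.beta"] = dbet;
      fmat dWs; fvec dbs;
      conv_bwd(dhc, P(p, "stem.W"), stem_cc, dWs, dbs);
      g["stem.W"] = dWs; g["stem.b"] = dbs;
    }
  }

  // ---- assemble result ----
  Rcpp::NumericMatrix probs_r(B, probs.n_rows);
  for (int s = 0; s < B; ++s)
    for (uword k = 0; k < probs.n_rows; ++k) probs_r(s, k) = probs(k, s);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("probs") = probs_r,
                                      Rcpp::Named("loss") = loss);
  if (want_features) {
    Rcpp::List fl;
    if (has_cnn(variant)) fl["c"] = Rcpp::wrap(fmat(ft.c_feat.t()));
    if (has_tr(variant)) fl["t"] = Rcpp::wrap(fmat(ft.t_feat.t()));
    if (has_proj(variant)) {
      fl["c_tilde"] = Rcpp::wrap(fmat(ft.ct.t()));
      fl["t_tilde"] = Rcpp::wrap(fmat(ft.tt.t()));
    }
    if (variant == 0) fl["g"] = Rcpp::wrap(fmat(ft.gate.t()));
    fl["f"] = Rcpp::wrap(fmat(ft.fused.t()));
    out["features"] = fl;
  }
  if (backward) {
    out["grads"] = pmap_to_list(g, params_r);
    // updated batch-norm running statistics
    Rcpp::List st_out = pmap_to_list(stv, state_r);
    out["state"] = st_out;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_hctg_forward(Rcpp::List params, Rcpp::List state,
                            Rcpp::NumericMatrix pe, Rcpp::NumericMatrix X,
                            int variant, int n_layers, int n_heads,
                            bool want_features) {
  return engine_run(params, state, pe, X, Rcpp::IntegerVector(0), variant,
                    n_layers, n_heads, false, 0.0, 0.0, 1, 0.1,
                    want_features);
}

// [[Rcpp::export]]
Rcpp::List cpp_hctg_train_batch(Rcpp::List params, Rcpp::List state,
                                Rcpp::NumericMatrix pe, Rcpp::NumericMatrix X,
                                Rcpp::IntegerVector y, int variant,
                                int n_layers, int n_heads, double drop_tr,
                                double drop_clf, int seed, double momentum) {
  if (y.size() != X.nrow()) Rcpp::stop("label/batch size mismatch");
  return engine_run(params, state, pe, X, y, variant, n_layers, n_heads,
                    true, drop_tr, drop_clf, seed, momentum, false);
}
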