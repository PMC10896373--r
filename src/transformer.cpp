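// Compact decoder-only transformer with hand-written backpropagation.
//
// Pre-layernorm residual blocks, learned positional embeddings, multi-head
// causal self-attention with an optional per-token key mask (used for the
// attention-ablation experiments and for context-free retention queries),
// ReLU feedforward of width 2*d_model, untied output projection.
//
// Layout: the whole batch is stacked into one (B*T x h) matrix so that the
// projection and feedforward products are single large GEMMs; the
// attention scores are computed per example and head with causal-prefix
// loops (only the lower triangle is ever touched).
//
// The cross-entropy loss is evaluated only at caller-supplied positions
// (the positions whose next-token prediction is an answer token), so
// context tokens are never supervised.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uvec;
using arma::vec;

static const double LN_EPS = 1e-5;

struct LayerParams {
  mat Wq, Wk, Wv, Wo, W1, W2, rb; // rb: relative-position bias, maxlen x H
  rowvec bq, bk, bv, bo, c1, c2, g1, b1, g2, b2;
};

struct ModelParams {
  mat emb, pos, Wu; // pos may be empty (relative-position models)
  rowvec gf, bf, bu;
  bool tied;
  std::vector<LayerParams> layers;
};

struct LayerGrads {
  mat Wq, Wk, Wv, Wo, W1, W2, rb;
  rowvec bq, bk, bv, bo, c1, c2, g1, b1, g2, b2;
};

struct ModelGrads {
  mat emb, pos, Wu;
  rowvec gf, bf, bu;
  std::vector<LayerGrads> layers;
};

// per-layer activation cache for backward (stacked B*T rows)
struct LayerCache {
  mat z1, n1, Q, K, V, concat, dmask1, xin;
  mat z2, n2, Hpre, dmask2, xmid;
  vec sig1, sig2;
  std::vector<mat> A; // B*H lower-triangular attention matrices (T x T)
};

static ModelParams read_params(const List& params) {
  ModelParams p;
  p.emb = as<mat>(params["emb"]);
  if (params.containsElementNamed("pos")) p.pos = as<mat>(params["pos"]);
  p.tied = !params.containsElementNamed("Wu");
  p.Wu = p.tied ? mat(p.emb.t()) : as<mat>(params["Wu"]);
  p.gf = as<rowvec>(params["gf"]);
  p.bf = as<rowvec>(params["bf"]);
  p.bu = as<rowvec>(params["bu"]);
  List layers = params["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    List ly = layers[l];
    LayerParams lp;
    lp.Wq = as<mat>(ly["Wq"]); lp.bq = as<rowvec>(ly["bq"]);
    lp.Wk = as<mat>(ly["Wk"]); lp.bk = as<rowvec>(ly["bk"]);
    lp.Wv = as<mat>(ly["Wv"]); lp.bv = as<rowvec>(ly["bv"]);
    lp.Wo = as<mat>(ly["Wo"]); lp.bo = as<rowvec>(ly["bo"]);
    lp.g1 = as<rowvec>(ly["g1"]); lp.b1 = as<rowvec>(ly["b1"]);
    lp.g2 = as<rowvec>(ly["g2"]); lp.b2 = as<rowvec>(ly["b2"]);
    lp.W1 = as<mat>(ly["W1"]); lp.c1 = as<rowvec>(ly["c1"]);
    lp.W2 = as<mat>(ly["W2"]); lp.c2 = as<rowvec>(ly["c2"]);
    if (ly.containsElementNamed("rb")) lp.rb = as<mat>(ly["rb"]);
    p.layers.push_back(lp);
  }
  return p;
}

static ModelGrads zero_grads(const ModelParams& p) {
  ModelGrads g;
  g.emb.zeros(arma::size(p.emb));
  if (p.pos.n_elem > 0) g.pos.zeros(arma::size(p.pos));
  if (!p.tied) g.Wu.zeros(arma::size(p.Wu));
  g.gf.zeros(p.gf.n_elem); g.bf.zeros(p.bf.n_elem); g.bu.zeros(p.bu.n_elem);
  for (size_t l = 0; l < p.layers.size(); ++l) {
    const LayerParams& lp = p.layers[l];
    LayerGrads lg;
    lg.Wq.zeros(arma::size(lp.Wq)); lg.bq.zeros(lp.bq.n_elem);
    lg.Wk.zeros(arma::size(lp.Wk)); lg.bk.zeros(lp.bk.n_elem);
    lg.Wv.zeros(arma::size(lp.Wv)); lg.bv.zeros(lp.bv.n_elem);
    lg.Wo.zeros(arma::size(lp.Wo)); lg.bo.zeros(lp.bo.n_elem);
    lg.g1.zeros(lp.g1.n_elem); lg.b1.zeros(lp.b1.n_elem);
    lg.g2.zeros(lp.g2.n_elem); lg.b2.zeros(lp.b2.n_elem);
    lg.W1.zeros(arma::size(lp.W1)); lg.c1.zeros(lp.c1.n_elem);
    lg.W2.zeros(arma::size(lp.W2)); lg.c2.zeros(lp.c2.n_elem);
    if (lp.rb.n_elem > 0) lg.rb.zeros(arma::size(lp.rb));
    g.layers.push_back(lg);
  }
  return g;
}

static List grads_to_list(const ModelGrads& g) {
  List layers(g.layers.size());
  for (size_t l = 0; l < g.layers.size(); ++l) {
    const LayerGrads& lg = g.layers[l];
    List ll = List::create(
      _["Wq"] = lg.Wq, _["bq"] = lg.bq, _["Wk"] = lg.Wk, _["bk"] = lg.bk,
      _["Wv"] = lg.Wv, _["bv"] = lg.bv, _["Wo"] = lg.Wo, _["bo"] = lg.bo,
      _["g1"] = lg.g1, _["b1"] = lg.b1, _["g2"] = lg.g2, _["b2"] = lg.b2,
      _["W1"] = lg.W1, _["c1"] = lg.c1, _["W2"] = lg.W2, _["c2"] = lg.c2);
    if (lg.rb.n_elem > 0) ll["rb"] = lg.rb;
    layers[l] = ll;
  }
  List out = List::create(
    _["emb"] = g.emb, _["gf"] = g.gf, _["bf"] = g.bf,
    _["bu"] = g.bu, _["layers"] = layers);
  if (g.pos.n_elem > 0) out["pos"] = g.pos;
  if (g.Wu.n_elem > 0) out["Wu"] = g.Wu;
  return out;
}

// row-wise layernorm over the hidden dimension
static mat ln_forward(const mat& X, const rowvec& g, const rowvec& b,
                      mat& z, vec& sig) {
  vec mu = arma::mean(X, 1);
  mat Xc = X.each_col() - mu;
  sig = arma::sqrt(arma::mean(arma::square(Xc), 1) + LN_EPS);
  z = Xc.each_col() / sig;
  mat n = z;
  n.each_row() %= g;
  n.each_row() += b;
  return n;
}

static mat ln_backward(const mat& dn, const mat& z, const vec& sig,
                       const rowvec& g, rowvec& dg, rowvec& db) {
  dg += arma::sum(dn % z, 0);
  db += arma::sum(dn, 0);
  mat dz = dn;
  dz.each_row() %= g;
  const double h = static_cast<double>(dn.n_cols);
  vec m1 = arma::sum(dz, 1) / h;
  vec m2 = arma::sum(dz % z, 1) / h;
  mat dX = dz;
  dX.each_col() -= m1;
  dX -= z.each_col() % m2;
  dX.each_col() /= sig;
  return dX;
}

// visibility of key j to query i within one example: causal, and a masked
// key stays visible to itself so no query row ever has an empty support
static inline bool key_visible(int i, int j, const double* km) {
  if (j > i) return false;
  if (km && km[j] == 0.0 && j != i) return false;
  return true;
}

// copy a (T x dh) block of the stacked matrix into a contiguous transposed
// (dh x T) scratch buffer so the attention inner loops run down columns
static void gather_block(const mat& M, int row0, int c0, int dh, int T,
                         mat& out) {
  for (int j = 0; j < T; ++j)
    for (int d = 0; d < dh; ++d)
      out(d, j) = M(row0 + j, c0 + d);
}

static void scatter_block_add(const mat& in, int row0, int c0, int dh,
                              int T, mat& M) {
  for (int j = 0; j < T; ++j)
    for (int d = 0; d < dh; ++d)
      M(row0 + j, c0 + d) += in(d, j);
}

// causal-prefix attention for one (example, head): S = softmax(QK^T/s + M)
// computed over visible keys only; out = S V. A (T x T) stores the weights.
// Qh, Kh, Vh, Oh are contiguous (dh x T) scratch blocks.
static void attn_head_forward(const mat& Qh, const mat& Kh, const mat& Vh,
                              int dh, int T, double scale, const double* km,
                              const double* rb, mat& A, mat& Oh) {
  std::vector<double> srow(T);
  for (int i = 0; i < T; ++i) {
    const double* qi = Qh.colptr(i);
    double mx = -arma::datum::inf;
    for (int j = 0; j <= i; ++j) {
      if (!key_visible(i, j, km)) { srow[j] = -arma::datum::inf; continue; }
      const double* kj = Kh.colptr(j);
      double s = 0.0;
      for (int d = 0; d < dh; ++d) s += qi[d] * kj[d];
      srow[j] = s * scale + (rb ? rb[i - j] : 0.0);
      if (srow[j] > mx) mx = srow[j];
    }
    double Z = 0.0;
    for (int j = 0; j <= i; ++j) {
      double a = (srow[j] == -arma::datum::inf) ? 0.0
                                                : std::exp(srow[j] - mx);
      srow[j] = a;
      Z += a;
    }
    double* oi = Oh.colptr(i);
    for (int d = 0; d < dh; ++d) oi[d] = 0.0;
    double* Ai = A.colptr(i); // store row i in column i (A kept transposed)
    for (int j = 0; j <= i; ++j) {
      double a = srow[j] / Z;
      Ai[j] = a;
      if (a != 0.0) {
        const double* vj = Vh.colptr(j);
        for (int d = 0; d < dh; ++d) oi[d] += a * vj[d];
      }
    }
  }
}

// backward through one (example, head) attention; A is transposed (key j in
// rows, query i in columns), dOh is (dh x T), outputs are (dh x T) blocks
static void attn_head_backward(const mat& Qh, const mat& Kh, const mat& Vh,
                               const mat& A, const mat& dOh, int dh, int T,
                               double scale, mat& dQh, mat& dKh, mat& dVh,
                               double* drb) {
  std::vector<double> dArow(T);
  for (int i = 0; i < T; ++i) {
    const double* doi = dOh.colptr(i);
    const double* Ai = A.colptr(i);
    double dot = 0.0;
    for (int j = 0; j <= i; ++j) {
      const double* vj = Vh.colptr(j);
      double da = 0.0;
      for (int d = 0; d < dh; ++d) da += doi[d] * vj[d];
      dArow[j] = da;
      dot += da * Ai[j];
    }
    const double* qi = Qh.colptr(i);
    double* dqi = dQh.colptr(i);
    for (int j = 0; j <= i; ++j) {
      double a = Ai[j];
      if (a == 0.0) continue;
      double ds_raw = a * (dArow[j] - dot);
      if (drb) drb[i - j] += ds_raw;
      double ds = ds_raw * scale;
      const double* kj = Kh.colptr(j);
      double* dkj = dKh.colptr(j);
      double* dvj = dVh.colptr(j);
      for (int d = 0; d < dh; ++d) {
        dqi[d] += ds * kj[d];
        dkj[d] += ds * qi[d];
        dvj[d] += a * doi[d];
      }
    }
  }
}

struct ForwardState {
  mat x;                 // (B*T x h) output of the layer stack
  std::vector<LayerCache> caches;
  uvec tokidx;
};

static void forward_stack(const ModelParams& p, const IntegerMatrix& tokens,
                          const NumericMatrix* km, int n_heads,
                          double dropout, bool train, int dropout_seed,
                          bool want_grads, ForwardState& fs) {
  const int B = tokens.nrow();
  const int T = tokens.ncol();
  const int h = p.emb.n_cols;
  const int dh = h / n_heads;
  const double scale = 1.0 / std::sqrt(static_cast<double>(dh));
  const int BT = B * T;

  uvec tokidx(BT), posidx(BT);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) {
      tokidx(b * T + t) = tokens(b, t);
      posidx(b * T + t) = t;
    }
  fs.tokidx = tokidx;
  mat x = p.emb.rows(tokidx);
  if (p.pos.n_elem > 0) x += p.pos.rows(posidx);

  // per-example key-mask pointers (column-major access of km is avoided by
  // copying each example's row once)
  std::vector<std::vector<double>> kmrows;
  if (km) {
    kmrows.assign(B, std::vector<double>(T));
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < T; ++t) kmrows[b][t] = (*km)(b, t);
  }

  std::mt19937 gen(static_cast<unsigned>(dropout_seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  for (size_t l = 0; l < p.layers.size(); ++l) {
    const LayerParams& lp = p.layers[l];
    LayerCache cc;
    if (want_grads) cc.xin = x;
    mat z1; vec sig1;
    mat n1 = ln_forward(x, lp.g1, lp.b1, z1, sig1);
    mat Q = n1 * lp.Wq; Q.each_row() += lp.bq;
    mat K = n1 * lp.Wk; K.each_row() += lp.bk;
    mat V = n1 * lp.Wv; V.each_row() += lp.bv;
    mat concat(BT, h);
    std::vector<mat> As;
    if (want_grads) As.reserve(B * n_heads);
    mat Qh(dh, T), Kh(dh, T), Vh(dh, T), Oh(dh, T);
    for (int b = 0; b < B; ++b) {
      const double* kmp = km ? kmrows[b].data() : nullptr;
      for (int hd = 0; hd < n_heads; ++hd) {
        gather_block(Q, b * T, hd * dh, dh, T, Qh);
        gather_block(K, b * T, hd * dh, dh, T, Kh);
        gather_block(V, b * T, hd * dh, dh, T, Vh);
        mat A(T, T, arma::fill::zeros);
        attn_head_forward(Qh, Kh, Vh, dh, T, scale, kmp,
                          lp.rb.n_elem > 0 ? lp.rb.colptr(hd) : nullptr,
                          A, Oh);
        for (int j = 0; j < T; ++j)
          for (int d = 0; d < dh; ++d)
            concat(b * T + j, hd * dh + d) = Oh(d, j);
        if (want_grads) As.push_back(std::move(A));
      }
    }
    mat branch1 = concat * lp.Wo;
    branch1.each_row() += lp.bo;
    mat dmask1;
    if (train && dropout > 0.0) {
      dmask1.set_size(BT, h);
      for (arma::uword i = 0; i < dmask1.n_elem; ++i)
        dmask1(i) = (unif(gen) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      branch1 %= dmask1;
    }
    mat xmid = x + branch1;

    mat z2; vec sig2;
    mat n2 = ln_forward(xmid, lp.g2, lp.b2, z2, sig2);
    mat Hpre = n2 * lp.W1; Hpre.each_row() += lp.c1;
    mat branch2 = arma::clamp(Hpre, 0.0, arma::datum::inf) * lp.W2;
    branch2.each_row() += lp.c2;
    mat dmask2;
    if (train && dropout > 0.0) {
      dmask2.set_size(BT, h);
      for (arma::uword i = 0; i < dmask2.n_elem; ++i)
        dmask2(i) = (unif(gen) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      branch2 %= dmask2;
    }
    mat xout = xmid + branch2;

    if (want_grads) {
      cc.z1 = std::move(z1); cc.sig1 = std::move(sig1);
      cc.n1 = std::move(n1); cc.Q = std::move(Q); cc.K = std::move(K);
      cc.V = std::move(V); cc.concat = std::move(concat);
      cc.dmask1 = std::move(dmask1);
      cc.xmid = xmid; cc.z2 = std::move(z2); cc.sig2 = std::move(sig2);
      cc.n2 = std::move(n2); cc.Hpre = std::move(Hpre);
      cc.dmask2 = std::move(dmask2);
      cc.A = std::move(As);
      fs.caches.push_back(std::move(cc));
    }
    x = std::move(xout);
  }
  fs.x = std::move(x);
}

static void backward_stack(const ModelParams& p, int B, int T, int n_heads,
                           mat dx, ForwardState& fs, ModelGrads& g) {
  const int h = p.emb.n_cols;
  const int dh = h / n_heads;
  const double scale = 1.0 / std::sqrt(static_cast<double>(dh));

  for (int l = static_cast<int>(p.layers.size()) - 1; l >= 0; --l) {
    const LayerParams& lp = p.layers[l];
    LayerGrads& lg = g.layers[l];
    LayerCache& cc = fs.caches[l];

    mat dbranch2 = dx;
    if (cc.dmask2.n_elem > 0) dbranch2 %= cc.dmask2;
    mat Hrelu = arma::clamp(cc.Hpre, 0.0, arma::datum::inf);
    lg.W2 += Hrelu.t() * dbranch2;
    lg.c2 += arma::sum(dbranch2, 0);
    mat dHpre = (dbranch2 * lp.W2.t()) %
                arma::conv_to<mat>::from(cc.Hpre > 0.0);
    lg.W1 += cc.n2.t() * dHpre;
    lg.c1 += arma::sum(dHpre, 0);
    mat dn2 = dHpre * lp.W1.t();
    mat dxmid = dx + ln_backward(dn2, cc.z2, cc.sig2, lp.g2, lg.g2, lg.b2);

    mat dbranch1 = dxmid;
    if (cc.dmask1.n_elem > 0) dbranch1 %= cc.dmask1;
    lg.Wo += cc.concat.t() * dbranch1;
    lg.bo += arma::sum(dbranch1, 0);
    mat dconcat = dbranch1 * lp.Wo.t();
    mat dQ(arma::size(cc.Q), arma::fill::zeros);
    mat dK(arma::size(cc.K), arma::fill::zeros);
    mat dV(arma::size(cc.V), arma::fill::zeros);
    {
      mat Qh(dh, T), Kh(dh, T), Vh(dh, T), dOh(dh, T);
      mat dQh(dh, T), dKh(dh, T), dVh(dh, T);
      for (int b = 0; b < B; ++b)
        for (int hd = 0; hd < n_heads; ++hd) {
          gather_block(cc.Q, b * T, hd * dh, dh, T, Qh);
          gather_block(cc.K, b * T, hd * dh, dh, T, Kh);
          gather_block(cc.V, b * T, hd * dh, dh, T, Vh);
          gather_block(dconcat, b * T, hd * dh, dh, T, dOh);
          dQh.zeros(); dKh.zeros(); dVh.zeros();
          attn_head_backward(Qh, Kh, Vh, cc.A[b * n_heads + hd], dOh, dh,
                             T, scale, dQh, dKh, dVh,
                             lg.rb.n_elem > 0 ? lg.rb.colptr(hd) : nullptr);
          scatter_block_add(dQh, b * T, hd * dh, dh, T, dQ);
          scatter_block_add(dKh, b * T, hd * dh, dh, T, dK);
          scatter_block_add(dVh, b * T, hd * dh, dh, T, dV);
        }
    }
    lg.Wq += cc.n1.t() * dQ; lg.bq += arma::sum(dQ, 0);
    lg.Wk += cc.n1.t() * dK; lg.bk += arma::sum(dK, 0);
    lg.Wv += cc.n1.t() * dV; lg.bv += arma::sum(dV, 0);
    mat dn1 = dQ * lp.Wq.t() + dK * lp.Wk.t() + dV * lp.Wv.t();
    dx = dxmid + ln_backward(dn1, cc.z1, cc.sig1, lp.g1, lg.g1, lg.b1);
  }
  // embedding + positional scatter
  const int BT = B * T;
  bool has_pos = g.pos.n_elem > 0;
  for (int i = 0; i < BT; ++i) {
    g.emb.row(fs.tokidx(i)) += dx.row(i);
    if (has_pos) g.pos.row(i % T) += dx.row(i);
  }
}

//' @noRd
// [[Rcpp::export(name = ".tf_batch")]]
List tf_batch(List params, List config, IntegerMatrix tokens,
              Nullable<NumericMatrix> keymask, IntegerVector target_pos,
              Nullable<IntegerMatrix> targets, bool want_grads, bool train,
              int dropout_seed) {
  ModelParams p = read_params(params);
  const int n_heads = as<int>(config["n_heads"]);
  const double dropout = as<double>(config["dropout"]);
  const int B = tokens.nrow();
  const int T = tokens.ncol();
  const int n_t = target_pos.size();
  const int d_v = p.Wu.n_cols;
  const int h = p.emb.n_cols;
  const int maxlen = as<int>(config["max_sequence_length"]);
  if (T > maxlen)
    stop("sequence length %d exceeds max_sequence_length %d", T, maxlen);

  NumericMatrix km_;
  const NumericMatrix* kmp = nullptr;
  if (keymask.isNotNull()) { km_ = keymask.get(); kmp = &km_; }
  IntegerMatrix tg_;
  bool has_tg = targets.isNotNull();
  if (has_tg) tg_ = targets.get();

  ForwardState fs;
  forward_stack(p, tokens, kmp, n_heads, dropout, train, dropout_seed,
                want_grads, fs);

  // final layernorm + readout at the target rows only
  uvec rows(B * n_t);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < n_t; ++k)
      rows(b * n_t + k) = b * T + target_pos[k];
  mat xt = fs.x.rows(rows);
  mat zf; vec sigf;
  mat nf = ln_forward(xt, p.gf, p.bf, zf, sigf);
  mat logits_m = nf * p.Wu;
  logits_m.each_row() += p.bu;

  double loss = NA_REAL;
  ModelGrads g;
  if (want_grads) g = zero_grads(p);
  arma::cube logits(n_t, d_v, B);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < n_t; ++k)
      logits.slice(b).row(k) = logits_m.row(b * n_t + k);

  if (has_tg) {
    loss = 0.0;
    const double denom = static_cast<double>(B * std::max(n_t, 1));
    mat dlog(arma::size(logits_m), arma::fill::none);
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < n_t; ++k) {
        int r = b * n_t + k;
        rowvec lgr = logits_m.row(r);
        double m = lgr.max();
        rowvec ex = arma::exp(lgr - m);
        double Z = arma::accu(ex);
        int y = tg_(b, k);
        loss += -(lgr(y) - m - std::log(Z)) / denom;
        if (want_grads) {
          rowvec dl = ex / (Z * denom);
          dl(y) -= 1.0 / denom;
          dlog.row(r) = dl;
        }
      }
    if (want_grads) {
      if (p.tied) g.emb += dlog.t() * nf;
      else g.Wu += nf.t() * dlog;
      g.bu += arma::sum(dlog, 0);
      mat dnf = dlog * p.Wu.t();
      mat dxt = ln_backward(dnf, zf, sigf, p.gf, g.gf, g.bf);
      mat dx(arma::size(fs.x), arma::fill::zeros);
      for (arma::uword i = 0; i < rows.n_elem; ++i)
        dx.row(rows(i)) += dxt.row(i);
      backward_stack(p, B, T, n_heads, std::move(dx), fs, g);
    }
  }

  List out = List::create(_["loss"] = loss, _["logits"] = logits);
  if (want_grads) out["grads"] = grads_to_list(g);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".tf_full_logits")]]
List tf_full_logits(List params, List config, IntegerMatrix tokens,
                    Nullable<NumericMatrix> keymask) {
  ModelParams p = read_params(params);
  const int n_heads = as<int>(config["n_heads"]);
  const int B = tokens.nrow();
  const int T = tokens.ncol();
  if (T > as<int>(config["max_sequence_length"]))
    stop("sequence length exceeds max_sequence_length");
  NumericMatrix km_;
  const NumericMatrix* kmp = nullptr;
  if (keymask.isNotNull()) { km_ = keymask.get(); kmp = &km_; }
  ForwardState fs;
  forward_stack(p, tokens, kmp, n_heads, 0.0, false, 0, false, fs);
  mat zf; vec sigf;
  mat nf = ln_forward(fs.x, p.gf, p.bf, zf, sigf);
  mat lg = nf * p.Wu;
  lg.each_row() += p.bu;
  List out(B);
  for (int b = 0; b < B; ++b)
    out[b] = mat(lg.rows(b * T, (b + 1) * T - 1));
  return out;
}
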