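// Transformer encoder with CLS-token classification head, optional
// clinical-feature fusion, analytic backpropagation and AdamW training.
// Pre-LN layer arrangement; sinusoidal positional encodings. All
// parameters live in one flat vector so optimizer state and
// finite-difference gradient checks are straightforward; ParamView holds
// non-owning Armadillo views into that vector (emplace-constructed so the
// aux-memory binding is never copied).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::cube;

static const double LN_EPS = 1e-5;

struct TFConfig {
  int d, m, H, nlayers, f, n_clin, h;
  int max_len = 0;   // training crop window; 0 = no cropping
  bool use_clin;
  double dropout;
  std::vector<int> vsizes;
  int dk() const { return m / H; }
  int mm() const { return m + (use_clin ? h : 0); }
};

static TFConfig parse_config(const Rcpp::List& cfg) {
  TFConfig c;
  c.d = Rcpp::as<int>(cfg["d"]);
  c.m = Rcpp::as<int>(cfg["embed_dim"]);
  c.H = Rcpp::as<int>(cfg["n_heads"]);
  c.nlayers = Rcpp::as<int>(cfg["n_layers"]);
  c.f = Rcpp::as<int>(cfg["ffn_dim"]);
  c.use_clin = Rcpp::as<bool>(cfg["use_clinical"]);
  c.n_clin = c.use_clin ? Rcpp::as<int>(cfg["n_clinical"]) : 0;
  c.h = c.use_clin ? Rcpp::as<int>(cfg["clinical_hidden"]) : 0;
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  if (cfg.containsElementNamed("max_len"))
    c.max_len = Rcpp::as<int>(cfg["max_len"]);
  Rcpp::IntegerVector vs = cfg["vocab_sizes"];
  c.vsizes.assign(vs.begin(), vs.end());
  if ((int)c.vsizes.size() != c.d) Rcpp::stop("vocab_sizes length must equal d");
  if (c.m % c.H != 0) Rcpp::stop("embed_dim must be divisible by n_heads");
  return c;
}

// per-layer parameter slot order inside ParamView::M
enum { kWq = 0, kbq, kWk, kbk, kWv, kbv, kWo, kbo,
       kg1, kbe1, kW1, kb1, kW2, kb2, kg2, kbe2, kPerLayer };

struct ParamView {
  std::vector<mat> M;   // non-owning views, layout order
  int emb0 = 0, cls = 0, layer0 = 0, gf = 0, bef = 0,
      Wc = -1, bc = -1, Wout = 0, bout = 0;
  mat& lay(int l, int k) { return M[layer0 + l * kPerLayer + k]; }
  const mat& lay(int l, int k) const { return M[layer0 + l * kPerLayer + k]; }
};

static long tf_param_count_(const TFConfig& c) {
  long n = 0;
  for (int i = 0; i < c.d; ++i) n += (long)c.vsizes[i] * c.m;
  n += c.m;                                        // cls
  long per = 4L * (c.m * c.m + c.m) + 2L * c.m
           + (long)c.m * c.f + c.f + (long)c.f * c.m + c.m + 2L * c.m;
  n += per * c.nlayers;
  n += 2L * c.m;                                   // final LN
  if (c.use_clin) n += (long)c.n_clin * c.h + c.h;
  n += c.mm() + 1;                                 // output layer
  return n;
}

static ParamView make_views(double* p, const TFConfig& c) {
  ParamView v;
  // reserve so the vector never reallocates: Armadillo would deep-copy the
  // aux-memory views on element move, detaching them from the flat vector
  v.M.reserve((size_t)c.d + 1 + (size_t)c.nlayers * kPerLayer + 2
              + (c.use_clin ? 2 : 0) + 2);
  auto add = [&](int r, int co) {
    v.M.emplace_back(p, r, co, false, true);
    p += (long)r * co;
    return (int)v.M.size() - 1;
  };
  v.emb0 = (int)v.M.size();
  for (int ch = 0; ch < c.d; ++ch) add(c.vsizes[ch], c.m);
  v.cls = add(1, c.m);
  v.layer0 = (int)v.M.size();
  for (int l = 0; l < c.nlayers; ++l) {
    add(c.m, c.m); add(1, c.m);   // Wq bq
    add(c.m, c.m); add(1, c.m);   // Wk bk
    add(c.m, c.m); add(1, c.m);   // Wv bv
    add(c.m, c.m); add(1, c.m);   // Wo bo
    add(1, c.m); add(1, c.m);     // g1 be1
    add(c.m, c.f); add(1, c.f);   // W1 b1
    add(c.f, c.m); add(1, c.m);   // W2 b2
    add(1, c.m); add(1, c.m);     // g2 be2
  }
  v.gf = add(1, c.m);
  v.bef = add(1, c.m);
  if (c.use_clin) { v.Wc = add(c.n_clin, c.h); v.bc = add(1, c.h); }
  v.Wout = add(c.mm(), 1);
  v.bout = add(1, 1);
  return v;
}

static mat posenc(int L1, int m) {
  mat P(L1, m, arma::fill::zeros);
  for (int pos = 0; pos < L1; ++pos) {
    for (int k = 0; 2 * k < m; ++k) {
      double ang = pos / std::pow(10000.0, (2.0 * k) / m);
      P(pos, 2 * k) = std::sin(ang);
      if (2 * k + 1 < m) P(pos, 2 * k + 1) = std::cos(ang);
    }
  }
  return P;
}

static void layernorm_fwd(const mat& X, const mat& g, const mat& b,
                          mat& Y, mat& xhat, vec& isd) {
  vec mu = arma::mean(X, 1);
  mat Xc = X; Xc.each_col() -= mu;
  vec var = arma::mean(arma::square(Xc), 1);
  isd = 1.0 / arma::sqrt(var + LN_EPS);
  xhat = Xc; xhat.each_col() %= isd;
  Y = xhat;
  Y.each_row() %= rowvec(g.row(0));
  Y.each_row() += rowvec(b.row(0));
}

static mat layernorm_bwd(const mat& dY, const mat& g, const mat& xhat,
                         const vec& isd, mat& dg, mat& db) {
  dg += arma::sum(dY % xhat, 0);
  db += arma::sum(dY, 0);
  mat dxhat = dY; dxhat.each_row() %= rowvec(g.row(0));
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % xhat, 1);
  mat dX = dxhat; dX.each_col() -= m1;
  mat t = xhat; t.each_col() %= m2;
  dX -= t; dX.each_col() %= isd;
  return dX;
}

static void softmax_rows(mat& S) {
  S.each_col() -= arma::max(S, 1);
  S = arma::exp(S);
  S.each_col() /= arma::sum(S, 1);
}

struct LayerCache {
  mat A, Q, K, V, Oc, X1, B, H1;
  mat xhat1, xhat2; vec isd1, isd2;
  cube att;
  mat maskO, maskF;
};

struct ForwardCache {
  mat Z, xhatf; vec isdf;
  std::vector<LayerCache> layers;
  rowvec fused, clin_pre, clin_hid;
  double logit;
};

// forward pass for one case; ids: (L+1) x d with CLS in row 0, content
// ids starting at 2 (0 = PAD, 1 = CLS; PAD rows must be stripped upstream).
// Positions listed in mask_pos (masked-token pretraining) keep their
// positional encoding but contribute no content embedding.
static void forward_case(const ParamView& pv, const TFConfig& c,
                         const arma::imat& ids, const rowvec& clin,
                         ForwardCache& fc, bool keep_cache,
                         std::mt19937_64* drop_rng,
                         const std::vector<int>* mask_pos = nullptr) {
  const int L1 = ids.n_rows;
  mat X(L1, c.m, arma::fill::zeros);
  X.row(0) = pv.M[pv.cls].row(0);
  for (int i = 1; i < L1; ++i)
    for (int ch = 0; ch < c.d; ++ch) {
      int id = ids(i, ch) - 2;
      if (id < 0 || id >= c.vsizes[ch]) Rcpp::stop("token id out of range");
      X.row(i) += pv.M[pv.emb0 + ch].row(id);
    }
  if (mask_pos)
    for (int i : *mask_pos) X.row(i).zeros();
  X += posenc(L1, c.m);
  fc.layers.resize(c.nlayers);
  const double scale = 1.0 / std::sqrt((double)c.dk());
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (int l = 0; l < c.nlayers; ++l) {
    LayerCache& lc = fc.layers[l];
    mat A; layernorm_fwd(X, pv.lay(l, kg1), pv.lay(l, kbe1), A, lc.xhat1, lc.isd1);
    mat Q = A * pv.lay(l, kWq); Q.each_row() += rowvec(pv.lay(l, kbq).row(0));
    mat K = A * pv.lay(l, kWk); K.each_row() += rowvec(pv.lay(l, kbk).row(0));
    mat V = A * pv.lay(l, kWv); V.each_row() += rowvec(pv.lay(l, kbv).row(0));
    mat Oc(L1, c.m);
    lc.att.set_size(L1, L1, c.H);
    for (int hh = 0; hh < c.H; ++hh) {
      int a = hh * c.dk(), b = a + c.dk() - 1;
      mat S = Q.cols(a, b) * K.cols(a, b).t() * scale;
      softmax_rows(S);
      lc.att.slice(hh) = S;
      Oc.cols(a, b) = S * V.cols(a, b);
    }
    mat O = Oc * pv.lay(l, kWo); O.each_row() += rowvec(pv.lay(l, kbo).row(0));
    if (drop_rng && c.dropout > 0) {
      lc.maskO.set_size(L1, c.m);
      for (arma::uword i = 0; i < lc.maskO.n_elem; ++i)
        lc.maskO(i) = unif(*drop_rng) < c.dropout ? 0.0 : 1.0 / (1.0 - c.dropout);
      O %= lc.maskO;
    }
    mat X1 = X + O;
    mat B; layernorm_fwd(X1, pv.lay(l, kg2), pv.lay(l, kbe2), B, lc.xhat2, lc.isd2);
    mat H1 = B * pv.lay(l, kW1); H1.each_row() += rowvec(pv.lay(l, kb1).row(0));
    H1.transform([](double x) { return x > 0 ? x : 0.0; });
    mat F = H1 * pv.lay(l, kW2); F.each_row() += rowvec(pv.lay(l, kb2).row(0));
    if (drop_rng && c.dropout > 0) {
      lc.maskF.set_size(L1, c.m);
      for (arma::uword i = 0; i < lc.maskF.n_elem; ++i)
        lc.maskF(i) = unif(*drop_rng) < c.dropout ? 0.0 : 1.0 / (1.0 - c.dropout);
      F %= lc.maskF;
    }
    mat Xnext = X1 + F;
    if (keep_cache) { lc.A = A; lc.Q = Q; lc.K = K; lc.V = V; lc.Oc = Oc;
                      lc.X1 = X1; lc.B = B; lc.H1 = H1; }
    X = Xnext;
  }
  mat Z; layernorm_fwd(X, pv.M[pv.gf], pv.M[pv.bef], Z, fc.xhatf, fc.isdf);
  fc.Z = Z;
  rowvec fused;
  if (c.use_clin) {
    rowvec pre = clin * pv.M[pv.Wc] + rowvec(pv.M[pv.bc].row(0));
    rowvec hid = pre; hid.transform([](double x) { return x > 0 ? x : 0.0; });
    fc.clin_pre = pre; fc.clin_hid = hid;
    fused = arma::join_rows(rowvec(Z.row(0)), hid);
  } else {
    fused = Z.row(0);
  }
  fc.fused = fused;
  fc.logit = arma::as_scalar(fused * pv.M[pv.Wout]) + pv.M[pv.bout](0, 0);
}

// encoder backward from gradients w.r.t. the final normalized output Z;
// requires a forward pass run with keep_cache = true. Masked positions
// (pretraining) contributed no content embedding, so they receive none of
// the embedding gradient.
static void backward_encoder(const ParamView& pv, ParamView& gv,
                             const TFConfig& c, const arma::imat& ids,
                             const ForwardCache& fc, const mat& dZ,
                             const std::vector<int>* mask_pos = nullptr) {
  const int L1 = ids.n_rows;
  mat dX = layernorm_bwd(dZ, pv.M[pv.gf], fc.xhatf, fc.isdf,
                         gv.M[gv.gf], gv.M[gv.bef]);
  const double scale = 1.0 / std::sqrt((double)c.dk());
  for (int l = c.nlayers - 1; l >= 0; --l) {
    const LayerCache& lc = fc.layers[l];
    // X2 = X1 + F(LN2(X1))
    mat dF = dX;
    if (lc.maskF.n_elem) dF %= lc.maskF;
    mat dX1 = dX;
    gv.lay(l, kW2) += lc.H1.t() * dF;
    gv.lay(l, kb2) += arma::sum(dF, 0);
    mat dH1 = dF * pv.lay(l, kW2).t();
    for (arma::uword i = 0; i < dH1.n_elem; ++i) if (lc.H1(i) <= 0) dH1(i) = 0;
    gv.lay(l, kW1) += lc.B.t() * dH1;
    gv.lay(l, kb1) += arma::sum(dH1, 0);
    mat dB = dH1 * pv.lay(l, kW1).t();
    dX1 += layernorm_bwd(dB, pv.lay(l, kg2), lc.xhat2, lc.isd2,
                         gv.lay(l, kg2), gv.lay(l, kbe2));
    // X1 = Xin + O(LN1(Xin))
    mat dO = dX1;
    if (lc.maskO.n_elem) dO %= lc.maskO;
    mat dXin = dX1;
    gv.lay(l, kWo) += lc.Oc.t() * dO;
    gv.lay(l, kbo) += arma::sum(dO, 0);
    mat dOc = dO * pv.lay(l, kWo).t();
    mat dQ(L1, c.m), dK(L1, c.m), dV(L1, c.m);
    for (int hh = 0; hh < c.H; ++hh) {
      int a = hh * c.dk(), b = a + c.dk() - 1;
      const mat& att = lc.att.slice(hh);
      mat dOh = dOc.cols(a, b);
      mat datt = dOh * lc.V.cols(a, b).t();
      dV.cols(a, b) = att.t() * dOh;
      vec rs = arma::sum(datt % att, 1);
      mat dS = att % (datt.each_col() - rs);
      dQ.cols(a, b) = dS * lc.K.cols(a, b) * scale;
      dK.cols(a, b) = dS.t() * lc.Q.cols(a, b) * scale;
    }
    gv.lay(l, kWq) += lc.A.t() * dQ; gv.lay(l, kbq) += arma::sum(dQ, 0);
    gv.lay(l, kWk) += lc.A.t() * dK; gv.lay(l, kbk) += arma::sum(dK, 0);
    gv.lay(l, kWv) += lc.A.t() * dV; gv.lay(l, kbv) += arma::sum(dV, 0);
    mat dA = dQ * pv.lay(l, kWq).t() + dK * pv.lay(l, kWk).t()
           + dV * pv.lay(l, kWv).t();
    dXin += layernorm_bwd(dA, pv.lay(l, kg1), lc.xhat1, lc.isd1,
                          gv.lay(l, kg1), gv.lay(l, kbe1));
    dX = dXin;
  }
  gv.M[gv.cls] += dX.row(0);
  std::vector<char> masked(L1, 0);
  if (mask_pos) for (int i : *mask_pos) masked[i] = 1;
  for (int i = 1; i < L1; ++i) {
    if (masked[i]) continue;
    for (int ch = 0; ch < c.d; ++ch)
      gv.M[gv.emb0 + ch].row(ids(i, ch) - 2) += dX.row(i);
  }
}

// classifier backward: output-layer and clinical-branch gradients, then
// the encoder backward through the CLS row
static void backward_case(const ParamView& pv, ParamView& gv,
                          const TFConfig& c, const arma::imat& ids,
                          const rowvec& clin, const ForwardCache& fc,
                          double dlogit) {
  const int L1 = ids.n_rows;
  gv.M[gv.Wout] += dlogit * fc.fused.t();
  gv.M[gv.bout](0, 0) += dlogit;
  rowvec dfused = dlogit * pv.M[pv.Wout].t();
  rowvec dcls = dfused.cols(0, c.m - 1);
  if (c.use_clin) {
    rowvec dhid = dfused.cols(c.m, c.mm() - 1);
    rowvec dpre = dhid;
    for (int i = 0; i < c.h; ++i) if (fc.clin_pre(i) <= 0) dpre(i) = 0;
    gv.M[gv.Wc] += clin.t() * dpre;
    gv.M[gv.bc] += dpre;
  }
  mat dZ(L1, c.m, arma::fill::zeros);
  dZ.row(0) = dcls;
  backward_encoder(pv, gv, c, ids, fc, dZ);
}

static double softplus(double x) {
  return x > 30 ? x : std::log1p(std::exp(x));
}

static double bce_loss(double logit, double y, double pos_weight) {
  return pos_weight * y * softplus(-logit) + (1 - y) * softplus(logit);
}

static double bce_dlogit(double logit, double y, double pos_weight) {
  double s = 1.0 / (1.0 + std::exp(-logit));
  return -pos_weight * y * (1.0 - s) + (1 - y) * s;
}

// [[Rcpp::export]]
double tf_param_count(const Rcpp::List& cfg) {
  return (double)tf_param_count_(parse_config(cfg));
}

static std::vector<arma::imat> as_imat_list(const Rcpp::List& ids_list) {
  std::vector<arma::imat> out;
  out.reserve(ids_list.size());
  for (int i = 0; i < ids_list.size(); ++i) {
    Rcpp::IntegerMatrix M = ids_list[i];
    arma::imat A(M.nrow(), M.ncol());
    for (int r = 0; r < M.nrow(); ++r)
      for (int cc = 0; cc < M.ncol(); ++cc) A(r, cc) = M(r, cc);
    out.push_back(A);
  }
  return out;
}

// mean loss and gradient over a set of cases
// [[Rcpp::export]]
Rcpp::List tf_loss_grad(const arma::vec& params, const Rcpp::List& cfg,
                        const Rcpp::List& ids_list, const arma::mat& clin,
                        const arma::vec& y, double pos_weight = 1.0,
                        int dropout_seed = 0) {
  TFConfig c = parse_config(cfg);
  if ((long)params.n_elem != tf_param_count_(c))
    Rcpp::stop("parameter vector has wrong length");
  ParamView pv = make_views(const_cast<double*>(params.memptr()), c);
  arma::vec grad(params.n_elem, arma::fill::zeros);
  ParamView gv = make_views(grad.memptr(), c);
  std::mt19937_64 rng((uint64_t)dropout_seed);
  std::mt19937_64* rp = dropout_seed != 0 ? &rng : nullptr;
  const int n = ids_list.size();
  std::vector<arma::imat> ids = as_imat_list(ids_list);
  double loss = 0;
  for (int i = 0; i < n; ++i) {
    rowvec cr = c.use_clin ? rowvec(clin.row(i)) : rowvec();
    ForwardCache fc;
    forward_case(pv, c, ids[i], cr, fc, true, rp);
    loss += bce_loss(fc.logit, y(i), pos_weight);
    backward_case(pv, gv, c, ids[i], cr, fc,
                  bce_dlogit(fc.logit, y(i), pos_weight) / n);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss / n,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export]]
Rcpp::List tf_forward_case(const arma::vec& params, const Rcpp::List& cfg,
                           const Rcpp::IntegerMatrix& ids_in,
                           const arma::rowvec& clin) {
  TFConfig c = parse_config(cfg);
  ParamView pv = make_views(const_cast<double*>(params.memptr()), c);
  arma::imat ids(ids_in.nrow(), ids_in.ncol());
  for (int r = 0; r < ids_in.nrow(); ++r)
    for (int cc = 0; cc < ids_in.ncol(); ++cc) ids(r, cc) = ids_in(r, cc);
  ForwardCache fc;
  forward_case(pv, c, ids, clin, fc, false, nullptr);
  Rcpp::List attn(c.nlayers);
  for (int l = 0; l < c.nlayers; ++l) attn[l] = fc.layers[l].att;
  double prob = 1.0 / (1.0 + std::exp(-fc.logit));
  return Rcpp::List::create(
    Rcpp::Named("logit") = fc.logit,
    Rcpp::Named("probability") = prob,
    Rcpp::Named("attention") = attn,
    Rcpp::Named("cls_representation") = rowvec(fc.Z.row(0)));
}

// batch scoring: probabilities plus final-layer head-averaged CLS-row
// attention over content positions (entry j = attention CLS -> token j)
// [[Rcpp::export]]
Rcpp::List tf_score(const arma::vec& params, const Rcpp::List& cfg,
                    const Rcpp::List& ids_list, const arma::mat& clin) {
  TFConfig c = parse_config(cfg);
  ParamView pv = make_views(const_cast<double*>(params.memptr()), c);
  std::vector<arma::imat> ids = as_imat_list(ids_list);
  const int n = (int)ids.size();
  Rcpp::NumericVector prob(n), logit(n);
  Rcpp::List cls_attn(n);
  for (int i = 0; i < n; ++i) {
    rowvec cr = c.use_clin ? rowvec(clin.row(i)) : rowvec();
    ForwardCache fc;
    forward_case(pv, c, ids[i], cr, fc, false, nullptr);
    logit[i] = fc.logit;
    prob[i] = 1.0 / (1.0 + std::exp(-fc.logit));
    const cube& att = fc.layers[c.nlayers - 1].att;
    rowvec row(att.n_cols, arma::fill::zeros);
    for (int hh = 0; hh < c.H; ++hh) row += att.slice(hh).row(0);
    row /= c.H;
    cls_attn[i] = Rcpp::NumericVector(row.begin() + 1, row.end());
  }
  return Rcpp::List::create(Rcpp::Named("probability") = prob,
                            Rcpp::Named("logit") = logit,
                            Rcpp::Named("cls_attention") = cls_attn);
}

static arma::imat crop_case(const arma::imat& ids, int max_len,
                            std::mt19937_64& rng);

// Masked-token pretraining (BERT-style) with tied input/output
// embeddings: random content positions lose their token embeddings and
// the encoder must reconstruct each channel's token id from context via a
// softmax over z_i Emb_c'. Learning local transition structure this way
// gives the classifier transition-aware representations before it ever
// sees an outcome label.
// [[Rcpp::export]]
Rcpp::List tf_pretrain(const arma::vec& params0, const Rcpp::List& cfg,
                       const Rcpp::List& ids_list, double mask_prob,
                       double lr, double weight_decay, int batch_size,
                       int epochs, int seed, double clip_norm = 1.0) {
  TFConfig c = parse_config(cfg);
  if ((long)params0.n_elem != tf_param_count_(c))
    Rcpp::stop("parameter vector has wrong length");
  arma::vec params = params0;
  arma::vec mAdam(params.n_elem, arma::fill::zeros);
  arma::vec vAdam(params.n_elem, arma::fill::zeros);
  std::vector<arma::imat> ids = as_imat_list(ids_list);
  std::vector<int> order(ids.size());
  for (size_t i = 0; i < ids.size(); ++i) order[i] = (int)i;
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  arma::vec decay_mask(params.n_elem, arma::fill::zeros);
  {
    ParamView mv = make_views(decay_mask.memptr(), c);
    for (int ch = 0; ch < c.d; ++ch) mv.M[mv.emb0 + ch].fill(1.0);
    for (int l = 0; l < c.nlayers; ++l)
      for (int k : {kWq, kWk, kWv, kWo, kW1, kW2}) mv.lay(l, k).fill(1.0);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  std::vector<double> hist;
  arma::vec grad(params.n_elem);
  rowvec empty_clin;
  for (int epoch = 1; epoch <= epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0; int n_seen = 0;
    for (size_t start = 0; start < order.size(); start += batch_size) {
      size_t stop = std::min(start + (size_t)batch_size, order.size());
      grad.zeros();
      ParamView pv = make_views(params.memptr(), c);
      ParamView gv = make_views(grad.memptr(), c);
      int nb = (int)(stop - start);
      for (size_t k = start; k < stop; ++k) {
        arma::imat cid = crop_case(ids[order[k]], c.max_len, rng);
        const int L1 = cid.n_rows;
        std::vector<int> mask_pos;
        for (int i = 1; i < L1; ++i)
          if (unif(rng) < mask_prob) mask_pos.push_back(i);
        if (mask_pos.empty())
          mask_pos.push_back(1 + (int)(rng() % (uint64_t)(L1 - 1)));
        ForwardCache fc;
        forward_case(pv, c, cid, empty_clin, fc, true, nullptr, &mask_pos);
        mat dZ(L1, c.m, arma::fill::zeros);
        double case_loss = 0;
        const double wscale = 1.0 / (double)(mask_pos.size() * c.d * nb);
        for (int i : mask_pos) {
          for (int ch = 0; ch < c.d; ++ch) {
            const mat& E = pv.M[pv.emb0 + ch];
            vec logits = E * fc.Z.row(i).t();
            logits -= logits.max();
            vec p = arma::exp(logits);
            p /= arma::accu(p);
            int truth = cid(i, ch) - 2;
            case_loss += -std::log(std::max(p(truth), 1e-12));
            vec dp = p; dp(truth) -= 1.0;
            dZ.row(i) += wscale * (dp.t() * E);
            gv.M[gv.emb0 + ch] += wscale * (dp * fc.Z.row(i));
          }
        }
        epoch_loss += case_loss / (mask_pos.size() * c.d);
        backward_encoder(pv, gv, c, cid, fc, dZ, &mask_pos);
      }
      n_seen += nb;
      ++step;
      if (clip_norm > 0) {
        double gn = arma::norm(grad, 2);
        if (gn > clip_norm) grad *= clip_norm / gn;
      }
      double bc1 = 1.0 - std::pow(b1, (double)step);
      double bc2 = 1.0 - std::pow(b2, (double)step);
      mAdam = b1 * mAdam + (1 - b1) * grad;
      vAdam = b2 * vAdam + (1 - b2) * arma::square(grad);
      params -= lr * ((mAdam / bc1) / (arma::sqrt(vAdam / bc2) + eps)
                      + weight_decay * (decay_mask % params));
    }
    hist.push_back(epoch_loss / n_seen);
  }
  return Rcpp::List::create(Rcpp::Named("params") = params,
                            Rcpp::Named("loss") = hist);
}

static double eval_loss(const ParamView& pv, const TFConfig& c,
                        const std::vector<arma::imat>& ids,
                        const arma::mat& clin, const arma::vec& y,
                        const std::vector<int>& idx, double pos_weight) {
  double loss = 0;
  for (int i : idx) {
    rowvec cr = c.use_clin ? rowvec(clin.row(i)) : rowvec();
    ForwardCache fc;
    forward_case(pv, c, ids[i], cr, fc, false, nullptr);
    loss += bce_loss(fc.logit, y(i), pos_weight);
  }
  return loss / idx.size();
}

// random contiguous crop of a sequence to the training window:
// row 0 (CLS) is kept, content rows are a random max_len-long window
static arma::imat crop_case(const arma::imat& ids, int max_len,
                            std::mt19937_64& rng) {
  int L = (int)ids.n_rows - 1;
  if (max_len <= 0 || L <= max_len) return ids;
  int start = (int)(rng() % (uint64_t)(L - max_len + 1));
  arma::imat out(max_len + 1, ids.n_cols);
  out.row(0) = ids.row(0);
  out.rows(1, max_len) = ids.rows(start + 1, start + max_len);
  return out;
}

// AdamW training with minibatches and early stopping on a monitored loss
// (validation loss when val_idx is non-empty, else epoch-mean train loss).
// Training sequences longer than max_len are re-cropped to a random
// contiguous window every epoch (data augmentation); validation and
// inference always use the leading window. When swa_start >= 0,
// parameters are tail-averaged over epochs > swa_start and the average is
// returned instead of the best-epoch parameters. Indices are 0-based.
// [[Rcpp::export]]
Rcpp::List tf_train(const arma::vec& params0, const Rcpp::List& cfg,
                    const Rcpp::List& ids_list, const arma::mat& clin,
                    const arma::vec& y,
                    const Rcpp::IntegerVector& train_idx,
                    const Rcpp::IntegerVector& val_idx,
                    double lr, double weight_decay, int batch_size,
                    int max_epochs, int patience, double pos_weight,
                    int seed, int swa_start = -1, double clip_norm = 1.0) {
  TFConfig c = parse_config(cfg);
  if ((long)params0.n_elem != tf_param_count_(c))
    Rcpp::stop("parameter vector has wrong length");
  arma::vec params = params0;
  arma::vec mAdam(params.n_elem, arma::fill::zeros);
  arma::vec vAdam(params.n_elem, arma::fill::zeros);
  std::vector<arma::imat> ids = as_imat_list(ids_list);
  // leading-window view used for validation scoring
  std::vector<arma::imat> ids_lead;
  ids_lead.reserve(ids.size());
  for (const arma::imat& M : ids) {
    if (c.max_len > 0 && (int)M.n_rows - 1 > c.max_len)
      ids_lead.push_back(M.rows(0, c.max_len));
    else
      ids_lead.push_back(M);
  }
  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  if (tr.empty()) Rcpp::stop("empty training index set");
  std::mt19937_64 rng((uint64_t)seed);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  double best = std::numeric_limits<double>::infinity();
  arma::vec best_params = params;
  int best_epoch = 0, bad = 0;
  arma::vec swa_sum; int swa_n = 0;
  std::vector<double> hist_train, hist_val;
  // decoupled weight decay applies to weight matrices only; biases,
  // LayerNorm parameters and the CLS/output vectors are exempt
  arma::vec decay_mask(params.n_elem, arma::fill::zeros);
  {
    ParamView mv = make_views(decay_mask.memptr(), c);
    for (int ch = 0; ch < c.d; ++ch) mv.M[mv.emb0 + ch].fill(1.0);
    for (int l = 0; l < c.nlayers; ++l)
      for (int k : {kWq, kWk, kWv, kWo, kW1, kW2}) mv.lay(l, k).fill(1.0);
    if (c.use_clin) mv.M[mv.Wc].fill(1.0);
  }
  arma::vec grad(params.n_elem);
  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double epoch_loss = 0; int n_seen = 0;
    for (size_t start = 0; start < tr.size(); start += batch_size) {
      size_t stop = std::min(start + (size_t)batch_size, tr.size());
      grad.zeros();
      ParamView pv = make_views(params.memptr(), c);
      ParamView gv = make_views(grad.memptr(), c);
      int nb = (int)(stop - start);
      int dseed = c.dropout > 0 ? (int)(rng() % 2147483647ULL) + 1 : 0;
      std::mt19937_64 drng((uint64_t)dseed);
      std::mt19937_64* rp = dseed != 0 ? &drng : nullptr;
      for (size_t k = start; k < stop; ++k) {
        int i = tr[k];
        rowvec cr = c.use_clin ? rowvec(clin.row(i)) : rowvec();
        arma::imat cid = crop_case(ids[i], c.max_len, rng);
        ForwardCache fc;
        forward_case(pv, c, cid, cr, fc, true, rp);
        epoch_loss += bce_loss(fc.logit, y(i), pos_weight);
        backward_case(pv, gv, c, cid, cr, fc,
                      bce_dlogit(fc.logit, y(i), pos_weight) / nb);
      }
      n_seen += nb;
      ++step;
      if (clip_norm > 0) {
        double gn = arma::norm(grad, 2);
        if (gn > clip_norm) grad *= clip_norm / gn;
      }
      double bc1 = 1.0 - std::pow(b1, (double)step);
      double bc2 = 1.0 - std::pow(b2, (double)step);
      mAdam = b1 * mAdam + (1 - b1) * grad;
      vAdam = b2 * vAdam + (1 - b2) * arma::square(grad);
      params -= lr * ((mAdam / bc1) / (arma::sqrt(vAdam / bc2) + eps)
                      + weight_decay * (decay_mask % params));
    }
    double train_loss = epoch_loss / n_seen;
    hist_train.push_back(train_loss);
    double monitored = train_loss;
    if (!va.empty()) {
      ParamView pv = make_views(params.memptr(), c);
      monitored = eval_loss(pv, c, ids_lead, clin, y, va, pos_weight);
      hist_val.push_back(monitored);
    }
    if (swa_start >= 0 && epoch > swa_start) {
      if (swa_n == 0) swa_sum.zeros(params.n_elem);
      swa_sum += params;
      ++swa_n;
    }
    if (monitored < best - 1e-6) {
      best = monitored; best_params = params; best_epoch = epoch; bad = 0;
    } else if (swa_start < 0 && ++bad >= patience) break;
  }
  if (swa_n > 0) best_params = swa_sum / swa_n;
  else if (swa_start >= 0) best_params = params;
  return Rcpp::List::create(
    Rcpp::Named("params") = best_params,
    Rcpp::Named("train_loss") = hist_train,
    Rcpp::Named("val_loss") = hist_val,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("epochs_run") = (int)hist_train.size());
}
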